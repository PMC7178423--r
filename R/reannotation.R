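# Coverage-supported reannotation of distal 3'-UTR ends. Only single-interval
# 3'-UTR annotations are eligible; novel UTRs are never created, the 5' edge
# of a UTR is never moved, and truncation is applied only to transcripts at or
# above the TPM truncation gate.

#' Parameters of the distal-end detector and integration rules
#'
#' @param window_w Window length in bases used for the coverage scan.
#' @param step Stride of the scan in bases (`window_w >= step >= 1`).
#' @param min_cov Absolute floor on acceptable mean window coverage
#'   (reads/base).
#' @param cov_fraction Fraction `f` in (0, 1] of the proximal reference
#'   coverage a window must retain to be called covered.
#' @param extension_limit Maximum extension `E` in bases searched beyond the
#'   annotated distal end.
#' @param min_delta Minimum |change| in bases for a proposal to be called an
#'   extension or truncation rather than unchanged.
#' @param tpm_truncation_gate Truncations are integrated only for transcripts
#'   with TPM at or above this gate (extensions are not gated).
#' @return A list of class `reannotation_params`.
#' @export
reannotation_params <- function(window_w = 100L, step = 50L, min_cov = 1.0,
                                cov_fraction = 0.2, extension_limit = 5000L,
                                min_delta = 50L, tpm_truncation_gate = 5.0) {
  p <- list(window_w = as.integer(window_w), step = as.integer(step),
            min_cov = min_cov, cov_fraction = cov_fraction,
            extension_limit = as.integer(extension_limit),
            min_delta = as.integer(min_delta),
            tpm_truncation_gate = tpm_truncation_gate)
  stopifnot(p$window_w >= p$step, p$step >= 1L,
            p$cov_fraction > 0, p$cov_fraction <= 1,
            p$extension_limit >= 0L, p$min_delta >= 0L,
            p$min_cov >= 0, p$tpm_truncation_gate >= 0)
  structure(p, class = "reannotation_params")
}

reann_row <- function(id, old_end, new_end = old_end,
                      outcome = "skipped", reason = "none", delta = 0L) {
  data.frame(transcript_id = id, old_distal_end = old_end,
             new_distal_end = new_end, outcome = outcome,
             skip_reason = reason, bases_delta = as.integer(delta),
             stringsAsFactors = FALSE)
}

#' Propose a coverage-supported distal 3'-UTR end for one transcript
#'
#' The coverage vector is oriented 5'-to-3' over the annotated UTR plus an
#' extension margin. A proximal reference coverage `r` is taken over the
#' first `window_w` bases of the annotated UTR; windows of length `window_w`
#' at stride `step` are then scanned outward and the proposed end is the 3'
#' edge of the farthest window whose mean coverage is at least
#' `max(min_cov, cov_fraction * r)`, with all nearer windows also passing,
#' refined to single-base resolution by walking from that window to the
#' first base below the threshold. Zero proximal coverage yields a skip.
#'
#' @param model A `transcript_model` (non-single-interval UTRs are reported
#'   as skipped, not errors).
#' @param track A `coverage_track` (chromosomes absent from it count as
#'   zero coverage).
#' @param params A [reannotation_params] object.
#' @param chrom_length Optional chromosome length used to clip the search.
#' @param clip Optional genomic bound from a neighbouring gene on the same
#'   strand: the search never runs past it (an upper bound on `+`, a lower
#'   bound on `-`).
#' @return A one-row data.frame: `transcript_id`, `old_distal_end`,
#'   `new_distal_end`, `outcome` (`extended`/`truncated`/`unchanged`/
#'   `skipped`), `skip_reason`, `bases_delta` (signed; positive = extension).
#' @export
propose_distal_end <- function(model, track, params = reannotation_params(),
                               chrom_length = NULL, clip = NULL) {
  if (nrow(model$utr3) == 0L)
    return(reann_row(model$transcript_id, NA_integer_,
                     reason = "no_utr_annotation"))
  old_end <- utr3_distal_edge(model)
  if (!single_exon_utr3(model))
    return(reann_row(model$transcript_id, old_end, reason = "multi_exon_utr"))

  u <- model$utr3[1L, ]
  w <- params$window_w
  old_off <- u$end - u$start
  if (model$strand == "+") {
    lim <- u$end + params$extension_limit
    if (!is.null(chrom_length)) lim <- min(lim, chrom_length)
    if (!is.null(clip)) lim <- min(lim, clip)
    lim <- max(lim, u$end)
    cov <- track_values(track, model$chrom, u$start, lim)
  } else {
    lo <- max(u$start - params$extension_limit, 0L)
    if (!is.null(clip)) lo <- max(lo, clip)
    lo <- min(lo, u$start)
    cov <- rev(track_values(track, model$chrom, lo, u$end))
  }
  L <- length(cov)
  r <- mean(cov[seq_len(min(w, old_off, L))])
  if (r <= 0)
    return(reann_row(model$transcript_id, old_end, reason = "no_coverage"))
  thr <- max(params$min_cov, params$cov_fraction * r)

  w_eff <- min(w, L)
  starts <- seq.int(0L, L - w_eff, by = params$step)
  cs <- c(0, cumsum(cov))
  wmeans <- (cs[starts + w_eff + 1L] - cs[starts + 1L]) / w_eff
  fail <- which(wmeans < thr)
  last_pass <- if (length(fail) == 0L) length(starts) else fail[1L] - 1L

  refine <- function(a) {
    tail_cov <- cov[(a + 1L):L]
    below <- which(tail_cov < thr)
    if (length(below) == 0L) L else a + below[1L] - 1L
  }
  if (last_pass == 0L) {
    new_off <- refine(0L)
  } else {
    a <- starts[last_pass]
    new_off <- refine(a)
    if (new_off <= a) new_off <- a + w_eff  # refinement uninformative
  }
  new_off <- max(min(new_off, L), 1L)

  delta <- new_off - old_off
  if (delta > params$min_delta) {
    outcome <- "extended"
  } else if (delta < -params$min_delta) {
    outcome <- "truncated"
  } else {
    outcome <- "unchanged"
    new_off <- old_off
    delta <- 0L
  }
  new_end <- if (model$strand == "+") u$start + new_off else u$end - new_off
  reann_row(model$transcript_id, old_end, new_end, outcome, "none", delta)
}

# genomic bound of the nearest same-strand neighbour beyond the distal end
neighbor_clip <- function(model, models) {
  if (nrow(model$utr3) == 0L) return(NULL)
  old_end <- utr3_distal_edge(model)
  spans <- lapply(models, function(o) {
    if (identical(o$transcript_id, model$transcript_id)) return(NULL)
    if (o$chrom != model$chrom || o$strand != model$strand) return(NULL)
    model_span(o)
  })
  spans <- Filter(Negate(is.null), spans)
  if (length(spans) == 0L) return(NULL)
  if (model$strand == "+") {
    starts <- vapply(spans, `[`, 0, 1L)
    starts <- starts[starts >= old_end]
    if (length(starts) == 0L) NULL else min(starts)
  } else {
    ends <- vapply(spans, `[`, 0, 2L)
    ends <- ends[ends <= old_end]
    if (length(ends) == 0L) NULL else max(ends)
  }
}

#' Integrate proposed distal ends into transcript models
#'
#' Eligibility rules: models whose 3'-UTR spans multiple intervals are left
#' untouched; proposals for transcripts without an annotated 3'-UTR (novel
#' UTRs) are discarded; the 5' edge of a 3'-UTR is never moved; truncations
#' are applied only to transcripts with TPM at or above the truncation gate,
#' while extensions are applied regardless of expression. Applied proposals
#' move the single UTR interval's distal edge and the matching terminal exon
#' edge in lockstep.
#'
#' @param models Named list of `transcript_model` objects.
#' @param results Data.frame of proposals as returned by
#'   [propose_distal_end] (one row per transcript).
#' @param tpm Abundance table, named numeric vector, or `NULL` (all zero).
#' @param params A [reannotation_params] object.
#' @return A list with `models` (updated named list) and `report` (one row
#'   per proposal with final outcomes).
#' @export
apply_reannotations <- function(models, results, tpm = NULL,
                                params = reannotation_params()) {
  if (is.null(names(models)) || !all(nzchar(names(models))))
    names(models) <- vapply(models, function(m) m$transcript_id, "")
  unknown <- setdiff(results$transcript_id, names(models))
  if (length(unknown) > 0L)
    stop(sprintf("reannotation result references unknown transcript(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  tpm_vals <- tpm_lookup(tpm, results$transcript_id, warn = FALSE)
  report <- vector("list", nrow(results))
  for (i in seq_len(nrow(results))) {
    res <- results[i, ]
    id <- res$transcript_id
    m <- models[[id]]
    old_end <- if (nrow(m$utr3) > 0L) utr3_distal_edge(m) else NA_integer_
    if (nrow(m$utr3) == 0L) {
      report[[i]] <- reann_row(id, old_end, reason = "no_utr_annotation")
      next
    }
    if (!single_exon_utr3(m)) {
      report[[i]] <- reann_row(id, old_end, reason = "multi_exon_utr")
      next
    }
    if (!res$outcome %in% c("extended", "truncated")) {
      report[[i]] <- reann_row(id, old_end, res$new_distal_end,
                               res$outcome, res$skip_reason, 0L)
      next
    }
    if (res$outcome == "truncated" &&
        tpm_vals[[id]] < params$tpm_truncation_gate) {
      report[[i]] <- reann_row(id, old_end,
                               reason = "low_expression_truncation")
      next
    }
    models[[id]] <- move_distal_edge(m, res$new_distal_end)
    report[[i]] <- reann_row(id, old_end, res$new_distal_end, res$outcome,
                             "none", res$bases_delta)
  }
  list(models = models, report = do.call(rbind, report))
}

# set the distal edge of a single-interval 3'-UTR, adjusting the terminal
# exon edge in lockstep so the UTR stays inside the exon union
move_distal_edge <- function(m, new_end) {
  u <- m$utr3[1L, ]
  ex <- m$exons
  if (m$strand == "+") {
    if (new_end <= u$start)
      stop(sprintf("transcript %s: proposed end would empty the 3'-UTR",
                   m$transcript_id), call. = FALSE)
    i <- which(ex$start <= u$end & u$end <= ex$end)
    i <- i[length(i)]
    ex$end[i] <- if (ex$end[i] == u$end) new_end else max(ex$end[i], new_end)
    m$utr3$end[1L] <- new_end
  } else {
    if (new_end >= u$end)
      stop(sprintf("transcript %s: proposed end would empty the 3'-UTR",
                   m$transcript_id), call. = FALSE)
    i <- which(ex$start <= u$start & u$start <= ex$end)
    i <- i[1L]
    ex$start[i] <- if (ex$start[i] == u$start) new_end else min(ex$start[i], new_end)
    m$utr3$start[1L] <- new_end
  }
  m$exons <- ex
  validate_model(m)
  m
}

#' Reannotate a model set from replicate coverage
#'
#' Convenience wrapper: merges replicate tracks, proposes a distal end for
#' every protein-coding model (clipping each search at the nearest
#' same-strand downstream gene and at the chromosome end), and integrates
#' the proposals under the eligibility rules.
#'
#' @param models Named list of `transcript_model` objects.
#' @param tracks A single `coverage_track` or a list of replicate tracks.
#' @param tpm Abundance table or named numeric vector (see [tpm_lookup]).
#' @param params A [reannotation_params] object.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return A list with `models` and `report` (as [apply_reannotations]).
#' @export
reannotate <- function(models, tracks, tpm = NULL,
                       params = reannotation_params(), chrom_lengths = NULL) {
  track <- if (inherits(tracks, "coverage_track")) tracks
           else merge_replicates(tracks)
  if (is.null(names(models)) || !all(nzchar(names(models))))
    names(models) <- vapply(models, function(m) m$transcript_id, "")
  coding <- Filter(function(m) m$biotype == "protein_coding", models)
  proposals <- do.call(rbind, lapply(coding, function(m) {
    propose_distal_end(m, track, params,
                       chrom_length = chrom_lengths[[m$chrom]] %||% NULL,
                       clip = neighbor_clip(m, coding))
  }))
  rownames(proposals) <- NULL
  out <- apply_reannotations(models, proposals, tpm, params)
  out
}

#' Write a reannotation report as TSV
#' @param report The `report` element returned by [reannotate] or
#'   [apply_reannotations].
#' @param path Output path.
#' @export
write_reannotation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
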