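# Canonical miRNA seed-site taxonomy on contiguous 3'-UTR sequences.
# S6 = reverse complement of miRNA positions 2-7; S7 = reverse complement of
# positions 2-8 (one extra base on the mRNA 5' side). Each S6 occurrence is
# reported once, with precedence 8mer > 7mer-m8 > 7mer-A1 > 6mer.

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Normalise a mature miRNA sequence
#'
#' Converts RNA (U) to the DNA alphabet and validates it: at least 8 nt,
#' alphabet within A/C/G/T after conversion. Positions are numbered 1-based
#' from the 5' end.
#'
#' @param seq Mature miRNA sequence, 5'-to-3', U or T alphabet.
#' @return Upper-case DNA-alphabet sequence.
#' @export
normalize_mirna <- function(seq) {
  s <- chartr("uU", "tT", toupper(seq))
  s <- toupper(s)
  if (nchar(s) < 8L)
    stop("mature miRNA must be at least 8 nt", call. = FALSE)
  if (grepl("[^ACGT]", s))
    stop("mature miRNA contains characters outside A/C/G/U/T", call. = FALSE)
  s
}

#' Read mature miRNA sequences from FASTA
#'
#' U/T tolerant; duplicate ids are dropped (first kept) with a warning.
#'
#' @param path Path to a FASTA file of mature miRNA sequences.
#' @return A data.frame with columns `mirna_id` and `seq` (DNA alphabet).
#' @export
read_mirna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    warning(sprintf("%d duplicate miRNA id(s) dropped", sum(duplicated(ids))),
            call. = FALSE)
    set <- set[!duplicated(ids)]
    ids <- ids[!duplicated(ids)]
  }
  data.frame(mirna_id = ids,
             seq = vapply(as.character(set), normalize_mirna, ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

empty_sites <- function() {
  data.frame(transcript_id = character(), mirna_id = character(),
             site_type = character(), utr_offset = integer(),
             match_len = integer(), stringsAsFactors = FALSE)
}

#' Scan a 3'-UTR sequence for canonical seed sites of one miRNA
#'
#' At each occurrence of the 6mer seed complement the site is classified as
#' 8mer (seed complement extended to miRNA position 8 on the mRNA 5' side
#' and an A opposite miRNA position 1 on the 3' side), 7mer-m8 (extension
#' only), 7mer-A1 (the A only) or 6mer, with precedence in that order.
#' `utr_offset` is the 0-based start of the maximal matched span;
#' N never matches; matches truncated by the UTR boundary fall back to the
#' type fully contained.
#'
#' @param utr_seq mRNA-sense UTR sequence (DNA alphabet, may contain N).
#' @param mirna_seq Mature miRNA sequence (U or T alphabet, >= 8 nt).
#' @param mirna_id,transcript_id Identifiers copied into the output.
#' @return A data.frame of seed sites (possibly empty): `transcript_id`,
#'   `mirna_id`, `site_type`, `utr_offset`, `match_len`.
#' @export
scan_seed_sites <- function(utr_seq, mirna_seq, mirna_id = NA_character_,
                            transcript_id = NA_character_) {
  m <- normalize_mirna(mirna_seq)
  s6 <- revcomp_chr(substr(m, 2L, 7L))
  m8_comp <- DNA_COMP[[substr(m, 8L, 8L)]]  # mRNA base 5' of the S6 match
  L <- nchar(utr_seq)
  if (L < 6L) return(empty_sites())
  hits <- Biostrings::matchPattern(s6, Biostrings::DNAString(utr_seq),
                                   fixed = TRUE)
  if (length(hits) == 0L) return(empty_sites())
  i0 <- Biostrings::start(hits) - 1L  # 0-based S6 offsets
  prev <- ifelse(i0 >= 1L, substring(utr_seq, i0, i0), "")
  nxt <- ifelse(i0 + 6L < L, substring(utr_seq, i0 + 7L, i0 + 7L), "")
  has_m8 <- prev == m8_comp
  has_a1 <- nxt == "A"
  type <- ifelse(has_m8 & has_a1, "8mer",
          ifelse(has_m8, "7mer-m8",
          ifelse(has_a1, "7mer-A1", "6mer")))
  offset <- ifelse(has_m8, i0 - 1L, i0)
  len <- 6L + has_m8 + has_a1
  data.frame(transcript_id = transcript_id, mirna_id = mirna_id,
             site_type = type, utr_offset = as.integer(offset),
             match_len = as.integer(len), stringsAsFactors = FALSE)
}

# Independent straight-line scanner used to build synthetic truth tables:
# tests every UTR position by direct substring comparison.
scan_seed_sites_bruteforce <- function(utr_seq, mirna_seq,
                                       mirna_id = NA_character_,
                                       transcript_id = NA_character_) {
  m <- normalize_mirna(mirna_seq)
  s6 <- revcomp_chr(substr(m, 2L, 7L))
  m8_comp <- DNA_COMP[[substr(m, 8L, 8L)]]
  L <- nchar(utr_seq)
  rows <- empty_sites()
  if (L < 6L) return(rows)
  for (i0 in 0:(L - 6L)) {
    if (substring(utr_seq, i0 + 1L, i0 + 6L) != s6) next
    has_m8 <- i0 >= 1L && substring(utr_seq, i0, i0) == m8_comp
    has_a1 <- i0 + 6L < L && substring(utr_seq, i0 + 7L, i0 + 7L) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1" else "6mer"
    rows <- rbind(rows, data.frame(
      transcript_id = transcript_id, mirna_id = mirna_id, site_type = type,
      utr_offset = as.integer(if (has_m8) i0 - 1L else i0),
      match_len = as.integer(6L + has_m8 + has_a1),
      stringsAsFactors = FALSE))
  }
  rows
}

# genomic positions (0-based) of selected 0-based UTR offsets, walking the
# UTR intervals in transcription order
utr_offsets_to_genomic <- function(model, offsets) {
  ivs <- model$utr3[order(model$utr3$start), , drop = FALSE]
  widths <- ivs$end - ivs$start
  if (model$strand == "-") {
    ivs <- ivs[rev(seq_len(nrow(ivs))), , drop = FALSE]
    widths <- rev(widths)
  }
  cum <- cumsum(c(0L, widths))
  vapply(offsets, function(o) {
    k <- findInterval(o, cum, rightmost.closed = FALSE)
    if (k < 1L || k > nrow(ivs) || o >= cum[nrow(ivs) + 1L])
      stop("UTR offset beyond UTR length", call. = FALSE)
    within <- o - cum[k]
    if (model$strand == "+") ivs$start[k] + within
    else ivs$end[k] - 1L - within
  }, 0L)
}

#' Predict canonical seed sites over a model set
#'
#' Orchestrates [extract_utr_sequence] and [scan_seed_sites] over all
#' protein-coding models with a non-empty 3'-UTR, mapping each site back to
#' genomic coordinates. The genomic span covers the maximal matched bases
#' (on the minus strand the 5'-most matched base has the highest genomic
#' coordinate).
#'
#' @param bundle A `reference_bundle`.
#' @param models List of models (defaults to the bundle's).
#' @param mirnas Data.frame with `mirna_id` and `seq` columns (see
#'   [read_mirna_fasta]); duplicate ids are deduplicated with a warning.
#' @param annotation_label Label stored on the result (attribute
#'   `annotation_label`).
#' @return A prediction set: data.frame with `transcript_id`, `mirna_id`,
#'   `site_type`, `utr_offset`, `match_len`, `chrom`, `genomic_start`,
#'   `genomic_end`, `strand`.
#' @export
predict_targets <- function(bundle, models = bundle$models, mirnas,
                            annotation_label = "annotation") {
  if (anyDuplicated(mirnas$mirna_id)) {
    warning(sprintf("%d duplicate miRNA id(s) dropped", sum(duplicated(mirnas$mirna_id))),
            call. = FALSE)
    mirnas <- mirnas[!duplicated(mirnas$mirna_id), , drop = FALSE]
  }
  models <- Filter(function(m) m$biotype == "protein_coding" &&
                     nrow(m$utr3) > 0L, models)
  out <- list()
  for (m in models) {
    useq <- extract_utr_sequence(bundle, m)
    for (j in seq_len(nrow(mirnas))) {
      sites <- scan_seed_sites(useq, mirnas$seq[j], mirnas$mirna_id[j],
                               m$transcript_id)
      if (nrow(sites) == 0L) next
      g_first <- utr_offsets_to_genomic(m, sites$utr_offset)
      g_last <- utr_offsets_to_genomic(m, sites$utr_offset + sites$match_len - 1L)
      sites$chrom <- m$chrom
      sites$genomic_start <- as.integer(pmin(g_first, g_last))
      sites$genomic_end <- as.integer(pmax(g_first, g_last) + 1L)
      sites$strand <- m$strand
      out[[length(out) + 1L]] <- sites
    }
  }
  res <- if (length(out) == 0L) {
    cbind(empty_sites(),
          data.frame(chrom = character(), genomic_start = integer(),
                     genomic_end = integer(), strand = character()))
  } else {
    do.call(rbind, out)
  }
  rownames(res) <- NULL
  attr(res, "annotation_label") <- annotation_label
  res
}

#' Filter a prediction set by transcript expression
#'
#' Retains exactly the sites on transcripts with TPM at or above the
#' threshold (transcripts absent from the table count as TPM 0). The ids of
#' removed transcripts are attached as attribute `removed_transcripts`.
#'
#' @param preds A prediction set (see [predict_targets]).
#' @param tpm Abundance table or named numeric vector.
#' @param threshold Minimum TPM (inclusive); must be >= 0. Default 0.1.
#' @return The filtered prediction set.
#' @export
filter_by_expression <- function(preds, tpm, threshold = 0.1) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("expression threshold must be a single non-negative number",
         call. = FALSE)
  ids <- unique(preds$transcript_id)
  vals <- tpm_lookup(tpm, ids, warn = TRUE)
  keep_ids <- ids[vals >= threshold]
  out <- preds[preds$transcript_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "annotation_label") <- attr(preds, "annotation_label")
  attr(out, "removed_transcripts") <- setdiff(ids, keep_ids)
  out
}

site_key <- function(preds) {
  paste(preds$transcript_id, preds$mirna_id, preds$site_type,
        preds$chrom, preds$genomic_start, preds$strand, sep = "\r")
}

#' Compare prediction sets across annotation versions
#'
#' Site identity uses genomic coordinates (transcript, miRNA, type, genomic
#' start, strand) so an unchanged site is never relabelled by a UTR length
#' change. Percentages are relative to the baseline site total and reported
#' as `NA` when the baseline is empty.
#'
#' @param baseline,revised Prediction sets over the same transcript
#'   namespace.
#' @param baseline_models,revised_models The model lists the two sets were
#'   derived from (used for UTR base deltas).
#' @return An object of class `comparison_stats`: counts and percentages of
#'   gained/lost sites, UTR bases added/removed, the percentage of baseline
#'   UTR bases lost, the fraction of baseline UTRs affected, and the
#'   `gained`/`lost` site tables themselves.
#' @export
compare_annotation_sets <- function(baseline, revised,
                                    baseline_models, revised_models) {
  bk <- site_key(baseline)
  rk <- site_key(revised)
  gained <- revised[!rk %in% bk, , drop = FALSE]
  lost <- baseline[!bk %in% rk, , drop = FALSE]
  n_base <- nrow(baseline)
  pct <- function(n) if (n_base == 0L) NA_real_ else 100 * n / n_base

  if (is.null(names(baseline_models)))
    names(baseline_models) <- vapply(baseline_models, `[[`, "", "transcript_id")
  if (is.null(names(revised_models)))
    names(revised_models) <- vapply(revised_models, `[[`, "", "transcript_id")
  ids <- union(names(baseline_models), names(revised_models))
  blen <- vapply(ids, function(id) {
    m <- baseline_models[[id]]; if (is.null(m)) 0L else utr3_length(m)
  }, 0L)
  rlen <- vapply(ids, function(id) {
    m <- revised_models[[id]]; if (is.null(m)) 0L else utr3_length(m)
  }, 0L)
  d <- rlen - blen
  bases_added <- sum(pmax(d, 0L))
  bases_removed <- sum(pmax(-d, 0L))
  total_base <- sum(blen)
  affected_ids <- union(ids[d != 0L],
                        union(gained$transcript_id, lost$transcript_id))
  with_utr <- ids[blen > 0L]
  structure(list(
    sites_gained = nrow(gained), sites_lost = nrow(lost),
    pct_gained = pct(nrow(gained)), pct_lost = pct(nrow(lost)),
    bases_added = bases_added, bases_removed = bases_removed,
    pct_utr_bases_lost = if (total_base == 0L) NA_real_
                         else 100 * bases_removed / total_base,
    fraction_utrs_affected = if (length(with_utr) == 0L) NA_real_
      else length(intersect(affected_ids, with_utr)) / length(with_utr),
    gained = gained, lost = lost
  ), class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat("<comparison_stats>\n")
  cat(sprintf("  sites gained: %d (%s%%)  lost: %d (%s%%)\n",
              x$sites_gained, format(x$pct_gained, digits = 3),
              x$sites_lost, format(x$pct_lost, digits = 3)))
  cat(sprintf("  UTR bases added: %d  removed: %d (%s%% of baseline)\n",
              x$bases_added, x$bases_removed,
              format(x$pct_utr_bases_lost, digits = 3)))
  cat(sprintf("  fraction of baseline UTRs affected: %s\n",
              format(x$fraction_utrs_affected, digits = 3)))
  invisible(x)
}

#' Write a prediction set as TSV
#' @param preds A prediction set.
#' @param path Output path.
#' @export
write_predictions <- function(preds, path) {
  utils::write.table(preds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a prediction set from TSV
#' @param path Path to a predictions TSV written by [write_predictions].
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
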