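# Seeded generator of complete toy datasets: a toy genome with plus- and
# minus-strand protein-coding genes, annotated 3'-UTRs, planted distal-APA
# breakpoints in coverage, planted canonical seed sites, a consistent
# abundance table, and transfection log2 fold changes with planted
# repression of true targets. One RNG seed per run makes every emitted file
# byte-identical across repeats; replicate/transfection noise uses sub-seeds
# derived deterministically from the run seed.

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * k) %% 2147483647)
}

#' Parameters of the synthetic-data generator
#'
#' The defaults describe the study conditions the package is validated
#' under: 100 transcripts with 0.5-1.5 kb 3'-UTRs on both strands, mean
#' coverage 20 reads/base with Poisson noise over two replicates, a single
#' planted miRNA with 8mer sites in half of the UTRs, and a repression shift
#' of -0.5 log2 units (noise SD 0.5) for true targets.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param utr_len_range Annotated 3'-UTR length range (nt).
#' @param cds_len_range Length range of the upstream coding exon (nt).
#' @param intron_len Intron length between the coding and terminal exon.
#' @param intergenic_gap Gap between neighbouring genes (must exceed the
#'   extension search limit so searches are clipped by coverage, not
#'   neighbours).
#' @param frac_minus_strand Fraction of minus-strand genes.
#' @param frac_multi_exon_utr Fraction of transcripts with a 3'-UTR spanning
#'   two exons (ineligible for reannotation).
#' @param frac_no_utr Fraction of transcripts without a 3'-UTR annotation.
#' @param breakpoint_delta Planted signed distal-end changes in bases
#'   (recycled over eligible single-interval-UTR transcripts; positive =
#'   true end beyond the annotation, negative = short of it; 0 = none).
#' @param coverage_depth Mean coverage (reads/base) over expressed bases.
#' @param noise Apply per-base Poisson noise to coverage?
#' @param n_replicates Number of replicate coverage tracks.
#' @param mirna_id,mirna_seq The planted miRNA (U/T alphabet).
#' @param frac_target Fraction of UTR-bearing transcripts given a planted
#'   8mer site inside the true (post-breakpoint) UTR; these are repressed.
#' @param frac_decoy_site Fraction of truncated, non-target transcripts
#'   given a planted site between the true end and the annotated end; such
#'   transcripts behave like non-targets under transfection.
#' @param frac_gained_site Fraction of extended, non-target transcripts
#'   given a planted (repressed) site inside the extension, beyond the
#'   annotated end.
#' @param repression_delta Mean log2 fold-change shift of true targets.
#' @param repression_sigma Fold-change noise SD (both groups).
#' @param tpm_meanlog,tpm_sdlog Log-normal parameters of raw abundance
#'   (normalised to sum to 1e6 TPM).
#' @param seed Integer RNG seed for the whole run.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_transcripts = 100L,
                              utr_len_range = c(500L, 1500L),
                              cds_len_range = c(300L, 800L),
                              intron_len = 200L,
                              intergenic_gap = 8000L,
                              frac_minus_strand = 0.5,
                              frac_multi_exon_utr = 0,
                              frac_no_utr = 0,
                              breakpoint_delta = 0,
                              coverage_depth = 20,
                              noise = TRUE,
                              n_replicates = 2L,
                              mirna_id = "miR-syn-1",
                              mirna_seq = "UACCCUGUAGAUCCGAAUUUGUG",
                              frac_target = 0.5,
                              frac_decoy_site = 0,
                              frac_gained_site = 0,
                              repression_delta = 0.5,
                              repression_sigma = 0.5,
                              tpm_meanlog = 2,
                              tpm_sdlog = 1.2,
                              seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_transcripts >= 1L,
            p$frac_minus_strand >= 0, p$frac_minus_strand <= 1,
            p$frac_multi_exon_utr >= 0, p$frac_no_utr >= 0,
            p$frac_multi_exon_utr + p$frac_no_utr <= 1,
            p$coverage_depth > 0, p$n_replicates >= 1L,
            p$repression_sigma > 0,
            min(p$utr_len_range) >= 250L,
            p$intergenic_gap >= 1000L)
  structure(p, class = "simulation_params")
}

#' Simulate a toy reference (genome, models, truth table)
#'
#' Lays the genes along one chromosome with intergenic gaps, plants 8mer
#' seed sites of the configured miRNA, and records ground truth (true
#' distal ends, planted deltas, planted sites, true TPM, target flags).
#' Planted sites are re-scanned with an independent straight-line scanner
#' so the truth table reflects actual occurrences, including any background
#' matches created by the random sequence.
#'
#' @param params A [simulation_params] object.
#' @return A list of class `simulation` with elements `bundle`
#'   (`reference_bundle`), `truth` (per-transcript data.frame), `mirnas`
#'   (data.frame `mirna_id`, `seq`) and `params`.
#' @export
simulate_reference <- function(params = simulation_params()) {
  set.seed(params$seed)
  n <- params$n_transcripts
  mseq <- normalize_mirna(params$mirna_seq)
  site8 <- paste0(revcomp_chr(substr(mseq, 2L, 8L)), "A")  # mRNA-sense 8mer

  strand <- ifelse(stats::runif(n) < params$frac_minus_strand, "-", "+")
  u <- stats::runif(n)
  utr_class <- ifelse(u < params$frac_multi_exon_utr, "multi",
               ifelse(u < params$frac_multi_exon_utr + params$frac_no_utr,
                      "none", "single"))
  utr_len <- sample(params$utr_len_range[1L]:params$utr_len_range[2L], n,
                    replace = TRUE)
  cds_len <- sample(params$cds_len_range[1L]:params$cds_len_range[2L], n,
                    replace = TRUE)
  delta <- rep_len(as.integer(params$breakpoint_delta), n)
  delta[utr_class != "single"] <- 0L
  # keep at least ~100 nt of true UTR so the proximal reference window holds
  delta <- pmax(delta, -(utr_len - 100L))

  site <- rep("none", n)
  has_utr <- utr_class != "none"
  is_tgt <- has_utr & stats::runif(n) < params$frac_target
  site[is_tgt] <- "retained"
  decoy_ok <- utr_class == "single" & delta <= -100L & !is_tgt
  site[decoy_ok & stats::runif(n) < params$frac_decoy_site] <- "decoy"
  gain_ok <- utr_class == "single" & delta >= 100L & site == "none"
  site[gain_ok & stats::runif(n) < params$frac_gained_site] <- "gained"

  models <- vector("list", n)
  cursor <- params$intergenic_gap
  truth <- vector("list", n)
  plant <- list()  # genomic stamps: list of (pos0, seq)
  for (i in seq_len(n)) {
    id <- sprintf("TX%04d", i)
    ul <- utr_len[i]
    true_ul <- ul + delta[i]
    if (strand[i] == "+") {
      e1 <- c(cursor, cursor + cds_len[i])
      e2s <- e1[2L] + params$intron_len
      if (utr_class[i] == "multi") {
        exA <- c(e2s, e2s + 50L + 100L)
        exBs <- exA[2L] + params$intron_len
        exB <- c(exBs, exBs + ul - 100L)
        exons <- intervals(c(e1[1L], exA[1L], exB[1L]),
                           c(e1[2L], exA[2L], exB[2L]))
        utr3 <- intervals(c(exA[1L] + 50L, exB[1L]), c(exA[2L], exB[2L]))
      } else if (utr_class[i] == "none") {
        e2 <- c(e2s, e2s + 150L)
        exons <- intervals(c(e1[1L], e2[1L]), c(e1[2L], e2[2L]))
        utr3 <- intervals()
      } else {
        e2 <- c(e2s, e2s + 50L + ul)
        exons <- intervals(c(e1[1L], e2[1L]), c(e1[2L], e2[2L]))
        utr3 <- intervals(e2s + 50L, e2[2L])
      }
      tx_end <- max(exons$end)
      ann_dist <- if (nrow(utr3) > 0L) max(utr3$end) else NA_integer_
      true_dist <- if (utr_class[i] == "single") ann_dist + delta[i] else ann_dist
      utr_gstart <- if (utr_class[i] == "single") utr3$start[1L] else NA_integer_
    } else {
      # minus strand: terminal (UTR) exon genomically first
      if (utr_class[i] == "multi") {
        exB <- c(cursor, cursor + ul - 100L)
        exAs <- exB[2L] + params$intron_len
        exA <- c(exAs, exAs + 100L + 50L)
        e1s <- exA[2L] + params$intron_len
        e1 <- c(e1s, e1s + cds_len[i])
        exons <- intervals(c(exB[1L], exA[1L], e1[1L]),
                           c(exB[2L], exA[2L], e1[2L]))
        utr3 <- intervals(c(exB[1L], exA[1L]), c(exB[2L], exA[1L] + 100L))
      } else if (utr_class[i] == "none") {
        e2 <- c(cursor, cursor + 150L)
        e1s <- e2[2L] + params$intron_len
        e1 <- c(e1s, e1s + cds_len[i])
        exons <- intervals(c(e2[1L], e1[1L]), c(e2[2L], e1[2L]))
        utr3 <- intervals()
      } else {
        e2 <- c(cursor, cursor + ul + 50L)
        e1s <- e2[2L] + params$intron_len
        e1 <- c(e1s, e1s + cds_len[i])
        exons <- intervals(c(e2[1L], e1[1L]), c(e2[2L], e1[2L]))
        utr3 <- intervals(e2[1L], e2[1L] + ul)
      }
      tx_end <- max(exons$end)
      ann_dist <- if (nrow(utr3) > 0L) min(utr3$start) else NA_integer_
      true_dist <- if (utr_class[i] == "single") ann_dist - delta[i] else ann_dist
      utr_gstart <- NA_integer_
    }
    models[[i]] <- transcript_model(id, "chr1", strand[i], exons, utr3,
                                    gene_id = sprintf("G%04d", i))
    # planted site offset in true-UTR 5'->3' coordinates
    off <- NA_integer_
    if (site[i] == "retained") {
      usable <- min(ul, true_ul) - 18L
      off <- sample(10:max(10L, usable), 1L)
    } else if (site[i] == "decoy") {
      off <- sample((true_ul + 10L):(ul - 18L), 1L)
    } else if (site[i] == "gained") {
      off <- sample((ul + 10L):(true_ul - 18L), 1L)
    }
    if (!is.na(off)) {
      # map UTR offset (contiguous terminal exon) to a genomic stamp
      if (strand[i] == "+") {
        u5 <- utr3_five_prime_edge(models[[i]])
        plant[[length(plant) + 1L]] <- list(pos = u5 + off, seq = site8)
      } else {
        u5 <- utr3_five_prime_edge(models[[i]])
        gpos <- u5 - off - 8L
        plant[[length(plant) + 1L]] <- list(pos = gpos, seq = revcomp_chr(site8))
      }
    }
    truth[[i]] <- data.frame(
      transcript_id = id, chrom = "chr1", strand = strand[i],
      utr_class = utr_class[i], annotated_utr_len = ifelse(has_utr[i], ul, 0L),
      annotated_distal_end = ann_dist, true_distal_end = true_dist,
      delta = delta[i], site = site[i], site_offset = off,
      is_target = site[i] %in% c("retained", "gained"),
      tx_start = min(exons$start), tx_end = tx_end,
      stringsAsFactors = FALSE)
    cursor <- tx_end + params$intergenic_gap
  }
  chrom_len <- cursor + params$intergenic_gap
  bases <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  for (st in plant) {
    bases[(st$pos + 1L):(st$pos + nchar(st$seq))] <-
      strsplit(st$seq, "")[[1L]]
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(
    paste(bases, collapse = ""), "chr1"))
  names(models) <- vapply(models, function(m) m$transcript_id, "")
  truth <- do.call(rbind, truth)

  # true TPM (normalised) and a consistent count/length table
  raw <- stats::rlnorm(n, params$tpm_meanlog, params$tpm_sdlog)
  truth$tpm <- 1e6 * raw / sum(raw)

  bundle <- reference_bundle(genome, models)
  mirnas <- data.frame(mirna_id = params$mirna_id, seq = mseq,
                       stringsAsFactors = FALSE)

  # record actual planted-site occurrences with the independent scanner
  truth$n_sites_true_utr <- vapply(seq_len(n), function(i) {
    m <- models[[i]]
    if (nrow(m$utr3) == 0L) return(0L)
    ivs <- true_utr_intervals(m, truth$true_distal_end[i])
    useq <- extract_utr_sequence(bundle, m, utr_override = ivs)
    nrow(scan_seed_sites_bruteforce(useq, mseq))
  }, 0L)

  structure(list(bundle = bundle, truth = truth, mirnas = mirnas,
                 params = params),
            class = "simulation")
}

# the model's UTR intervals with the distal edge moved to the true end
true_utr_intervals <- function(m, true_dist) {
  ivs <- m$utr3
  if (nrow(ivs) != 1L || is.na(true_dist)) return(ivs)
  if (m$strand == "+") ivs$end[1L] <- true_dist else ivs$start[1L] <- true_dist
  ivs
}

#' @export
print.simulation <- function(x, ...) {
  cat(sprintf("<simulation> %d transcripts, chromosome of %d nt, seed %d\n",
              nrow(x$truth), x$bundle$chrom_lengths[[1L]], x$params$seed))
  print(table(x$truth$utr_class))
  invisible(x)
}

#' Simulate replicate coverage tracks with planted breakpoints
#'
#' Coverage is piecewise constant at `coverage_depth` over every exon body,
#' with the terminal exon extended or truncated to the true distal end, and
#' (approximately) zero elsewhere; per-base Poisson noise is applied when
#' `params$noise` is `TRUE`. Replicates differ only by their derived noise
#' sub-seed.
#'
#' @param sim A `simulation` (from [simulate_reference]).
#' @param depth_scale Multiplier on the configured depth (for
#'   depth-titration experiments).
#' @return A list of `coverage_track` objects, one per replicate.
#' @export
simulate_coverage <- function(sim, depth_scale = 1) {
  params <- sim$params
  truth <- sim$truth
  models <- sim$bundle$models
  depth <- params$coverage_depth * depth_scale
  covered <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    m <- models[[truth$transcript_id[i]]]
    ex <- m$exons
    if (truth$utr_class[i] == "single") {
      td <- truth$true_distal_end[i]
      if (m$strand == "+") {
        j <- which.max(ex$end)
        ex$end[j] <- td
      } else {
        j <- which.min(ex$start)
        ex$start[j] <- td
      }
    }
    ex[ex$end > ex$start, , drop = FALSE]
  }))
  covered <- covered[order(covered$start), , drop = FALSE]
  lapply(seq_len(params$n_replicates), function(r) {
    if (params$noise) {
      set.seed(derive_seed(params$seed, r))
      rows <- do.call(rbind, lapply(seq_len(nrow(covered)), function(k) {
        len <- covered$end[k] - covered$start[k]
        v <- stats::rpois(len, depth)
        rl <- rle(v)
        ends <- covered$start[k] + cumsum(rl$lengths)
        data.frame(start = ends - rl$lengths, end = ends, value = rl$values)
      }))
      rows <- rows[rows$value > 0, , drop = FALSE]
      coalesce_track(coverage_track(list(chr1 = rows)))
    } else {
      coalesce_track(coverage_track(list(
        chr1 = data.frame(start = covered$start, end = covered$end,
                          value = depth))))
    }
  })
}

#' Simulate a miRNA-transfection fold-change table
#'
#' Non-targets draw log2 fold changes from Normal(0, sigma); true targets
#' (planted site inside the true UTR) from Normal(-delta, sigma).
#' Transcripts whose planted site lies beyond a planted truncation behave
#' like non-targets.
#'
#' @param sim A `simulation`.
#' @param noise_seed Optional sub-seed index for re-drawing the noise
#'   (default 0 reproduces the run's canonical table).
#' @return Data.frame with `transcript_id` and `log2fc`.
#' @export
simulate_transfection <- function(sim, noise_seed = 0L) {
  params <- sim$params
  set.seed(derive_seed(params$seed, 100000L + noise_seed))
  mu <- ifelse(sim$truth$is_target, -params$repression_delta, 0)
  data.frame(transcript_id = sim$truth$transcript_id,
             log2fc = stats::rnorm(nrow(sim$truth), mu,
                                   params$repression_sigma),
             stringsAsFactors = FALSE)
}

#' Abundance table consistent with the simulated truth
#'
#' Builds estimated counts and effective lengths whose [compute_tpm] output
#' reproduces the truth TPM exactly.
#'
#' @param sim A `simulation`.
#' @param library_size Total fragment count to distribute.
#' @return Data.frame `transcript_id`, `est_count`, `eff_length`, `tpm`.
#' @export
simulate_abundance <- function(sim, library_size = 1e6) {
  eff <- vapply(sim$bundle$models[sim$truth$transcript_id],
                function(m) interval_width(m$exons), 0L)
  counts <- sim$truth$tpm * eff
  counts <- counts / sum(counts) * library_size
  compute_tpm(data.frame(transcript_id = sim$truth$transcript_id,
                         est_count = counts, eff_length = eff,
                         stringsAsFactors = FALSE))
}

#' Write a complete simulated dataset to a directory
#'
#' Emits `genome.fa`, `annotation.gtf`, `coverage_rep<k>.bedgraph`,
#' `abundance.tsv`, `mirnas.fa`, `log2fc.tsv` and `truth.tsv`, all in the
#' plain-text formats the package's own readers consume. Runs with the same
#' seed produce byte-identical files.
#'
#' @param params A [simulation_params] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the `simulation` object and file paths.
#' @export
simulate_dataset <- function(params = simulation_params(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_reference(params)
  tracks <- simulate_coverage(sim)
  ab <- simulate_abundance(sim)
  fc <- simulate_transfection(sim)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    bedgraph = file.path(dir, sprintf("coverage_rep%d.bedgraph",
                                      seq_along(tracks))),
    abundance = file.path(dir, "abundance.tsv"),
    mirnas = file.path(dir, "mirnas.fa"),
    log2fc = file.path(dir, "log2fc.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_fasta(stats::setNames(as.character(sim$bundle$genome),
                              names(sim$bundle$genome)), paths$genome)
  write_gtf(sim$bundle$models, paths$gtf)
  for (k in seq_along(tracks)) write_bedgraph(tracks[[k]], paths$bedgraph[k])
  write_abundance(ab, paths$abundance)
  writeLines(c(paste0(">", sim$mirnas$mirna_id),
               chartr("T", "U", sim$mirnas$seq)), paths$mirnas)
  utils::write.table(fc, paths$log2fc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(sim = sim, tracks = tracks, abundance = ab, fc = fc,
                 paths = paths))
}
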