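#' Run the full reannotation / prediction / benchmark pipeline
#'
#' End-to-end closure over in-memory objects: merge replicate coverage,
#' reannotate distal 3'-UTR ends, predict canonical seed sites under the
#' baseline and reannotated models, filter by expression, compare the two
#' prediction sets, and benchmark the derived transcript groups against a
#' fold-change table with one-sided KS tests.
#'
#' @param bundle A `reference_bundle` (genome + baseline models).
#' @param tracks A `coverage_track` or list of replicate tracks.
#' @param abundance Abundance table (see [read_abundance]).
#' @param mirnas miRNA table (see [read_mirna_fasta]).
#' @param fc Fold-change table with `transcript_id` and `log2fc`, or `NULL`
#'   to skip the benchmark.
#' @param params [reannotation_params].
#' @param tpm_threshold Expression-filter threshold (TPM, inclusive).
#' @return A list: `reannotation` (report + revised models), `baseline`,
#'   `revised`, `filtered` (prediction sets), `comparison`
#'   (`comparison_stats`), `groups`, `benchmark` (`benchmark_result` or
#'   `NULL`).
#' @export
run_pipeline <- function(bundle, tracks, abundance, mirnas, fc = NULL,
                         params = reannotation_params(),
                         tpm_threshold = 0.1) {
  re <- reannotate(bundle$models, tracks, abundance, params,
                   chrom_lengths = bundle$chrom_lengths)
  baseline <- predict_targets(bundle, bundle$models, mirnas,
                              annotation_label = "baseline")
  revised <- predict_targets(bundle, re$models, mirnas,
                             annotation_label = "reannotated")
  filtered <- filter_by_expression(baseline, abundance, tpm_threshold)
  comparison <- compare_annotation_sets(baseline, revised,
                                        bundle$models, re$models)
  groups <- assign_groups(bundle$models, baseline, filtered, revised)
  bench <- NULL
  if (!is.null(fc)) {
    pairs <- list(c("seed_target", "non_target"))
    if ("filtered_target" %in% groups$group)
      pairs <- c(pairs, list(c("filtered_target", "non_target")))
    if ("removed_target" %in% groups$group)
      pairs <- c(pairs, list(c("removed_target", "non_target")))
    if ("gained_target" %in% groups$group)
      pairs <- c(pairs, list(c("gained_target", "non_target")))
    bench <- benchmark_predictions(fc, groups, pairs)
  }
  list(reannotation = re, baseline = baseline, revised = revised,
       filtered = filtered, comparison = comparison, groups = groups,
       benchmark = bench)
}
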