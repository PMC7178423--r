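# Transcripts-per-million: rate_i = count_i / eff_length_i,
# tpm_i = 1e6 * rate_i / sum_j rate_j. TPM over a sample sums to 1e6 and is
# invariant to uniform rescaling of the counts.

#' Compute TPM from estimated counts and effective lengths
#'
#' @param records A data.frame with columns `transcript_id`, `est_count`
#'   (fragments, >= 0) and `eff_length` (bases, > 0).
#' @return The input with a `tpm` column appended; TPM sums to 1e6.
#' @export
compute_tpm <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("transcript_id", "est_count", "eff_length") %in% names(records)))
  if (any(records$eff_length <= 0))
    stop("effective lengths must be positive", call. = FALSE)
  if (any(records$est_count < 0))
    stop("estimated counts must be non-negative", call. = FALSE)
  if (all(records$est_count == 0))
    stop("all counts are zero: TPM is undefined", call. = FALSE)
  rate <- records$est_count / records$eff_length
  records$tpm <- 1e6 * rate / sum(rate)
  records
}

#' Read a transcript abundance table
#'
#' Tab-separated with a header; requires `transcript_id` and `tpm` columns
#' (`est_count` and `eff_length` are optional). Duplicate transcript ids are
#' rejected.
#'
#' @param path Path to a TSV file.
#' @return A data.frame of class `abundance_table`.
#' @export
read_abundance <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "tpm")
  if (!all(need %in% names(tab)))
    stop(sprintf("abundance table lacks required column(s): %s",
                 paste(setdiff(need, names(tab)), collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(tab$transcript_id))
    stop("abundance table contains duplicate transcript ids", call. = FALSE)
  if (any(!is.finite(tab$tpm)) || any(tab$tpm < 0))
    stop("TPM values must be finite and non-negative", call. = FALSE)
  class(tab) <- c("abundance_table", "data.frame")
  tab
}

#' Write an abundance table as TSV
#' @param abundance A data.frame with at least `transcript_id` and `tpm`.
#' @param path Output path.
#' @export
write_abundance <- function(abundance, path) {
  utils::write.table(abundance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Look up TPM values for transcripts
#'
#' Transcripts absent from the table default to TPM 0 (so they fail every
#' expression gate); the number of missing lookups is reported via a warning
#' when `warn = TRUE`.
#'
#' @param abundance A data.frame with `transcript_id` and `tpm` columns, a
#'   named numeric vector, or `NULL` (all zeros).
#' @param ids Character vector of transcript ids.
#' @param warn Emit a warning counting unknown transcripts?
#' @return Named numeric vector of TPM values, one per id.
#' @export
tpm_lookup <- function(abundance, ids, warn = TRUE) {
  if (is.null(abundance)) return(stats::setNames(numeric(length(ids)), ids))
  if (is.data.frame(abundance)) {
    v <- stats::setNames(abundance$tpm, abundance$transcript_id)
  } else {
    stopifnot(is.numeric(abundance), !is.null(names(abundance)))
    v <- abundance
  }
  out <- v[ids]
  miss <- is.na(out)
  if (any(miss) && warn)
    warning(sprintf("%d transcript(s) absent from abundance table; TPM set to 0",
                    sum(miss)), call. = FALSE)
  out[miss] <- 0
  stats::setNames(as.numeric(out), ids)
}
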