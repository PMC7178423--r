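# Per-base mean coverage as sorted non-overlapping value intervals per
# chromosome (0-based half-open). Bases absent from the table have value 0,
# matching the semantics of bedgraph emitted by genome-coverage tools.

#' Construct a coverage track
#'
#' @param x A data.frame with columns `chrom`, `start`, `end`, `value`, or a
#'   named list of per-chromosome data.frames with `start`, `end`, `value`.
#' @return An object of class `coverage_track`: a named list of sorted,
#'   non-overlapping interval tables.
#' @export
coverage_track <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
    x <- split(x[c("start", "end", "value")], x$chrom)
  }
  out <- lapply(x, function(d) {
    d <- data.frame(start = as.numeric(d$start), end = as.numeric(d$end),
                    value = as.numeric(d$value))
    d <- d[order(d$start), , drop = FALSE]
    if (any(d$end <= d$start)) stop("empty or inverted coverage interval", call. = FALSE)
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      stop("overlapping coverage intervals", call. = FALSE)
    if (any(d$value < 0)) stop("negative coverage value", call. = FALSE)
    rownames(d) <- NULL
    d
  })
  structure(out, class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s), %d interval(s)\n",
              length(x), sum(vapply(x, nrow, 0L))))
  invisible(x)
}

# drop zero-value intervals, merge adjacent equal-value neighbours
coalesce_track <- function(track) {
  out <- lapply(unclass(track), function(d) {
    d <- d[d$value > 0, , drop = FALSE]
    if (nrow(d) <= 1L) { rownames(d) <- NULL; return(d) }
    keep_new <- c(TRUE, !(d$start[-1L] == d$end[-nrow(d)] &
                            d$value[-1L] == d$value[-nrow(d)]))
    grp <- cumsum(keep_new)
    data.frame(start = tapply(d$start, grp, min),
               end = tapply(d$end, grp, max),
               value = d$value[keep_new], row.names = NULL)
  })
  structure(out[vapply(out, nrow, 0L) > 0L], class = "coverage_track")
}

#' Read a bedgraph file into a coverage track
#'
#' Four tab-separated columns (chrom, start, end, value), 0-based half-open;
#' `track` header lines and `#` comments are skipped.
#'
#' @param path Path to a bedgraph file.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) return(coverage_track(list()))
  tab <- utils::read.table(text = lines, sep = "\t",
                           col.names = c("chrom", "start", "end", "value"),
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric"))
  coverage_track(tab)
}

#' Write a coverage track as bedgraph
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  lines <- unlist(lapply(names(track), function(chrom) {
    d <- track[[chrom]]
    sprintf("%s\t%s\t%s\t%s", chrom,
            format(d$start, scientific = FALSE, trim = TRUE),
            format(d$end, scientific = FALSE, trim = TRUE),
            vapply(d$value, function(v)
              format(v, scientific = FALSE, trim = TRUE, digits = 17L), ""))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Per-base coverage values over a genomic window
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name; chromosomes absent from the track are
#'   treated as uniformly zero.
#' @param start,end 0-based half-open window.
#' @return Numeric vector of length `end - start`.
#' @export
track_values <- function(track, chrom, start, end) {
  n <- end - start
  if (n <= 0L) return(numeric(0L))
  d <- track[[chrom]]
  if (is.null(d) || nrow(d) == 0L) return(numeric(n))
  pos <- seq.int(start, end - 1L)
  idx <- findInterval(pos, d$start)
  val <- numeric(n)
  hit <- idx >= 1L
  hit[hit] <- pos[hit] < d$end[idx[hit]]
  val[hit] <- d$value[idx[hit]]
  val
}

#' Merge replicate coverage tracks into a mean track
#'
#' The output value at every base is the arithmetic mean of the input values
#' at that base (bases absent from a track count as 0). Output intervals are
#' the atomic intervals of the union of input breakpoints, with equal-value
#' neighbours coalesced and zero-value intervals dropped.
#'
#' @param tracks A list of `coverage_track` objects over the same chromosome
#'   namespace (a single track is returned coalesced).
#' @return A `coverage_track`.
#' @export
merge_replicates <- function(tracks) {
  if (length(tracks) == 0L)
    stop("merge_replicates() needs at least one coverage track", call. = FALSE)
  chroms <- unique(unlist(lapply(tracks, names)))
  n <- length(tracks)
  out <- lapply(chroms, function(chrom) {
    ds <- lapply(tracks, function(t) t[[chrom]])
    ds <- Filter(Negate(is.null), ds)
    bps <- sort(unique(unlist(lapply(ds, function(d) c(d$start, d$end)))))
    if (length(bps) < 2L) return(data.frame(start = numeric(), end = numeric(),
                                            value = numeric()))
    a_start <- bps[-length(bps)]
    a_end <- bps[-1L]
    total <- numeric(length(a_start))
    for (d in ds) {
      idx <- findInterval(a_start, d$start)
      hit <- idx >= 1L
      hit[hit] <- a_start[hit] < d$end[idx[hit]]
      total[hit] <- total[hit] + d$value[idx[hit]]
    }
    data.frame(start = a_start, end = a_end, value = total / n)
  })
  coalesce_track(coverage_track(stats::setNames(out, chroms)))
}
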