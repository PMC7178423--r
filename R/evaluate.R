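# Benchmarking prediction sets against miRNA-transfection log2 fold changes:
# cumulative distributions per transcript group and one-sided two-sample
# Kolmogorov-Smirnov tests. The first sample of a comparison is hypothesized
# stochastically smaller (more repressed), i.e. its CDF lies above; the
# statistic uses signed CDF differences, and the approximate p-value is the
# one-sided asymptotic formula min(1, exp(-2 d^2 n1 n2 / (n1 + n2))).

#' Empirical CDF as a step-function table
#'
#' @param values Numeric vector (finite, at least one value).
#' @return Data.frame with columns `x` (sorted unique support) and `F`
#'   (right-continuous cumulative fractions reaching 1 at the maximum).
#' @export
ecdf_table <- function(values) {
  if (length(values) == 0L) stop("ecdf of an empty sample", call. = FALSE)
  if (any(!is.finite(values))) stop("ecdf requires finite values", call. = FALSE)
  f <- stats::ecdf(values)
  x <- sort(unique(values))
  data.frame(x = x, F = f(x))
}

# one-sided statistic D+ = max over the pooled support of (F1(x) - F2(x))
ks_dplus <- function(x, y) {
  sx <- sort(x); sy <- sort(y)
  z <- sort(unique(c(sx, sy)))
  f1 <- findInterval(z, sx) / length(sx)
  f2 <- findInterval(z, sy) / length(sy)
  max(f1 - f2)
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests whether the first sample is stochastically smaller (more repressed)
#' than the reference: `d` is the supremum over the pooled support of
#' `F_more(x) - F_ref(x)`, and the approximate p-value is the one-sided
#' asymptotic tail `min(1, exp(-2 d^2 n1 n2 / (n1 + n2)))`. A permutation
#' p-value is available as a cross-check.
#'
#' @param more_repressed Numeric sample hypothesized to have smaller values.
#' @param reference Numeric reference sample.
#' @param p_method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm Number of label permutations when `p_method` is
#'   `"permutation"`.
#' @return An object of class `ks_result`: list with `d`, `p_approx`, `n1`,
#'   `n2`, `direction`, `p_method`.
#' @export
ks_one_sided <- function(more_repressed, reference,
                         p_method = c("asymptotic", "permutation"),
                         n_perm = 1000L) {
  p_method <- match.arg(p_method)
  if (length(more_repressed) == 0L || length(reference) == 0L)
    stop("both samples must contain at least one value", call. = FALSE)
  if (any(!is.finite(more_repressed)) || any(!is.finite(reference)))
    stop("samples must be finite", call. = FALSE)
  n1 <- length(more_repressed)
  n2 <- length(reference)
  d <- ks_dplus(more_repressed, reference)
  if (p_method == "asymptotic") {
    p <- min(1, exp(-2 * d^2 * n1 * n2 / (n1 + n2)))
  } else {
    pool <- c(more_repressed, reference)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n1 + n2, n1)
      if (ks_dplus(pool[idx], pool[-idx]) >= d) exceed <- exceed + 1L
    }
    p <- (1L + exceed) / (n_perm + 1L)
  }
  structure(list(d = d, p_approx = p, n1 = n1, n2 = n2,
                 direction = "first sample more repressed",
                 p_method = p_method),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> one-sided two-sample KS: D+ = %.4f, p = %.3g (%s; n1 = %d, n2 = %d)\n",
              x$d, x$p_approx, x$p_method, x$n1, x$n2))
  invisible(x)
}

#' Benchmark transcript groups against transfection fold changes
#'
#' Joins a group assignment to a log2 fold-change table (transcripts missing
#' from the table are dropped, with a message counting them), emits
#' per-group sizes and CDF tables, and runs the requested one-sided KS
#' comparisons (first group of each pair hypothesized more repressed).
#'
#' @param fc Data.frame with `transcript_id` and `log2fc` columns; duplicate
#'   ids are rejected, values must be finite.
#' @param groups Data.frame with `transcript_id` and `group` columns
#'   (long format; a transcript may belong to several groups).
#' @param comparisons List of length-2 character vectors
#'   `c(more_repressed_group, reference_group)`.
#' @return An object of class `benchmark_result`: `results` (one row per
#'   comparison with `d`, `p_approx`, `n1`, `n2`), `sizes` (named group
#'   sizes after the join), `cdf` (long table: `group`, `x`, `F`),
#'   `n_dropped` (transcripts absent from `fc`).
#' @export
benchmark_predictions <- function(fc, groups, comparisons) {
  stopifnot(all(c("transcript_id", "log2fc") %in% names(fc)),
            all(c("transcript_id", "group") %in% names(groups)))
  if (anyDuplicated(fc$transcript_id))
    stop("fold-change table contains duplicate transcript ids", call. = FALSE)
  if (any(!is.finite(fc$log2fc)))
    stop("fold-change values must be finite", call. = FALSE)
  fcv <- stats::setNames(fc$log2fc, fc$transcript_id)
  known <- groups$transcript_id %in% names(fcv)
  n_dropped <- sum(!known)
  if (n_dropped > 0L)
    message(sprintf("%d group member(s) absent from the fold-change table were dropped",
                    n_dropped))
  groups <- groups[known, , drop = FALSE]
  values <- split(unname(fcv[groups$transcript_id]), groups$group)
  sizes <- vapply(values, length, 0L)

  cdf <- do.call(rbind, lapply(names(values), function(g) {
    cbind(group = g, ecdf_table(values[[g]]))
  }))
  res <- do.call(rbind, lapply(comparisons, function(pair) {
    stopifnot(length(pair) == 2L)
    for (g in pair) {
      if (is.null(values[[g]]) || length(values[[g]]) == 0L)
        stop(sprintf("group '%s' is empty after joining to the fold-change table", g),
             call. = FALSE)
    }
    k <- ks_one_sided(values[[pair[1L]]], values[[pair[2L]]])
    data.frame(more_repressed = pair[1L], reference = pair[2L],
               d = k$d, p_approx = k$p_approx, n1 = k$n1, n2 = k$n2,
               stringsAsFactors = FALSE)
  }))
  structure(list(results = res, sizes = sizes, cdf = cdf,
                 n_dropped = n_dropped),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n  group sizes:",
      paste(sprintf("%s (%d)", names(x$sizes), x$sizes), collapse = ", "), "\n")
  print(x$results)
  invisible(x)
}

#' Derive benchmark groups from prediction sets
#'
#' Produces a long-format group assignment over protein-coding transcripts
#' with an annotated 3'-UTR: `seed_target` (at least one baseline site),
#' `non_target` (no baseline site), `filtered_target` (site surviving the
#' expression filter), `gained_target` (targets only under the revised
#' annotation) and `removed_target` (targets only under the baseline
#' annotation).
#'
#' @param models Baseline model list.
#' @param baseline Prediction set from the baseline annotation.
#' @param filtered Optional expression-filtered prediction set.
#' @param revised Optional prediction set from a revised annotation.
#' @return Data.frame with `transcript_id` and `group`.
#' @export
assign_groups <- function(models, baseline, filtered = NULL, revised = NULL) {
  coding <- Filter(function(m) m$biotype == "protein_coding" &&
                     nrow(m$utr3) > 0L, models)
  ids <- vapply(coding, function(m) m$transcript_id, "")
  btar <- unique(baseline$transcript_id)
  grp <- function(members, g) {
    data.frame(transcript_id = members, group = rep(g, length(members)),
               stringsAsFactors = FALSE)
  }
  out <- list(
    grp(intersect(ids, btar), "seed_target"),
    grp(setdiff(ids, btar), "non_target")
  )
  if (!is.null(filtered))
    out <- c(out, list(grp(intersect(ids, unique(filtered$transcript_id)),
                           "filtered_target")))
  if (!is.null(revised)) {
    rtar <- unique(revised$transcript_id)
    out <- c(out, list(grp(setdiff(rtar, btar), "gained_target"),
                       grp(setdiff(btar, rtar), "removed_target")))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot cumulative log2 fold-change distributions per group
#'
#' @param bench A `benchmark_result`.
#' @return A ggplot object with one CDF step curve per group.
#' @export
plot_benchmark_cdf <- function(bench) {
  d <- bench$cdf
  ggplot2::ggplot(d, ggplot2::aes(x = x, y = F, colour = group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = "cumulative fraction", colour = "group") +
    ggplot2::theme_minimal()
}
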