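# Independent oracles, implemented with deliberately naive bookkeeping so
# they share no code path with the package implementations.

# per-base complement / reverse complement
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# classify every UTR window by direct (vectorised) substring comparison,
# with the canonical precedence 8mer > 7mer-m8 > 7mer-A1 > 6mer
oracle_seed_scan <- function(utr, mirna) {
  m <- chartr("U", "T", toupper(mirna))
  s6 <- oracle_revcomp(substr(m, 2, 7))
  s7 <- oracle_revcomp(substr(m, 2, 8))
  L <- nchar(utr)
  if (L < 6) return(data.frame(site_type = character(), utr_offset = integer(),
                               match_len = integer()))
  starts <- seq_len(L - 5)                     # 1-based S6 starts
  hit <- substring(utr, starts, starts + 5) == s6
  starts <- starts[hit]
  out <- lapply(starts, function(st) {
    has_m8 <- st >= 2 && substring(utr, st - 1, st + 5) == s7
    has_a1 <- st + 6 <= L && substring(utr, st + 6, st + 6) == "A"
    if (has_m8 && has_a1) {
      data.frame(site_type = "8mer", utr_offset = st - 2L, match_len = 8L)
    } else if (has_m8) {
      data.frame(site_type = "7mer-m8", utr_offset = st - 2L, match_len = 7L)
    } else if (has_a1) {
      data.frame(site_type = "7mer-A1", utr_offset = st - 1L, match_len = 7L)
    } else {
      data.frame(site_type = "6mer", utr_offset = st - 1L, match_len = 6L)
    }
  })
  if (length(out) == 0)
    return(data.frame(site_type = character(), utr_offset = integer(),
                      match_len = integer()))
  do.call(rbind, out)
}

# per-base mean coverage over [0, len): brute force over a dense vector
oracle_mean_coverage <- function(tracks, chrom, len) {
  acc <- matrix(0, nrow = length(tracks), ncol = len)
  for (k in seq_along(tracks)) {
    d <- tracks[[k]][[chrom]]
    if (is.null(d)) next
    for (i in seq_len(nrow(d))) {
      lo <- d$start[i]; hi <- min(d$end[i], len)
      if (hi > lo) acc[k, (lo + 1):hi] <- d$value[i]
    }
  }
  colMeans(acc)
}

# dense per-base values of a single track
oracle_track_vector <- function(track, chrom, len) {
  oracle_mean_coverage(list(track), chrom, len)
}

# one-sided KS D+ by looping over every pooled point
oracle_ks_dplus <- function(x, y) {
  z <- c(x, y)
  max(vapply(z, function(t) mean(x <= t) - mean(y <= t), 0))
}

# random sparse coverage track over one chromosome of given length
random_track <- function(chrom_len, n_iv = 8, max_val = 10) {
  bp <- sort(sample(0:chrom_len, 2 * n_iv))
  st <- bp[seq(1, length(bp), by = 2)]
  en <- bp[seq(2, length(bp), by = 2)]
  keep <- en > st
  coverage_track(list(chr1 = data.frame(
    start = st[keep], end = en[keep],
    value = sample(0:max_val, sum(keep), replace = TRUE))))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

random_mirna <- function(len = 21) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# canonical form of a coverage track for equality tests
track_canonical <- function(track) {
  out <- lapply(unclass(track), function(d) {
    d <- d[d$value > 0, , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  out[order(names(out))]
}
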