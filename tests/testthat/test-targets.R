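MIR <- "UACCCUGUAGAUCCGAAUUUGUG"  # seed CCCUGU -> S6 = CAGGGT on the mRNA

test_that("canonical site taxonomy classifies each seed occurrence once", {
  # 8mer: S7 extension plus the 3' A
  s <- scan_seed_sites("GGACAGGGTAGG", MIR)
  expect_equal(s$site_type, "8mer")
  expect_equal(s$utr_offset, 2L)
  expect_equal(s$match_len, 8L)

  # no seed complement, no site
  expect_equal(nrow(scan_seed_sites("CCCCCCCC", MIR)), 0L)

  # boundary fall-back: no 5' base available, 3' base not A -> 6mer
  s <- scan_seed_sites("CAGGGTG", MIR)
  expect_equal(s$site_type, "6mer")
  expect_equal(s$utr_offset, 0L)

  # 7mer-m8 (extension only) and 7mer-A1 (A only)
  expect_equal(scan_seed_sites("GACAGGGTG", MIR)$site_type, "7mer-m8")
  expect_equal(scan_seed_sites("GGCAGGGTAGG", MIR)$site_type, "7mer-A1")

  # N never matches
  expect_equal(nrow(scan_seed_sites("GGACAGNGTAGG", MIR)), 0L)

  expect_error(scan_seed_sites("ACGTACGT", "UACCCUG"), "at least 8")
})

test_that("scanner agrees with the window-classification oracle on random pairs", {
  set.seed(51)
  for (rep in 1:150) {
    mir <- random_mirna(sample(19:23, 1))
    utr <- random_dna(sample(30:400, 1))
    if (runif(1) < 0.5) {  # plant a site so hits are common
      s8 <- paste0(oracle_revcomp(chartr("U", "T", substr(mir, 2, 8))), "A")
      pos <- sample(nchar(utr) - 10, 1)
      substr(utr, pos, pos + 7) <- s8
    }
    got <- scan_seed_sites(utr, mir)
    exp <- oracle_seed_scan(utr, mir)
    expect_equal(got[c("site_type", "utr_offset", "match_len")],
                 exp, ignore_attr = TRUE,
                 info = paste("rep", rep))
  }
})

test_that("prediction maps sites to genomic coordinates consistently on both strands", {
  set.seed(61)
  mirnas <- data.frame(mirna_id = "m1", seq = normalize_mirna(MIR))
  s8 <- paste0(oracle_revcomp(chartr("U", "T", substr(MIR, 2, 8))), "A")

  # plus strand: plant the 8mer at UTR offset 40
  g <- random_dna(2000)
  substr(g, 641, 648) <- s8  # UTR starts at 0-based 600
  bp <- reference_bundle(c(chr1 = g),
                         list(TXP = fixture_plus_model(term = c(500L, 1000L),
                                                       utr_start = 600L)))
  pp <- predict_targets(bp, mirnas = mirnas)
  i <- which(pp$site_type == "8mer")
  expect_true(length(i) >= 1)
  expect_equal(pp$utr_offset[i[1]], 40L)
  expect_equal(pp$genomic_start[i[1]], 640L)
  expect_equal(pp$genomic_end[i[1]], 648L)
  # re-extracting the genomic span reproduces the matched bases
  expect_equal(substr(g, pp$genomic_start[i[1]] + 1, pp$genomic_end[i[1]]), s8)

  # minus strand: plant at UTR offset 40 from the 5' edge (genomic end 1400)
  g2 <- random_dna(2000)
  substr(g2, 1400 - 40 - 8 + 1, 1400 - 40) <- oracle_revcomp(s8)
  bm <- reference_bundle(c(chr1 = g2),
                         list(TXM = fixture_minus_model(term = c(1100L, 1500L),
                                                        cds = c(1700L, 1900L),
                                                        utr_end = 1400L)))
  pm <- predict_targets(bm, mirnas = mirnas)
  j <- which(pm$site_type == "8mer")
  expect_true(length(j) >= 1)
  expect_equal(pm$utr_offset[j[1]], 40L)
  span <- substr(g2, pm$genomic_start[j[1]] + 1, pm$genomic_end[j[1]])
  expect_equal(oracle_revcomp(span), s8)

  # per-UTR re-scan of the extracted sequence reproduces every site
  for (pred in list(list(b = bp, p = pp), list(b = bm, p = pm))) {
    useq <- extract_utr_sequence(pred$b, pred$b$models[[1]])
    rescan <- scan_seed_sites(useq, MIR)
    expect_equal(sort(pred$p$utr_offset), sort(rescan$utr_offset))
  }
})

test_that("transcripts with no UTR contribute nothing; empty miRNA set gives empty predictions", {
  b <- fixture_bundle()
  b$models$NOUTR <- transcript_model("NOUTR", "chr1", "+", intervals(0L, 50L))
  p <- predict_targets(b, mirnas = data.frame(mirna_id = character(),
                                              seq = character()))
  expect_equal(nrow(p), 0L)
  expect_warning(
    predict_targets(b, mirnas = data.frame(mirna_id = c("m", "m"),
                                           seq = c(normalize_mirna(MIR),
                                                   normalize_mirna(MIR)))),
    "duplicate")
})

test_that("expression filtering keeps exactly transcripts at or above threshold and is monotone", {
  preds <- data.frame(transcript_id = rep(c("a", "b", "c"), each = 2),
                      mirna_id = "m", site_type = "6mer",
                      utr_offset = rep(c(1L, 10L), 3), match_len = 6L,
                      chrom = "chr1", genomic_start = 1:6,
                      genomic_end = 7:12, strand = "+")
  tpm <- c(a = 0.05, b = 0.1, c = 4)
  f <- filter_by_expression(preds, tpm, 0.1)
  expect_setequal(unique(f$transcript_id), c("b", "c"))  # 0.1 is inclusive
  expect_equal(attr(f, "removed_transcripts"), "a")
  expect_equal(nrow(filter_by_expression(preds, tpm, 0)), nrow(preds))
  expect_error(filter_by_expression(preds, tpm, -1), "non-negative")

  set.seed(71)
  for (rep in 1:30) {
    ids <- sprintf("t%02d", 1:20)
    tpm <- setNames(stats::rlnorm(20, 0, 2), ids)
    preds <- data.frame(transcript_id = sample(ids, 50, replace = TRUE),
                        mirna_id = "m", site_type = "6mer",
                        utr_offset = 1L, match_len = 6L, chrom = "chr1",
                        genomic_start = 1L, genomic_end = 7L, strand = "+")
    t1 <- sort(stats::runif(2, 0, 5))
    lo <- filter_by_expression(preds, tpm, t1[1])
    hi <- filter_by_expression(preds, tpm, t1[2])
    expect_true(all(hi$transcript_id %in% lo$transcript_id))
    expect_setequal(unique(lo$transcript_id),
                    intersect(unique(preds$transcript_id),
                              names(tpm)[tpm >= t1[1]]))
  }
})

test_that("annotation-set comparison counts gains and losses by genomic identity", {
  mk_pred <- function(n, label) {
    data.frame(transcript_id = sprintf("t%02d", 1:n), mirna_id = "m",
               site_type = "6mer", utr_offset = 1L, match_len = 6L,
               chrom = "chr1", genomic_start = 100L + 10L * (1:n),
               genomic_end = 106L + 10L * (1:n), strand = "+")
  }
  base <- mk_pred(10)
  revised <- rbind(base[-(1:2), ],
                   data.frame(transcript_id = "t99", mirna_id = "m",
                              site_type = "8mer", utr_offset = 5L,
                              match_len = 8L, chrom = "chr1",
                              genomic_start = 900L, genomic_end = 908L,
                              strand = "+"))
  models <- lapply(sprintf("t%02d", 1:10), function(id)
    transcript_model(id, "chr1", "+", intervals(0L, 1000L),
                     utr3 = intervals(100L, 400L)))
  names(models) <- sprintf("t%02d", 1:10)
  st <- compare_annotation_sets(base, revised, models, models)
  expect_equal(st$sites_lost, 2L)
  expect_equal(st$sites_gained, 1L)
  expect_equal(st$pct_lost, 20)
  expect_equal(st$pct_gained, 10)
  # gained and lost are disjoint by key
  expect_length(intersect(
    with(st$gained, paste(transcript_id, genomic_start)),
    with(st$lost, paste(transcript_id, genomic_start))), 0L)

  # identical sets: all zero
  st0 <- compare_annotation_sets(base, base, models, models)
  expect_equal(st0$sites_gained + st0$sites_lost, 0L)
  expect_equal(st0$bases_added + st0$bases_removed, 0L)
  expect_equal(st0$fraction_utrs_affected, 0)

  # zero baseline sites: percentages undefined, no error
  empty <- base[0, ]
  stna <- compare_annotation_sets(empty, revised, models, models)
  expect_true(is.na(stna$pct_gained) && is.na(stna$pct_lost))
})

test_that("an extension that adds a planted site is reported as gained with its base delta", {
  set.seed(81)
  mirnas <- data.frame(mirna_id = "m1", seq = normalize_mirna(MIR))
  s8 <- paste0(oracle_revcomp(chartr("U", "T", substr(MIR, 2, 8))), "A")
  g <- random_dna(3000)
  substr(g, 1101, 1108) <- s8  # inside the 400 nt extension
  base_m <- list(TX = fixture_plus_model("TX", term = c(500L, 1000L),
                                         utr_start = 600L))
  ext_m <- base_m
  ext_m$TX$utr3$end <- 1400L
  ext_m$TX$exons$end[2] <- 1400L
  b <- reference_bundle(c(chr1 = g), base_m)
  p_base <- predict_targets(b, base_m, mirnas)
  p_ext <- predict_targets(b, ext_m, mirnas)
  st <- compare_annotation_sets(p_base, p_ext, base_m, ext_m)
  expect_true(any(st$gained$site_type == "8mer" &
                    st$gained$genomic_start == 1100L))
  expect_equal(st$bases_added, 400L)
})
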