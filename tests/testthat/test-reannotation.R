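params_default <- reannotation_params()

# helper for constructing truncation proposals
reann_trunc <- function(id, old, new) {
  data.frame(transcript_id = id, old_distal_end = old, new_distal_end = new,
             outcome = "truncated", skip_reason = "none",
             bases_delta = as.integer(new - old), stringsAsFactors = FALSE)
}

test_that("coverage matching the annotation exactly leaves the end unchanged", {
  m <- fixture_plus_model(term = c(500L, 1600L), utr_start = 600L)
  tr <- uniform_track(100L, 1600L, 20)  # covers transcript, 0 beyond UTR end
  res <- propose_distal_end(m, tr, params_default)
  expect_equal(res$outcome, "unchanged")
  expect_equal(res$new_distal_end, 1600L)
  expect_equal(res$bases_delta, 0L)
})

test_that("coverage running past the annotated end proposes an extension", {
  m <- fixture_plus_model(term = c(500L, 1600L), utr_start = 600L)  # 1000 nt UTR
  tr <- uniform_track(100L, 2000L, 20)  # 400 nt beyond the annotation
  res <- propose_distal_end(m, tr, params_default)
  expect_equal(res$outcome, "extended")
  expect_equal(res$bases_delta, 400L, tolerance = 0)  # noise-free: exact
  expect_equal(res$new_distal_end, 2000L)
})

test_that("coverage stopping inside the annotation proposes a truncation", {
  m <- fixture_plus_model(term = c(500L, 1600L), utr_start = 600L)
  tr <- uniform_track(100L, 1100L, 20)  # covers only first 500 nt of the UTR
  res <- propose_distal_end(m, tr, params_default)
  expect_equal(res$outcome, "truncated")
  expect_equal(res$bases_delta, -500L)
  expect_equal(res$new_distal_end, 1100L)
})

test_that("zero proximal coverage and ineligible UTRs are skips, not errors", {
  m <- fixture_plus_model()
  res <- propose_distal_end(m, coverage_track(list()), params_default)
  expect_equal(res$outcome, "skipped")
  expect_equal(res$skip_reason, "no_coverage")

  m_multi <- transcript_model("MM", "chr1", "+",
                              exons = intervals(c(0L, 300L), c(200L, 900L)),
                              utr3 = intervals(c(100L, 300L), c(200L, 900L)))
  res <- propose_distal_end(m_multi, uniform_track(0L, 900L, 20), params_default)
  expect_equal(res$skip_reason, "multi_exon_utr")

  m_none <- transcript_model("MN", "chr1", "+", intervals(0L, 200L))
  res <- propose_distal_end(m_none, uniform_track(0L, 900L, 20), params_default)
  expect_equal(res$skip_reason, "no_utr_annotation")
})

test_that("the detector is strand-symmetric on mirrored fixtures", {
  L <- 10000L
  for (true_delta in c(-420L, 0L, 380L)) {
    # plus strand: UTR [600, 1600), coverage to 1600 + delta
    mp <- fixture_plus_model(term = c(500L, 1600L), utr_start = 600L)
    tp <- uniform_track(100L, 1600L + true_delta, 20)
    rp <- propose_distal_end(mp, tp, params_default)

    # mirrored minus strand: positions x -> L - x
    mm <- transcript_model("TXM", "chr1", "-",
                           exons = intervals(c(L - 1600L, L - 300L),
                                             c(L - 500L, L - 100L)),
                           utr3 = intervals(L - 1600L, L - 600L))
    tm <- uniform_track(L - (1600L + true_delta), L - 100L, 20)
    rm <- propose_distal_end(mm, tm, params_default)

    expect_equal(rm$outcome, rp$outcome, info = paste("delta", true_delta))
    expect_equal(rm$bases_delta, rp$bases_delta)
    if (rp$outcome != "skipped")
      expect_equal(rm$new_distal_end, L - rp$new_distal_end)
  }
})

test_that("scaling coverage down never converts a truncation into an extension", {
  m <- fixture_plus_model(term = c(500L, 1600L), utr_start = 600L)
  base_depth <- 20
  for (edge in c(1100L, 1600L)) {  # truncation and exact-match fixtures
    deltas <- sapply(c(1, 0.5, 0.2, 0.05), function(s) {
      tr <- uniform_track(100L, edge, base_depth * s)
      propose_distal_end(m, tr, params_default)$bases_delta
    })
    expect_true(all(diff(deltas) <= 0))
    expect_true(all(deltas <= 0))
  }
})

test_that("breakpoints planted in noisy simulated coverage are recovered", {
  p <- simulation_params(n_transcripts = 30,
                         breakpoint_delta = c(250L, -250L, 450L, -450L, 0L),
                         frac_minus_strand = 0.5, noise = TRUE, seed = 404)
  sim <- simulate_reference(p)
  merged <- merge_replicates(simulate_coverage(sim))
  err <- vapply(seq_len(nrow(sim$truth)), function(i) {
    res <- propose_distal_end(sim$bundle$models[[i]], merged, params_default,
                              chrom_length = sim$bundle$chrom_lengths[[1]])
    res$new_distal_end - sim$truth$true_distal_end[i]
  }, 0)
  expect_true(mean(abs(err) <= 100) >= 0.9)
})

test_that("integration honours the eligibility rules and the TPM gate", {
  models <- list(
    multi = transcript_model("multi", "chr1", "+",
                             exons = intervals(c(0L, 300L), c(200L, 900L)),
                             utr3 = intervals(c(100L, 300L), c(200L, 900L))),
    none = transcript_model("none", "chr1", "+", intervals(1000L, 1400L)),
    low = fixture_plus_model("low", cds = c(2000L, 2200L),
                             term = c(2400L, 3400L), utr_start = 2500L),
    high = fixture_plus_model("high", cds = c(5000L, 5200L),
                              term = c(5400L, 6400L), utr_start = 5500L)
  )
  results <- rbind(
    reann_trunc("multi", 900L, 600L),
    reann_trunc("none", 1400L, 1200L),   # novel-UTR proposal
    reann_trunc("low", 3400L, 2900L),
    reann_trunc("high", 6400L, 5900L)
  )
  tpm <- c(multi = 50, none = 50, low = 2, high = 7)
  out <- apply_reannotations(models, results, tpm, params_default)
  rep <- out$report
  expect_equal(rep$outcome[rep$transcript_id == "multi"], "skipped")
  expect_equal(rep$skip_reason[rep$transcript_id == "multi"], "multi_exon_utr")
  expect_equal(rep$skip_reason[rep$transcript_id == "none"], "no_utr_annotation")
  expect_equal(rep$skip_reason[rep$transcript_id == "low"],
               "low_expression_truncation")
  expect_equal(rep$outcome[rep$transcript_id == "high"], "truncated")

  # applied model: distal edge and terminal exon moved in lockstep
  high <- out$models$high
  expect_equal(high$utr3$end, 5900L)
  expect_equal(max(high$exons$end), 5900L)
  # untouched models unchanged
  expect_equal(out$models$multi$utr3, models$multi$utr3)
  expect_equal(out$models$low$utr3, models$low$utr3)
  # extensions are not gated by expression
  ext <- data.frame(transcript_id = "low", old_distal_end = 3400L,
                    new_distal_end = 3700L, outcome = "extended",
                    skip_reason = "none", bases_delta = 300L)
  out2 <- apply_reannotations(models, ext, tpm, params_default)
  expect_equal(out2$report$outcome, "extended")
  expect_equal(out2$models$low$utr3$end, 3700L)

  expect_error(apply_reannotations(models, reann_trunc("ghost", 1L, 0L), tpm,
                                   params_default),
               "unknown transcript")
})

test_that("integration never moves the 5' edge of any 3'-UTR", {
  p <- simulation_params(n_transcripts = 25, breakpoint_delta = c(300L, -300L),
                         frac_multi_exon_utr = 0.15, frac_no_utr = 0.15,
                         seed = 77)
  sim <- simulate_reference(p)
  out <- reannotate(sim$bundle$models, simulate_coverage(sim),
                    tpm = setNames(sim$truth$tpm, sim$truth$transcript_id),
                    params = params_default,
                    chrom_lengths = sim$bundle$chrom_lengths)
  for (id in names(sim$bundle$models)) {
    before <- sim$bundle$models[[id]]
    after <- out$models[[id]]
    if (nrow(before$utr3) == 0L) {
      expect_equal(nrow(after$utr3), 0L)
    } else if (before$strand == "+") {
      expect_equal(min(after$utr3$start), min(before$utr3$start), info = id)
    } else {
      expect_equal(max(after$utr3$end), max(before$utr3$end), info = id)
    }
  }
})
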