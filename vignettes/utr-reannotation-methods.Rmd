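---
title: "Methods: coverage-driven 3'-UTR reannotation and expression-filtered seed-site prediction"
author: "utrtar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-driven 3'-UTR reannotation and expression-filtered seed-site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrtar)
```

## The problem

MicroRNAs repress mRNAs mainly through short "seed" matches in 3'-UTRs.
Generic seed-match prediction over a reference annotation ignores two facts
about any particular cell type: (i) a transcript that is not expressed there
cannot be repressed, and (ii) alternative cleavage and polyadenylation (APA)
means the 3'-UTR actually present may be longer or shorter than the
annotated one, adding or deleting target sites. `utrtar` addresses both: it
refines annotated distal 3'-UTR ends from bulk RNA-Seq read coverage,
re-predicts canonical seed sites on the refined UTRs, filters predictions by
transcript abundance (TPM), and benchmarks the resulting prediction sets
against miRNA-transfection log2 fold-change data.

All coordinates are 0-based half-open internally; GTF is converted at the
I/O boundary, BED12 and bedgraph are native. This single convention is the
package's main defence against off-by-one errors, and the GTF/BED12/bedgraph
round-trip tests pin it down.

## Distal-end detection

Replicate bedgraph tracks are first merged into a per-base arithmetic-mean
track (bases absent from a file count as zero, matching the semantics of
genome-coverage emitters). For each protein-coding transcript whose 3'-UTR
annotation spans a single interval, the detector:

1. orients a coverage vector 5'→3' over the annotated UTR plus an extension
   margin of `extension_limit` bases (default 5000), clipped at the
   chromosome end and at the nearest same-strand neighbouring gene so an
   extension can never run through a downstream gene;
2. computes a proximal reference coverage $r$ as the mean over the first
   `window_w` bases (default 100) of the annotated UTR; $r = 0$ yields a
   `skipped/no_coverage` record;
3. scans windows of length `window_w` at stride `step` (default 50) outward
   from the UTR start and finds the farthest window whose mean coverage is
   at least $\max(\texttt{min\_cov},\, f\,r)$ with every nearer window also
   passing (`min_cov` defaults to 1 read/base, the fraction $f$ to 0.2);
4. refines the proposed end to single-base resolution by walking from the
   start of that farthest passing window to the first base below the
   threshold.

The refinement step exists because a pure window-granularity detector can
only guarantee recovery to within `window_w` of a breakpoint; the per-base
walk recovers noise-free step functions exactly and, at 20x coverage, fails
on a given base only when a Poisson(20) draw lands below the threshold
(probability about 3e-6), so noisy recovery is typically within a few bases.
Proposals are classified `extended`/`truncated` only when the change exceeds
`min_delta` bases (default 50); ties and smaller changes resolve to
`unchanged`, which keeps the reannotation conservative.

Integration applies four hard rules: multi-interval 3'-UTRs are never
altered; proposals for transcripts without an annotated 3'-UTR (novel UTRs)
are discarded; the 5' edge of a 3'-UTR is never moved; and truncations are
applied only to transcripts with TPM at or above `tpm_truncation_gate`
(default 5), because sporadic coverage on weakly expressed transcripts makes
truncation calls unreliable. Extensions are not expression-gated: the design
reads the truncation gate as a statement about truncation specifically, and
an extension already requires positive distal coverage, which is itself
evidence of expression. When a proposal is applied, the UTR's distal edge
and the terminal exon edge move in lockstep so the UTR stays inside the exon
union.

## Seed-site taxonomy

For a mature miRNA (positions numbered 1-based from the 5' end), let S6 be
the reverse complement of positions 2-7 and S7 the reverse complement of
positions 2-8 (one extra base on the mRNA 5' side). Every S6 occurrence in
the mRNA-sense UTR yields exactly one site, classified with precedence
8mer > 7mer-m8 > 7mer-A1 > 6mer: the 8mer requires both the S7 extension
and an A immediately 3' of the seed match; the 7mer-m8 only the extension;
the 7mer-A1 only the A. `N` never matches, and matches truncated by the UTR
boundary fall back to the type fully contained. The reported offset and
length describe the maximal matched span. Sites are mapped back to genomic
coordinates through the UTR's interval structure, and gain/loss comparisons
between annotation versions key sites by *genomic* position (transcript,
miRNA, type, genomic start, strand) so a UTR length change never relabels an
unchanged site. Context scoring (local AU content, pairing energy,
conservation) is out of scope: the benchmarked grouping is by seed match.

## Expression filtering and TPM

TPM is computed in-house from estimated counts and effective lengths:
$\mathrm{rate}_i = c_i/\ell_i$, $\mathrm{TPM}_i = 10^6\,\mathrm{rate}_i /
\sum_j \mathrm{rate}_j$, so a sample always sums to $10^6$ and the values
are invariant to uniform count rescaling. Quantification itself (alignment
or pseudoalignment) is not reimplemented; any abundance TSV with
`transcript_id` and `tpm` columns is accepted. Transcripts missing from the
table default to TPM 0, which makes them fail every gate — the conservative
choice. The expression filter retains sites on transcripts with TPM >= the
threshold (inclusive; default 0.1) and is monotone: a larger threshold
always yields a subset.

## Benchmarking

Prediction sets are benchmarked against per-transcript log2 fold changes
from miRNA-mimic-versus-control transfection. Transcript groups
(`seed_target`, `non_target`, `filtered_target`, `gained_target`,
`removed_target`) are compared by a one-sided two-sample Kolmogorov–Smirnov
test: with the first group hypothesized more repressed, the statistic is
$D^+ = \sup_x\,[F_1(x) - F_2(x)]$ over the pooled support (signed, not
absolute differences), and the approximate p-value is the one-sided
asymptotic tail $\min\!\big(1, \exp(-2 {D^+}^2 n_1 n_2/(n_1+n_2))\big)$.
This formula is declared normative for the package; a label-permutation
p-value is available as a cross-check and agrees within a factor of two at
$n_1 = n_2 = 100$ for p-values inside the range a finite permutation test
can resolve (a 1000-permutation p cannot lie below 1/1001, so comparisons
are made on null-scale instances). Under the null the rejection rate at
0.05 sits near 5%. Transcripts present in a group but absent from the
fold-change table are dropped, with a count reported, rather than imputed.

## The synthetic generator

`simulate_reference()` lays single- or two-interval-UTR genes along one toy
chromosome with intergenic gaps larger than the extension search limit,
plants distal-end breakpoints (`breakpoint_delta`), 8mer seed sites of one
configurable miRNA, and a log-normal abundance profile normalised to
$10^6$ TPM. Sites can be planted in three places: inside the true UTR
(`retained`; these transcripts are repressed under transfection), beyond a
planted truncation (`decoy`; predicted from the annotation but not
repressed — the removed-target expectation), or inside a planted extension
(`gained`). Coverage is piecewise-constant over exon bodies — with the
terminal exon moved to the true distal end — plus optional per-base Poisson
noise; replicates differ only by a deterministic sub-seed. Fold changes are
Normal(0, σ) for non-targets and Normal(−δ, σ) for true targets, with
defaults δ = 0.5, σ = 0.5 and depth 20 reads/base chosen as typical of a
well-powered transfection experiment and a moderately deep bulk RNA-Seq
library.

What the generator does *not* emulate — splice-aware read placement, GC and
library-prep biases, 3'-UTR isoform mixtures within one sample, and
background repression of non-seed targets — bounds what passing tests show:
they validate the detector's contract (change-point recovery under Poisson
noise), the bookkeeping (coordinates, round trips, gain/loss attribution)
and the statistical machinery, not performance on real libraries. Note that
random background sequence does create genuine seed matches (about one per
4 kb of UTR per miRNA), so simulated "seed target" groups contain
unrepressed members exactly as real prediction sets contain false
positives.

Problem sizes used by the shipped validation suite — 1000 random
scanner-versus-oracle pairs, 100 transcripts for breakpoint recovery, 200
seeded replicates for null calibration, 1200 transcripts for the
planted-repression benchmark — were chosen so each property is measured at
the scale its guarantee is stated at.

## Numerical and degenerate-input choices

- Window acceptance uses `>=` against the threshold; outcome classification
  uses strict `>` against `min_delta`, so boundary ties resolve toward
  `unchanged`.
- If no window passes at all (coverage everywhere below threshold but
  $r > 0$), the proposal degenerates to a near-total truncation, clamped to
  leave at least one UTR base; the TPM gate is the intended guard against
  acting on such calls.
- `compute_tpm()` rejects all-zero count tables (TPM undefined) and
  non-positive lengths; `compare_annotation_sets()` reports percentages as
  `NA` when the baseline has no sites instead of dividing by zero.
- Empty samples are errors for `ecdf_table()` and `ks_one_sided()`; an
  empty group after the fold-change join is an error naming the group.
- Duplicate miRNA ids are deduplicated (first kept) with a warning;
  duplicate transcript ids in abundance or fold-change tables are rejected.

## Known limitations

Reannotation is single-interval-UTR only, by design; novel UTRs and
multi-exon UTRs are recorded as skips. One abundance table serves both the
truncation gate and the expression filter. The detector models a single
dominant 3'-UTR isoform per transcript: a genuine low-abundance long
isoform below the coverage threshold is truncated away, which is also why
marginally repressed "removed targets" can occur in real data. The
command-line front end (`system.file("scripts", "utrtar",
package = "utrtar")`) is a thin dispatcher over the exported functions;
programmatic use is the primary interface.
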