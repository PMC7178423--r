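# Fixture builders shared across test files. All fixtures are built in code.

# a plus-strand two-exon model: CDS exon, intron, terminal exon whose distal
# part is the 3'-UTR
fixture_plus_model <- function(id = "TXP", cds = c(100L, 300L),
                               term = c(500L, 1600L), utr_start = 600L) {
  transcript_model(id, "chr1", "+",
                   exons = intervals(c(cds[1], term[1]), c(cds[2], term[2])),
                   utr3 = intervals(utr_start, term[2]))
}

# its minus-strand mirror: terminal exon genomically first
fixture_minus_model <- function(id = "TXM", term = c(100L, 1200L),
                                cds = c(1400L, 1600L), utr_end = 1100L) {
  transcript_model(id, "chr1", "-",
                   exons = intervals(c(term[1], cds[1]), c(term[2], cds[2])),
                   utr3 = intervals(term[1], utr_end))
}

# uniform coverage track over [start, end) on chr1
uniform_track <- function(start, end, value) {
  coverage_track(list(chr1 = data.frame(start = start, end = end,
                                        value = value)))
}

# a tiny GTF file exercising both attribute spacing dialects
fixture_gtf_lines <- function() {
  c("#!genome-build toy1",
    paste0("chr1\ttoy\ttranscript\t101\t700\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1"; transcript_biotype "protein_coding";'),
    paste0("chr1\ttoy\texon\t101\t300\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1"; transcript_biotype "protein_coding";'),
    paste0("chr1\ttoy\texon\t401\t700\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1"; transcript_biotype "protein_coding";'),
    paste0("chr1\ttoy\tthree_prime_utr\t501\t700\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1"; transcript_biotype "protein_coding";'),
    # second transcript: minus strand, no 3'-UTR, compact attribute spacing
    paste0("chr1\ttoy\texon\t1001\t1400\t.\t-\t.\t",
           'gene_id"G2";transcript_id"T2";gene_biotype"protein_coding";'))
}

write_fixture_gtf <- function(path = tempfile(fileext = ".gtf")) {
  writeLines(fixture_gtf_lines(), path)
  path
}

# small bundle with one gene per strand and a known genome
fixture_bundle <- function(genome_len = 2000L) {
  set.seed(99)
  genome <- random_dna(genome_len)
  models <- list(
    TXP = fixture_plus_model(term = c(500L, 1000L), utr_start = 600L),
    TXM = fixture_minus_model(term = c(1100L, 1500L), cds = c(1700L, 1900L),
                              utr_end = 1400L)
  )
  reference_bundle(c(chr1 = genome), models)
}
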