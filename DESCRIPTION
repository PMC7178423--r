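Package: utrtar
Title: Coverage-Driven 3'-UTR Reannotation and Expression-Filtered miRNA
    Target Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines 3'-UTR annotations of protein-coding transcripts from
    bulk RNA-Seq read coverage (extending or truncating annotated distal ends
    under explicit eligibility rules), scans contiguous 3'-UTR sequences for
    canonical microRNA seed sites (6mer, 7mer-A1, 7mer-m8, 8mer), filters
    predictions by transcript expression (TPM), compares prediction sets
    across annotation versions, and benchmarks prediction sets against
    miRNA-transfection log2 fold-change data with one-sided two-sample
    Kolmogorov-Smirnov tests. Includes a seeded synthetic-data generator
    (toy genomes, coverage tracks with planted alternative-polyadenylation
    breakpoints, planted seed sites and planted repression) so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
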