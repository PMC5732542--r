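Package: rnaiscreen
Title: In Silico Off-Target Screening for Pesticidal RNAi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens pesticidal double-stranded RNAs (dsRNAs) and short
    interfering RNAs (siRNAs) against an annotated non-target gene set for
    putative RNA-interference off-target and non-target binding. Enumerates
    21-nt siRNA windows from each pesticidal RNA, finds every gene-set
    position matching at the 19/21, 20/21 or 21/21 identity class by an
    exhaustive mismatch-tolerant search on both orientations, collapses
    matches to deduplicated per-(RNA, gene) tallies, and tests length
    dependence (log-log least-squares regression with F test), target-taxon
    effects and gene-group enrichment (Pearson chi-square tests of
    independence). A synthetic data generator plants homologies with known
    ground truth so the whole pipeline is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
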