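Package: triplexmeth
Title: RNA:DNA Triplex Prediction and CpG Hypermethylation Protection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline asking whether a long non-coding RNA shields
    CpG loci from hypermethylation by forming RNA:DNA triple helices.
    Classifies CpG probes from two-group beta-value matrices into
    hypermethylated and non-hypermethylated sets, computes RNA secondary
    structure accessibility with an exact partition function and masks paired
    nucleotides, predicts triplex-forming oligonucleotide / triplex target
    site matches under canonical Hoogsteen motif rules with a brute-force
    verification oracle, clusters TFOs into DNA binding domains with
    background-resampled enrichment statistics, and validates predictions
    against RNA-chromatin contact data. Ships a synthetic-data generator
    that emulates the statistical structure of methylation-array cohorts,
    structured lncRNAs, and chromatin-contact experiments so every stage is
    testable with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
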