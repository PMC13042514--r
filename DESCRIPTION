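Package: readingm6a
Title: Quantifying and Predicting the Regulatory Readouts of m6A Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the downstream regulatory consequences
    ("readouts") of N6-methyladenosine (m6A) from count-level sequencing
    summaries and to predict them from the RNA-binding-protein (RBP) context
    of individual m6A sites. Implements ERCC spike-in anchored mRNA half-life
    estimation from actinomycin D time courses, translation-efficiency change
    testing from Ribo-seq/RNA-seq count pairs, exon-inclusion (Psi) change
    calling from junction counts, single-nucleotide m6A map construction from
    GLORI-style tables and MeRIP-seq peak projection with DRACH validation,
    an eleven-feature-set encoder of the RBP binding context around m6A
    sites, gradient-boosted per-cell-type readout classifiers with
    cross-validated ROC evaluation and feature-set gain analysis, and
    HyperTRIBE editing-site calling with m6A proximity profiling. A synthetic
    data generator with known ground truth emulates every input so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
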