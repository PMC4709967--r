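Package: oncostage
Title: Stage-Associated Somatic Variant Filtering and Copy-Number
    Significance for Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a cohort-genomics workflow for
    staged tumor cohorts: high-confidence somatic SNV filtering from
    tumor/normal per-read evidence (depth, allele-frequency contrast,
    rank-based mapping/base-quality and read-end tests, strand-bias and
    adjacency rules), germline-evidence indel classification, sequencing
    lane/read/sample quality-control gates, a GISTIC-style copy-number
    G-score over 1-kb marker windows with a permutation-derived null,
    comparative (delta-delta-Ct) qPCR copy-number inference, and
    cohort-level statistics (mutation-landscape frequency classes,
    stage-association Fisher tests, hypergeometric pathway enrichment with
    Benjamini-Hochberg correction, copy-number burden comparison, mutation
    spectra). A fully seeded synthetic-cohort generator provides every
    pipeline input, so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite
Config/testthat/edition: 3
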