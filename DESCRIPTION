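Package: relapsetype
Title: Clonal Evolution Typing of Matched Diagnosis-Relapse Leukemia Trios
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for longitudinal tumor sequencing trios
    (initial diagnosis, remission, relapse). Classifies matched
    diagnosis-relapse pairs into type-1 (major-clone persistence) and
    type-2 (major-clone eradication with minor-ancestor expansion)
    relapses from allele-frequency thresholds, separates somatic from
    constitutional variants using the remission sample, compares copy
    number aberration profiles between timepoints, refits 96-channel
    trinucleotide mutational-signature exposures by non-negative least
    squares, screens constitutional loss-of-function variants in cancer
    predisposition genes, deconvolves bulk chromatin-accessibility
    profiles into T-cell precursor stage mixtures, and reproduces the
    cohort-level exact statistics. Ships a fully labeled synthetic-cohort
    generator so every stage is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
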