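Package: muc16tr
Title: Tandem Repeat Decomposition and Proteogenomic Validation of the
    19-Repeat MUC16 (CA125) Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for revising and validating the molecular model of the
    ovarian cancer biomarker CA125 (MUC16) from long-read amplicon
    sequencing. Implements quality/length filtering of noisy long reads,
    template selection and iterative pileup-majority consensus polishing
    with a banded global aligner, translation and anchor-based tandem
    repeat segmentation of the ~156-residue mucin repeat units (including
    the conserved C-loop cysteines at positions 59 and 79), in silico
    tryptic digestion with peptide-to-model mapping, region-uniqueness
    classification, coverage reports and two-model digest comparison, and
    alignment-free multi-source consensus building with variant naming and
    N-glycosylation sequon change assessment. A seeded synthetic-data
    generator produces MUC16-like gene models, noisy reads and sampled
    peptide observations so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
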