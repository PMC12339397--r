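Package: microMetab
Title: Low-Input Metabolomics, Lipidomics and Isotope Tracing for Sorted Cells
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis stack for low-input LC-MS metabolomics and lipidomics of
    rare FACS-sorted cell populations. Provides feature-table containers built
    on SummarizedExperiment; process-blank based detection with normality
    adaptive testing; shorthand lipid nomenclature parsing, isomer merging and
    class/subclass aggregation; differential abundance with Inf-clamped log2
    fold changes and covariate-adaptive false discovery rate control; 13C mass
    isotopologue natural-abundance correction by non-negative least squares
    with labelled-fraction estimation; metabolome-transcriptome integration via
    metabolograms and univariate-linear-model regulon activity; and seeded
    synthetic-data generators with recorded ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Metabolomics, Lipidomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
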