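Package: methfert
Title: Sperm DNA Methylation Analysis and Fertility Prediction from
    Bisulfite Sequencing Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of reduced representation bisulfite
    sequencing (RRBS) data for bull fertility studies: reading per-CpG
    methylation counts in Bismark coverage format, estimating per-bull
    corrected non-return rates from binary artificial-insemination
    records by mixed-model equations (BLUP), filtering CpG sites by
    coverage, group presence and a variant mask, calling differentially
    methylated cytosines with a coverage-pooled likelihood-ratio test
    and a dispersion-aware beta-binomial Wald test, merging sites into
    differentially methylated regions, annotating sites and regions
    against gene features, CpG-island context and repeats, and building
    a Random-Forest classifier of fertility status evaluated by
    stratified resampling, group splits and an independent cohort. A
    synthetic-data module generates toy genomes, cohorts and count
    matrices with known ground truth so the whole pipeline can be
    exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    IRanges,
    S4Vectors,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
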