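Package: ephascore
Title: Single-Cell Phenotyping by EphA Receptor Clustering Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the spatial clustering of EphA receptors on single
    cells imaged on ephrinA1-functionalized supported lipid bilayers. The
    central statistic is an intensity-entropy score per cell (the mean of
    rho*ln(rho) over the pixels under the cell, rho being pixel intensity
    relative to the cell mean), which is gain-invariant and bounded by
    ln(N). The package provides reference-cell-line chip normalization
    with a Kruskal-Wallis/Dunn quality gate, population distribution
    statistics (Kolmogorov-Smirnov comparisons, colony-inheritance
    analyses, a bootstrap subset-confidence test, correlation with
    migration phenotypes), a single-cell EphA2-pathway transcriptomic
    enrichment score, and synthetic-data generators (images, chips,
    clonal colony series, expression matrices) that emulate the assay so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    EBImage,
    randomForest,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
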