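Package: refstab
Title: Reference Gene Stability Analysis for qRT-PCR Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting stable reference (housekeeping) genes for
    qRT-PCR normalization and for downstream relative quantification. Implements
    the geNorm M value with stepwise exclusion and pairwise variation, the
    NormFinder variance-decomposition stability value (intra- and inter-group),
    and the BestKeeper descriptive statistics and index correlation, together
    with an arithmetic-mean-rank consensus of the three rankings, standard-curve
    amplification efficiency, geometric-mean multi-reference 2^-ddCt
    quantification, candidate screening from FPKM tables, z-score
    standardization, K-means expression clustering, and a pairwise
    fold-change/p-value differential expression filter. Includes a synthetic
    quantification-cycle (Ct) data generator with known variance components for
    validating the stability algorithms. Data are held in
    SummarizedExperiment-derived containers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: GeneExpression, Normalization, qPCR
RoxygenNote: 7.3.3
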