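Package: tdfe
Title: Unsupervised Feature Extraction by Principal Component and Tensor
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects genes and genomic regions from small-sample,
    high-dimensional omics experiments by decomposing expression matrices
    and multi-way coverage tensors (gram-matrix PCA and higher-order
    singular value decomposition), attributing chi-squared P-values to
    features from decomposition components chosen to match the
    experimental design, and thresholding Benjamini-Hochberg adjusted
    P-values. Includes kernel tensor integration of two omics layers
    (e.g. RNA-seq expression and MeRIP-seq m6A coverage binned into
    fixed genomic windows), planted-signal benchmark generators, a native
    per-feature linear-regression baseline, and exact-test overlap
    statistics for comparing selections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    S4Vectors,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
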