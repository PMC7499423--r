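Package: atlastype
Title: Atlas-Guided Cell Type Annotation for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates cells in a new single-cell RNA-seq dataset by jointly
    clustering them with compressed landmarks of an annotated cell atlas
    (per-type average expression profiles or small labeled subsamples).
    A constrained Leiden-style community detection over a kNN similarity
    graph keeps atlas cell types frozen so they can neither split nor merge;
    every new cell is therefore assigned either a known atlas type or
    membership in a novel cluster. Includes marker and overdispersed-gene
    feature selection, a negative-binomial simulator with planted ground
    truth, and one-vs-rest Kolmogorov-Smirnov differential expression for
    characterizing novel clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
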