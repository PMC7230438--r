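Package: rhizonet
Title: Ensemble Co-Occurrence Networks and Differential Abundance for Soil Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing amplicon-derived OTU tables from factorial
    soil experiments: QIIME-classic and BIOM-JSON input/output, contaminant and
    read-count filtering, rarefaction, alpha diversity (Shannon, Chao1),
    Bray-Curtis beta diversity with PERMANOVA/ANOSIM, per-OTU G-tests of
    independence across treatments, ensemble co-occurrence network inference
    combining Bray-Curtis, Kullback-Leibler, Pearson and Spearman pairwise
    scores with a ReBoot permutation null, bootstrap edge-stability filtering,
    Brown's method for dependent p-value combination and Benjamini-Hochberg
    control, network cluster and hub statistics, and screening of OTU
    abundances against qPCR-derived nitrogen-cycle gene abundances. Includes a
    seeded synthetic-data generator with planted correlation blocks, treatment
    effects and gene links so the whole pipeline can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
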