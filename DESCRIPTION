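Package: meningiomics
Title: Somatic Copy-Number, Driver-Exclusivity, Co-Expression and
    Super-Enhancer Analysis for Meningioma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing and classification of somatic copy-number
    alteration (SCNA) segments from tumour-normal exome coverage ratios and
    B-allele frequencies; mutual-exclusivity and co-occurrence screening of
    driver events with a per-sample-rate-aware Poisson-binomial test;
    post-caller somatic variant filtering and candidate-driver selection;
    expression-based sample clustering (Ng-Jordan-Weiss spectral clustering
    with eigengap model selection); a modified local-maximal quasi-clique
    merger (lmQCM) gene co-expression network with overlap-based module
    merging; ROSE-style super-enhancer detection and enhancer-hijacking
    neo-loop comparison. Ships seeded synthetic-data generators with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    mclust,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    knitr,
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
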