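Package: regnet
Title: Regulator-Network Inference from Tumor Expression by Per-Sample Lasso
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers RBP-, TF- and miRNA-mediated regulation of gene expression
    in cancer from per-sample lasso regression of expression on genetic,
    epigenetic and binding-site features. Provides motif scanning with exact
    score p-values for building binding-site count features from sequence,
    expression and methylation preprocessing, a coordinate-descent lasso
    solver with nested cross-validated evaluation and feature-group ablation,
    fixed-lambda polyhedral (selective) inference to rank candidate
    regulators across samples, and permutation-null discovery of each
    regulator's target gene set with Benjamini-Hochberg FDR control. A
    synthetic-data generator with planted regulators and targets supports
    end-to-end validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
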