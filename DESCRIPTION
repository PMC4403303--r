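Package: toxitopic
Title: Asymmetric Author-Topic Modeling of Toxicogenomic Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Treats repeated-dose toxicogenomic expression studies as a text
    corpus: fold changes between treated and control samples are filtered,
    discretized into gene-token counts and modeled with an author-topic model
    under an asymmetric Dirichlet prior, where the "author" of each
    treatment document is the treatment itself, its drug, or its dose-time
    combination. Inference is collapsed Gibbs sampling with Minka fixed-point
    optimization of the asymmetric topic prior. Fitted latent biological
    processes support gene-list export, local hypergeometric gene-set
    enrichment, drug similarity ranking by symmetric Kullback-Leibler
    divergence, and a generalized-linear-model comparison that asks whether
    dose or time can be dropped from a design without changing pairwise
    similarity structure. Includes generators for synthetic factorial
    dose-time studies with planted gene modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    generics,
    methods,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
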