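Package: mmrules
Title: Interpretable Rule Networks for Paired Microbiome-Metabolome
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns sparse, human-readable logical rules that predict a
    binary host phenotype from paired microbial relative-abundance and
    metabolite-level tables. Rules are conjunctions of detectors, each a
    learned group of phylogenetically or chemically similar features with
    an activation threshold; the network is trained end-to-end by maximum
    a posteriori estimation with temperature-annealed continuous
    relaxations (BinaryConcrete selectors) so the fitted model discretizes
    into plain-English rules. Prior knowledge enters through principal
    coordinate embeddings of patristic and molecular-fingerprint
    distances. Includes a five-scenario semi-synthetic benchmark generator
    for paired count and metabolite data with known perturbed feature
    sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
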