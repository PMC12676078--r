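Package: rhizoadapt
Title: Host-Genotype Rhizosphere Microbiome Structure and Microbe-Contingent
    Nitrogen Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking host-genotype structure in rhizosphere
    amplicon communities to the historic environments of the host genotypes,
    and testing whether plant nitrogen responses are contingent on soil
    microbes. Implements rarefaction, alpha diversity, Bray-Curtis and
    weighted UniFrac dissimilarities, beta-dispersion, PERMANOVA with
    sequential variance partitioning, distance-based redundancy analysis
    conditioned on spatial and genetic Moran eigenvector maps, permutation
    forward selection of environmental predictors, mixed models for plant
    traits under crossed nitrogen-by-microbe treatments, and a
    microbial-effect response ratio with uncertainty propagation and a
    simulation-based comparison of reaction-norm slopes between nitrogen
    environments. A synthetic-data module generates genotype panels, marker
    matrices, Dirichlet-multinomial community tables and factorial trait
    experiments with the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    phyloseq,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
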