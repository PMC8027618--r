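Package: crisprcost
Title: Infection-Induced Fitness Costs of CRISPR-Cas Immunity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying why CRISPR-Cas
    immunity against lytic phage carries a fitness cost that is only paid upon
    infection. Provides an eco-evolutionary serial-transfer model of sensitive,
    CRISPR-immune and surface-mutant bacteria competing under daily phage
    challenge; a CRISPR-amplicon workflow (repeat-anchored spacer extraction,
    SWARM-style single-linkage clustering, abundance assignment, protospacer
    and PAM classification); alpha-diversity estimators with rarefaction; an
    estimator of the frequency of self-targeting spacer acquisition based on
    the canonical versus non-canonical PAM background ratio; competition-assay
    selection-coefficient estimation; phage transcriptional-programme
    clustering from time-course RNA-seq counts; and seeded generators that
    produce every input the pipeline consumes, so the whole analysis runs on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    deSolve,
    grDevices,
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
    utils,
    vegan,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
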