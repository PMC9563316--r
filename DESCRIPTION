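Package: metstab
Title: Stability Analysis for Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genotype-by-environment interaction (GEI) analysis of
    replicated multi-environment trials, with an emphasis on high-dimensional
    metabolite panels. Provides feature-matrix preprocessing (total-ion-count
    normalization, log10/Pareto scaling, Bonferroni-adjusted ANOVA screening),
    per-environment and combined RCBD analysis of variance with variance
    components and broad-sense heritability, the AMMI bilinear model with
    IPCA variance partitioning and biplot coordinates, thirteen AMMI-based
    stability indices, GGE which-won-where mega-environment analysis,
    BLUP-based stability indices (HMGV, RPGV, HMRPGV, WAASB), and the
    WAASBY/MTSI multi-trait selection index. A synthetic trial generator with
    fully retrievable truth makes every stage verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
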