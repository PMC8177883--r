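Package: pirateplanets
Title: Simulation and Analysis of a Conditioned-Punishment Free-Operant Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An event-driven, seed-reproducible simulator of the "Planets and
    Pirates" conditioned-punishment paradigm (free-operant clicking for
    reward, response-contingent conditioned stimuli, probabilistic attacks
    and a costly active-avoidance shield), a synthetic-cohort generator with
    punishment-sensitive and punishment-insensitive agent archetypes, and
    the complete analysis pipeline for such experiments: event-log
    validation and segmentation, preference and conditioned-suppression
    ratios, shield-use percentages, exclusion rules, k-means phenotype
    clustering with silhouette model selection, hierarchical
    Response-CS-Attack chain-inference regressions, orthogonal-contrast
    mixed ANOVAs, varimax-rotated PCA with a communality retention rule,
    and SPSS-style stepwise linear and logistic regression with the
    Nagelkerke pseudo r-squared.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    dplyr,
    tibble,
    tidyr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
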