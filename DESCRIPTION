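Package: socnetlong
Title: Social Association Networks, Group Structure, and Longevity in Wild
    Mammal Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for relating social-network structure to
    adult longevity and survival in long-term studies of marked, group-living
    mammals. Builds daily-resolution simple-ratio association matrices from
    focal observation records, tests networks for nonrandom long-term
    companionship with within-sample (Bejder-style) swap randomizations,
    assigns individuals to social groups by weighted clique percolation,
    computes individual and group centrality measures (strength, Bonacich
    power, information centrality, their within-group standard deviations,
    distance-based cohesion and network centralization), regresses adult
    longevity on group-level social structure with Manly-style randomization
    tests, and fits Barker joint live-recapture/dead-recovery/live-resight
    survival models with QAICc model selection and model averaging. A
    synthetic-data generator emulating daily focal sampling of marked
    individuals makes every stage testable without field data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
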