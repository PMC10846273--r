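Package: privcoop
Title: Privatization and Coexistence Dynamics in Microbial Public-Goods Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models cooperator-cheater dynamics in a microbial public-goods
    system in which cooperators secrete an enzyme that releases a shared
    resource and retain (privatize) a fraction of it. Provides the
    resource-share and cost-bearing Monod fitness model, the equal-fitness
    coexistence solver and privatization/secretion parameter sweeps, a
    deterministic serial-transfer (batch dilution) simulator with
    least-squares calibration of privatization and cost from frequency
    trajectories, a seeded synthetic-experiment generator emulating
    colony-count frequency assays of replicate coevolution lines, and
    frequency inference (Wilson intervals, replicate summaries, t-test
    group comparisons) on the resulting assay tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
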