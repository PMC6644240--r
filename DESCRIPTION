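Package: dmcstroop
Title: Diffusion Model for Conflict Tasks: Simulation, Fitting and
    Stroop Session Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the diffusion model for conflict (DMC) tasks --
    a drift-diffusion process whose drift is the superposition of a
    constant controlled process and a gamma-shaped, time-varying
    automatic process -- and fits it to two-choice Stroop data by
    minimising a multinomial G-squared statistic over reaction-time
    quantile bins with multi-restart Nelder-Mead. Includes a synthetic
    Stroop session generator with configurable conflict-adaptation and
    stimulation-condition effects, trial exclusion and congruency
    sequence (Gratton) effect tables, Monte-Carlo permutation tests
    (paired Fisher-Pitman, maxT multivariate Kruskal-Wallis) with
    Bonferroni-Holm correction, a parameter-recovery harness, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
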