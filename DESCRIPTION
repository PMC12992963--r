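Package: priortime
Title: Bayesian Prior Acquisition in Sensorimotor Interval Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for coincidence-timing
    experiments in which target intervals are drawn from two interleaved
    discrete prior distributions. Implements a Bayesian observer model with
    scalar (Weber-scaled) sensory variability, a synthetic participant and
    trial generator, trial exclusion and binned-mean preprocessing,
    least-squares fitting of one-prior and two-prior mean-response curves,
    prior-acquisition metrics derived from the fitted curves, a permutation
    test for between-group differences in the acquired-prior divergence, and
    small-sample-corrected Akaike (AICc) model comparison with Akaike
    weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
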