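Package: afsim
Title: Stochastic Individual-Based Simulation of Atrial Fibrillation Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven simulation of atrial fibrillation (AF) as a two-state
    (sinus rhythm / AF) switching process over a patient's lifetime. Episode
    initiation and termination hazards evolve deterministically between random
    switching events (age-related sigmoidal activation, exponentially declining
    recovery, and episode-induced remodelling with a post-episode recovery
    boost); switching times are sampled exactly by cumulative-hazard inversion.
    Includes clinical-stage classification (paroxysmal, persistent, permanent
    AF), burden and episode-count metrics over absolute or onset-aligned
    windows, ensemble statistics, and one-at-a-time parameter scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
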