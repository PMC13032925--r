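Package: vsdecision
Title: Spike-Train and Behavioral Analysis of Value-Based Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for sequential value-based decision experiments
    in which a subject evaluates an option and decides whether to act on it.
    Implements sliding-window classification of single-unit activity into
    value-modulated, intermediate and choice-modulated signals via nested
    model comparison against a Monte Carlo baseline-shuffle null; signal
    latencies and transition probabilities; ridge-regression analyses with
    permutation significance and max-statistic family-wise error control;
    psychometric logistic choice models and latency regressions; statistics
    for paired stimulation/control sessions (delta choice rate, per-site
    chi-square, distribution-width shuffle test); and a synthetic-data
    generator (logistic choice behavior, inhomogeneous-Poisson spiking,
    logit-shift stimulation) so every stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
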