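Package: chemosched
Title: Optimal Chemotherapy Scheduling in a Vascularized Tumor Model with
    Acquired Drug Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a heterogeneous extension of the Hahnfeldt
    tumor-angiogenesis model in which the tumor is split into
    chemotherapy-sensitive and chemotherapy-resistant compartments coupled by
    mutation, with a dynamic vascular carrying capacity under combined
    chemotherapy and anti-angiogenic treatment. Provides first-passage
    survival-time analysis under constant dosing (dose sweeps, dose heatmaps,
    mutation-rate sweeps), a resistance-penalizing optimal-control problem for
    short-horizon chemotherapy scheduling solved by direct transcription
    (forward Euler, exact adjoint gradients, multistart box-constrained
    quasi-Newton), clinically realizable piecewise-constant suboptimal
    protocols with optimized switching times, and a randomized sensitivity
    study over mutation rates.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    Rcpp,
    jsonlite,
    minpack.lm,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
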