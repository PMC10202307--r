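Package: abcadapt
Title: Adaptive Distances and Sensitivity Weights for Sequential Approximate Bayesian Computation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Likelihood-free Bayesian inference for stochastic simulators via an
    ABC-SMC (approximate Bayesian computation, sequential Monte Carlo) engine with
    adaptive scale-normalized Minkowski distances (MAD and outlier-robust PCMAD
    weights), mid-run training of inverse regression models used either as summary
    statistics or to derive per-coordinate sensitivity weights quantifying data
    informativeness, and augmented regression targets for non-identifiable models.
    Ships a zoo of benchmark problems (Gaussian test models, g-and-k order
    statistics, a conversion-reaction ODE, and an exact Gillespie simulation of a
    Lotka-Volterra Markov jump process) together with a replicate/RMSE evaluation
    workbench.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
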