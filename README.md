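# abcadapt

Likelihood-free Bayesian inference for stochastic simulators with
**adaptive, informativeness-aware distances** in a sequential ABC sampler.

## The problem

Approximate Bayesian computation (ABC) calibrates a simulator by accepting
parameter draws whose simulated data land close to the observed data:
accept θ when *d*(y, y_obs) ≤ ε. On heterogeneous data this comparison is
fragile twice over: coordinates on large scales dominate the distance, and
coordinates that are pure background noise dilute it. `abcadapt` provides an
ABC-SMC (sequential Monte Carlo) engine whose distance

d(y, y_obs) = ( Σᵢ | rᵢ (yᵢ − y_obs,ᵢ) |^p )^{1/p},  rᵢ = qᵢ / σᵢ

is rebuilt every generation:

- **σᵢ** — a robust per-coordinate scale (MAD, or outlier-robust PCMAD),
  recomputed each generation from all particles of the previous one
  (adaptive scale normalization);
- **qᵢ** — an optional *sensitivity weight* quantifying how informative
  coordinate *i* is: an inverse regression model s : y → λ(θ) is trained
  mid-run, its Jacobian S = ∇_y s(y_obs) is taken at the observed data by
  central finite differences, and qᵢ = Σₗ |Sᵢₗ| / Σⱼ |Sⱼₗ| (normalized per
  target);
- alternatively the regression outputs serve directly as **summary
  statistics**, compared under a freshly scale-normalized distance;
- **target augmentation** λ(θ) = (θ¹, …, θᵏ) makes sign-symmetric,
  non-identifiable parameters learnable through their even powers.

The package ships the benchmark problem zoo used to exercise all of this
(Gaussian test models, g-and-k order statistics, a conversion-reaction ODE,
an exact Gillespie Lotka–Volterra jump process), plus a replicate/RMSE
evaluation workbench and a small CLI (`inst/cli/abcadapt.R`). It is aimed at
researchers in systems biology and simulation-based inference who need
likelihood-free calibration that does not require hand-tuned distance
weights or hand-crafted summary statistics.

## Worked example

The quadratic toy is the smallest non-identifiable problem: y ~ N(θ², 0.1²)
with θ ~ U[−1, 1] and observed value 0.7, so the posterior is bimodal at
±√0.7 ≈ ±0.84.

```r
library(abcadapt)
r <- abc_smc("quadratic", n_particles = 1000, budget = 20000,
             seed = 1, max_generations = 8)
r
#> ABC-SMC run on 'quadratic': 4 generations, 20000 simulations (budget exhausted mid-generation)
#>   epsilon trajectory: 1.891 -> 1.891 -> 1.029 -> 0.5532 -> 0.2611
#>   final sample: 1000 particles (generation 3)
#>   weighted posterior mean: 0.03734
posterior_mean(r, function(t) t^2)
#> [1] 0.6868416
```

The weighted posterior mean of θ is ≈ 0 (the two modes cancel — the sampler
kept both) while the mean of θ² recovers the conditioned observation 0.7;
the ε trajectory shows the threshold contracting as generations proceed.

Method labels follow the composable grammar of `parse_method()`; the
replicate protocol reports weighted RMSE against ground truth, aggregated by
median and MAD across replicates, each replicate on freshly generated data:

```r
cfg <- list(problem = "T2", method = "L1+Ada.+MAD+SensiLR",
            n_particles = 200, budget = 10000, seed = 1)
replicate_runs(cfg, n_replicates = 3)$table
#>               method problem parameter median_rmse   mad_rmse n_replicates
#>  L1+Ada.+MAD+SensiLR      T2    theta1   0.1604371 0.01342583            3
```

See `vignettes/adaptive-abc.Rmd` for the full account of the algorithm, the
regression and sensitivity machinery, the benchmark zoo and its conventions,
and known limitations.

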