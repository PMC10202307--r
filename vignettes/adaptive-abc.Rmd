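---
title: "Adaptive distances and sensitivity weights in sequential ABC"
author: "abcadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive distances and sensitivity weights in sequential ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcadapt)
```

## The inference problem

Approximate Bayesian computation (ABC) targets the posterior
$\pi(\theta \mid y_{obs}) \propto \pi(y_{obs} \mid \theta)\,\pi(\theta)$
when the likelihood of a stochastic simulator is intractable but simulation is
cheap: draw $\theta$ from a proposal, simulate $y \sim \pi(y \mid \theta)$,
and accept when $d(y, y_{obs}) \le \varepsilon$. `abcadapt` implements the
sequential Monte Carlo variant (ABC-SMC): a series of particle populations
with decreasing thresholds $\varepsilon_1 > \varepsilon_2 > \dots$, where
generation $t$ samples from a Gaussian-mixture proposal built on the previous
accepted population and corrects by importance weights
$w = \pi(\theta)/g_t(\theta)$.

The scientific focus of the package is *how the distance $d$ is built*:

1. **Adaptive scale normalization.** The weighted Minkowski distance
   $d(y, y_{obs}) = \big(\sum_i |r_i (y_i - y_{obs,i})|^p\big)^{1/p}$
   with $r_i = 1/\sigma_i$, where $\sigma_i$ is a robust per-coordinate scale
   (MAD, or the outlier-robust PCMAD) recomputed each generation from **all**
   particles — accepted and rejected — of the previous generation. Without
   this, coordinates that vary on large scales dominate the acceptance
   decision.
2. **Regression-based summary statistics.** An inverse regression model
   $s : y \mapsto \lambda(\theta)$ trained mid-run; afterwards the engine
   compares $s(y)$ with $s(y_{obs})$ under a freshly scale-normalized
   adaptive distance on the statistics.
3. **Sensitivity weights.** The same inverse model, used not to transform the
   data but to *weight* them: with
   $S = \nabla_y s(y_{obs})$ (central finite differences at the observed
   data, on the regressor's normalized input scale), the weight of coordinate
   $i$ is
   $q_i = \sum_l |S_{il}| / \sum_j |S_{jl}|$ — the per-target-normalized
   absolute sensitivity — and the distance uses $r_i = q_i / \sigma_i$. Data
   that carry no information about any parameter get small $q$ and stop
   inflating the comparison, while no information is discarded (all $r_i > 0$
   coordinates still enter the distance).
4. **Target augmentation.** For structurally non-identifiable parameters an
   inverse map $y \mapsto \theta$ does not exist (e.g. $y \sim N(\theta^2,
   0.1^2)$ is symmetric in $\theta$). Regressing the componentwise powers
   $\lambda(\theta) = (\theta^1, \dots, \theta^k)$ (the default augmentation
   is $k = 4$, "P4") restores learnable targets: $\theta^2$ is linear in $y$
   even when $\theta$ is not.

Method labels compose these pieces exactly as
`parse_method()` documents: `"L1+Ada.+MAD"`, `"L1+StatLR"`,
`"L1+Ada.+MAD+SensiLR+P4"`, `"L1+Ada.+PCMAD+StatNN+Init"`, …

## The algorithm, generation by generation

*Calibration (generation 0).* $N$ prior draws are simulated; $\sigma$ is
computed from them and $\varepsilon_1$ is the median of their weighted
distances. Hard simulator errors are resampled (and counted against the
budget); sentinel outputs such as event-capped jump-process runs are kept
with infinite distance, so they can never be accepted but still count as
spent simulations.

*Each generation $t \ge 1$.*

1. $\sigma_t$ is recomputed from all previous-generation simulations. When
   the comparison runs on summary statistics, the scale is computed on the
   predicted statistics of those same particles.
2. If the simulations consumed have reached `train_fraction` of the budget
   (default 0.4; 0 means "Init", training on the calibration sample) and no
   model has been trained yet, the regression model is fitted once on **all**
   particles of the previous generation. In statistics mode the comparison
   space switches; in sensitivity mode $q$ is computed once and then held
   fixed while $\sigma$ keeps adapting.
3. The threshold $\varepsilon_t$ is the median of the previous accepted
   distances *re-evaluated under the new distance*. Thresholds computed under
   different weight vectors (or a different comparison space) are not
   commensurable, so re-scoring is done every generation; at the statistics
   switch this is what makes the handover well-defined.
4. Particles are proposed (generation 1: from the prior, with importance
   weight exactly 1; later: from the Gaussian mixture over the previous
   accepted particles with shared covariance $2 \times$ their weighted
   empirical covariance), simulated, and accepted while $d_t \le
   \varepsilon_t$, until $N$ acceptances or budget exhaustion.
5. Importance weights $\pi(\theta)/g_t(\theta)$ are normalized to sum to 1.
   The mixture density is used untruncated; prior support is enforced by
   redrawing proposals that fall outside.

The run stops when the budget is exhausted (a generation interrupted
mid-sampling is stored but flagged partial, and the *last complete*
generation provides the final weighted posterior sample), when a maximum
generation count is reached, or when $\varepsilon$ has not decreased by more
than $10^{-12}$ for three generations (stagnation guard).

## Regression model details

Both families fit one joint multi-output model for all targets.

* Inputs are $y / \sigma^{MAD}_{t_{train}}$. MAD is used for input
  normalization even when the distance uses PCMAD — folding the outlier
  correction into the regressor inputs would inversely re-scale the
  sensitivities — and also when the distance is unweighted, because the
  regressor still needs a scale-free input space. Coordinates with zero MAD
  are dropped from the regressor and recorded; their sensitivity weight is 0.
* Targets $\lambda(\theta)$ are z-scored; a target with zero spread gets
  standard deviation 1 (it then contributes nothing informative rather than
  NaNs). Predictions stay on the z-scored scale: the downstream adaptive
  distance renormalizes anyway, and sensitivity weights need scale-free
  outputs.
* `family = "linear"` is ordinary least squares (`lm.fit`), rank-deficient
  coefficients set to 0.
* `family = "nn"` is a single-hidden-layer ReLU network trained with ADAM
  (default rate $10^{-3}$), minibatches of 64, at most 500 epochs, and early
  stopping with patience 10 on a 10% validation split. The hidden width is
  $\lceil (n_y + n_\lambda)/2 \rceil$ with a floor of 4 — the formula alone
  degenerates to a single ReLU unit on low-dimensional problems, which can
  initialize dead; the floor plus small positive bias initialization removes
  that failure mode.
* The model is trained once per run. The statistic of the observed data
  $s(y_{obs})$ is computed at training time and cached.

The finite-difference step for the sensitivity matrix is chosen per input
coordinate from the ladder $h \in \{10^{-1}, 10^{-2}, 10^{-3}\} \cdot
\max(1, |x_i|)$: the estimate kept is the smaller-step member of the
adjacent pair that agrees best in relative terms. Large steps control
regressor noise, small steps control truncation error; the pairwise-agreement
rule balances the two without assuming either dominates. Targets whose
sensitivities are zero everywhere are skipped in the normalization (the
"conservative weights" convention); if *all* sensitivities vanish the engine
warns and falls back to scale-only weights.

## The benchmark zoo

All problems generate their own data; nothing is read from disk.

| name | parameters | data | notes |
|------|-----------|------|-------|
| `demo` | 4 | 17 | five Gaussian blocks: informative $y_1, y_2$, a 4-fold block $y_3$, a quadratic (sign-symmetric) $y_4 \sim N(\theta_4^2, 0.1^2)$ and ten pure-noise $y_5 \sim N(0, 10)$; fixed observed data $(0,\dots,0, 0.7, 0,\dots,0)$ |
| `quadratic` | 1 | 1 | $y \sim N(\theta^2, 0.1^2)$, $\theta \sim U[-1,1]$, $y_{obs} = 0.7$ |
| `gauss` | 1 | 1 | conjugate check: prior $N(0,1)$, $y \sim N(\theta, 1)$, $y_{obs} = 1$, analytic posterior $N(0.5, 0.5)$ |
| `T1` | 2 | 10 | conversion-reaction ODE, $x_2$ at $t = 3, 6, \dots, 30$ plus $N(0, 0.02^2)$ noise |
| `T2` | 1 | 2 | one informative, one pure-noise observable, prior $N(0, 100^2)$ |
| `T3` / `T5` | 4 | 7 / 100 | g-and-k order statistics (octiles of 1,000 draws / 100 evenly ranked of 10,000), priors $U[0,10]^4$ |
| `T4` / `T6` | 3 | 32 / 200 | Lotka–Volterra Markov jump process, exact Gillespie simulation, counts of both species on 16 / 100 evenly spaced times in $(0, 20]$, priors $U[0,2] \times U[0,0.1] \times U[0,1]$ |

Conventions worth stating explicitly:

* Gaussian notation: the second argument of every $N(\cdot,\cdot)$ above is a
  **variance** (so the $y_3$ block has standard deviation 200 and $y_5$ has
  $\sqrt{10}$), for internal consistency with $N(\theta_2, 100^2)$.
* The g-and-k distribution is defined by its quantile function with the
  conventional fixed $c = 0.8$; $g = k = 0$ reduces it to $N(A, B^2)$. Order
  statistics sit at the evenly spaced ranks $\lceil j n/(m+1) \rceil$ —
  chosen for symmetry, since nothing pins down a particular rank scheme.
* The Lotka–Volterra process starts from $(prey, predator) = (50, 100)$ (a
  standard configuration for the rates considered; the initial state is
  otherwise unconstrained) with rates: prey birth $\theta_1 X$, predation
  $\theta_2 X Y$, predator death $\theta_3 Y$. The observation grid excludes
  $t = 0$, where the known initial state would add a zero-variance
  coordinate. The registered problems cap a single simulation at $10^6$
  reaction events (the `gillespie_lv()` default cap is $10^7$): trajectories
  that exceed the cap are runaway prey explosions possible under the wide
  priors, need orders of magnitude more events than any trajectory resembling
  the observed data, and return a sentinel that is rejected with infinite
  distance either way — the cap changes no inference result, only the cost of
  hopeless simulations.
* The conversion model's configuration (initial state $(1,0)$, ten
  observation times in $(0,30]$, noise sd $0.02$, priors $U[0,0.4]^2$, ground
  truth $(0.08, 0.12)$) and the T2 ground truth $3$ are package defaults,
  chosen once as representative mid-prior values; both are configurable via
  `problem_spec()`.
* Every Gaussian-noise simulator takes a `noise_scale` multiplier whose zero
  setting exposes the deterministic part — a test hook. The intrinsically
  stochastic simulators (g-and-k sampling, Gillespie) have no zero-noise
  limit and omit it.
* PCMAD uses $\sigma = MAD$ when $MADO \le MAD$ and $MAD + MADO$ otherwise
  (non-strict comparison, so exactly unbiased simulations reduce to plain
  MAD). Medians use the midpoint convention for even counts.
* Coordinates with $\sigma = 0$ get weight 0 — they carry no comparison
  scale — rather than an infinite weight.

## What the synthetic benchmarks do and do not show

The generators emulate the structural difficulties the methods address:
heterogeneous scales, uninformative coordinates, sign-symmetric
non-identifiability, heavy-tailed distributions (g-and-k), and
discrete-state stochastic kinetics. They do not emulate model
misspecification (simulated and observed data always come from the same
process), real measurement pipelines, or correlated noise. Passing the test
suite therefore demonstrates correctness of the machinery and its behavior
under the intended failure modes, not performance on any particular
laboratory data set.

## Problem sizes used in tests and the acceptance script

The engine's end-to-end checks run at reduced scale, chosen as the smallest
configurations at which the qualitative claims stabilize across seeds:
quadratic toy at $N = 1000$ with $2 \times 10^4$ simulations; demonstration
problem at $N = 500$ with $5 \times 10^4$; g-and-k (T5) at $N = 200$ with
$2 \times 10^4$; Lotka–Volterra (T6) at $N = 100$ with $5 \times 10^3$; the
conjugate check at $N = 1000$ with $10^4$.

Two empirical notes from these configurations:

* At the reduced T6 scale the run affords only 5–6 generations and the
  posterior mean of $\theta_1$ remains near its $U[0,2]$ prior mean
  (measured $\approx 1.0$ across seeds), while the identical engine at
  $N = 500$ with $1.25 \times 10^5$ simulations recovers
  $(0.51, 0.0029, 0.33)$ against the truth $(0.5, 0.0025, 0.3)$. The
  200-dimensional jump-process problem simply needs more than $5 \times 10^3$
  simulations; the corresponding engine check is expected to fail at that
  scale and is kept as an honest record of it. A contributing effect is that
  more than half of the wide-prior trajectories go extinct, so early
  generations assign zero MAD — and hence zero weight — to most late-time
  coordinates.
* On the demonstration problem a bare "both signs of $\theta_4$ carry
  at least 20% posterior mass" proxy cannot distinguish a run that captures
  the bimodality at $\pm\sqrt{0.7}$ from one whose $\theta_4$ marginal has
  relaxed to the $U[-1,1]$ prior: the problem is exactly sign-symmetric, so
  signs stay balanced either way. The package's bimodality-capture check
  therefore additionally requires the weighted mean of $\theta_4^2$ to be
  closer to the mode location $0.7$ than to the prior second moment $1/3$.
  Under plain targets ($k = 1$) the statistics carry no information about
  $\theta_4$, the marginal relaxes ($E[\theta_4^2] \approx 0.39$) and the
  check fails; under P4 augmentation it passes ($\approx 0.61$).

## A worked example

```{r example, eval = FALSE}
# sensitivity-weighted adaptive distance on the demonstration problem
m <- parse_method("L1+Ada.+MAD+SensiLR+P4")
run <- abc_smc("demo", n_particles = 500, budget = 50000,
               p = m$p, scale = m$scale, regression = m$regression, seed = 1)
posterior_mean(run)                       # theta1..theta3 near 0
fin <- final_sample(run)
sum(fin$weights * fin$thetas[, 4]^2)      # near the observed 0.7

# replicate RMSE protocol on a ground-truth problem
cfg <- list(problem = "T2", method = "L1+Ada.+MAD+SensiLR",
            n_particles = 200, budget = 10000, seed = 1)
replicate_runs(cfg, n_replicates = 10)$table
```

## Known limitations

* Single-threaded by design; no parallel simulation of particles.
* The regression model is trained once per run; repeated re-training and
  regression model selection are out of scope.
* Only the median-of-distances threshold schedule and the Gaussian-mixture
  proposal with doubled weighted covariance are implemented; alternative
  schedules and covariance adaptations are not.
* Sensitivity weights rest on the regression model being an adequate local
  description of the inverse map around the observed data; a badly
  misspecified regressor yields weights that are conservative (via the
  per-target normalization) but not meaningful.
* No Mahalanobis/covariance-aware or kernel distances; coordinates are
  weighted independently.
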