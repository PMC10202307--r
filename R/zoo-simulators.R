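# Benchmark simulators. Gaussian-noise simulators expose a `noise_scale`
# multiplier (0 gives the noise-free limit) intended for testing; the
# intrinsically stochastic simulators (g-and-k draws, Gillespie) have no
# meaningful zero-noise limit and omit it.

#' Demonstration-problem simulator
#'
#' Four parameters, five data blocks, 17 data coordinates in total:
#' y1 ~ N(theta1, 0.1^2), y2 ~ N(theta2, 100^2), y3 ~ N(theta3, 4*100^2) four
#' times, y4 ~ N(theta4^2, 0.1^2) (quadratic, hence non-identifiable in sign),
#' and ten uninformative y5 ~ N(0, 10). Second arguments are variances.
#'
#' @param theta Numeric parameter vector of length 4.
#' @param noise_scale Multiplier on all noise standard deviations; 0 gives the
#'   noise-free limit (test hook).
#' @return Numeric vector of length 17: `c(y1, y2, y3[1:4], y4, y5[1:10])`.
#' @export
simulate_demo <- function(theta, noise_scale = 1) {
  if (length(theta) != 4L) stop("simulate_demo expects a parameter vector of length 4")
  ns <- noise_scale
  c(stats::rnorm(1L, theta[1L], 0.1 * ns),
    stats::rnorm(1L, theta[2L], 100 * ns),
    stats::rnorm(4L, theta[3L], 200 * ns),
    stats::rnorm(1L, theta[4L]^2, 0.1 * ns),
    stats::rnorm(10L, 0, sqrt(10) * ns))
}

#' Quadratic toy simulator
#'
#' One draw from N(theta^2, 0.1^2). The registered problem pairs it with the
#' prior theta ~ U[-1, 1] and the observed value 0.7, making theta
#' sign-symmetric and hence non-identifiable: the posterior is bimodal at
#' roughly +-sqrt(0.7).
#'
#' @inheritParams simulate_demo
#' @param theta Scalar parameter.
#' @return A single numeric value.
#' @export
simulate_quadratic <- function(theta, noise_scale = 1) {
  if (length(theta) != 1L) stop("simulate_quadratic expects a scalar parameter")
  stats::rnorm(1L, theta^2, 0.1 * noise_scale)
}

#' Informative/uninformative two-observable simulator (T2)
#'
#' Returns `c(y1, y2)` with y1 ~ N(theta, 0.1^2) informative of theta and
#' y2 ~ N(0, 1) pure background noise. The registered problem uses the wide
#' prior theta ~ N(0, 100^2).
#'
#' @inheritParams simulate_quadratic
#' @return Numeric vector of length 2.
#' @export
simulate_t2 <- function(theta, noise_scale = 1) {
  if (length(theta) != 1L) stop("simulate_t2 expects a scalar parameter")
  c(stats::rnorm(1L, theta, 0.1 * noise_scale),
    stats::rnorm(1L, 0, 1 * noise_scale))
}

#' g-and-k quantile function
#'
#' The g-and-k distribution is defined through its quantile function
#' `Q(p) = A + B * (1 + c*(1-exp(-g*z))/(1+exp(-g*z))) * (1+z^2)^k * z`,
#' with `z` the standard-normal quantile of `p`, location `A`, scale `B > 0`,
#' skewness `g`, kurtosis `k > -0.5`, and the conventional fixed `c = 0.8`.
#' For `g = k = 0` it reduces to the normal quantile `A + B*z`.
#'
#' @param p Probability (strictly between 0 and 1); vectorized.
#' @param A,B,g,k Location, scale, skewness and kurtosis parameters.
#' @param c Skewness bound constant, conventionally 0.8.
#' @return Quantile value(s).
#' @export
gk_quantile <- function(p, A, B, g, k, c = 0.8) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  if (B <= 0) stop("scale B must be positive")
  if (k <= -0.5) stop("kurtosis k must exceed -0.5")
  gk_from_z(stats::qnorm(p), A, B, g, k, c)
}

# quantile transform applied to standard-normal variates (vectorized core)
gk_from_z <- function(z, A, B, g, k, c = 0.8) {
  eg <- exp(-g * z)
  A + B * (1 + c * (1 - eg) / (1 + eg)) * (1 + z^2)^k * z
}

#' Order statistics of g-and-k samples
#'
#' Draws `n_samples` i.i.d. g-and-k variates (by applying the quantile
#' transform to standard-normal draws), sorts them, and returns the order
#' statistics at the `n_stats` evenly spaced ranks
#' `ceiling(j * n_samples / (n_stats + 1))`, `j = 1, ..., n_stats`.
#'
#' @param theta Numeric vector `c(A, B, g, k)`.
#' @param n_samples Number of raw draws (positive; at least `n_stats`).
#' @param n_stats Number of order statistics returned.
#' @return Non-decreasing numeric vector of length `n_stats`.
#' @export
simulate_gk_order_stats <- function(theta, n_samples, n_stats) {
  if (length(theta) != 4L) stop("g-and-k expects a parameter vector of length 4")
  if (n_samples < 1L || n_stats < 1L) stop("counts must be positive")
  if (n_stats > n_samples) stop("n_stats must not exceed n_samples")
  x <- gk_from_z(stats::rnorm(n_samples), theta[1L], theta[2L], theta[3L], theta[4L])
  x <- sort(x)
  ranks <- ceiling(seq_len(n_stats) * n_samples / (n_stats + 1))
  x[ranks]
}

#' Exact Gillespie simulation of a Lotka-Volterra Markov jump process
#'
#' Reactions on the state (X = prey, Y = predator): prey birth at rate
#' `theta1 * X`; predation at rate `theta2 * X * Y` (removes one prey, adds one
#' predator); predator death at rate `theta3 * Y`. Simulated exactly with the
#' direct method (exponential waiting times). Absorbed states (all propensities
#' zero) persist to the horizon.
#'
#' Trajectories exceeding `max_events` reaction events return a vector of
#' `NA` with attribute `capped = TRUE`; the SMC engine treats such sentinel
#' output as infinite distance (rejection).
#'
#' @param theta Numeric rate vector `c(theta1, theta2, theta3)`, non-negative.
#' @param x0 Integer vector `c(prey, predator)` of non-negative initial counts.
#' @param obs_times Increasing vector of recording times.
#' @param max_events Hard cap on the number of reaction events.
#' @return Numeric vector of length `2 * length(obs_times)`: all prey counts,
#'   then all predator counts.
#' @export
gillespie_lv <- function(theta, x0 = c(50, 100), obs_times = seq_len(100) / 5,
                         max_events = 1e7) {
  if (length(theta) != 3L) stop("gillespie_lv expects three reaction rates")
  if (any(!is.finite(theta)) || any(theta < 0)) stop("reaction rates must be non-negative")
  if (length(x0) != 2L || any(x0 < 0) || any(x0 != floor(x0))) {
    stop("x0 must be two non-negative integer counts")
  }
  if (is.unsorted(obs_times) || any(obs_times < 0)) {
    stop("obs_times must be a non-negative increasing grid")
  }
  out <- gillespie_lv_cpp(as.numeric(theta), as.numeric(x0),
                          as.numeric(obs_times), as.numeric(max_events))
  if (isTRUE(attr(out, "capped"))) {
    res <- rep(NA_real_, 2L * length(obs_times))
    attr(res, "capped") <- TRUE
    return(res)
  }
  out
}

#' Conversion-reaction ODE simulator
#'
#' Two-species conversion x1 <-> x2 with mass-action rates theta1 (forward) and
#' theta2 (backward): `dx1/dt = -theta1*x1 + theta2*x2`, `x2 = total - x1`,
#' from `x0 = (1, 0)`. The observable is x2 at `times`, corrupted by additive
#' centered Gaussian noise with standard deviation `noise_sd`.
#'
#' @param theta Positive rate vector `c(theta1, theta2)`.
#' @param times Observation time grid (default: 10 evenly spaced times in
#'   (0, 30]).
#' @param x0 Initial state `c(x1, x2)`.
#' @param noise_sd Observation noise standard deviation.
#' @param noise_scale Multiplier on `noise_sd` (0 = noise-free test hook).
#' @return Numeric vector of x2 observations, one per entry of `times`.
#' @export
simulate_conversion <- function(theta, times = seq(3, 30, by = 3),
                                x0 = c(1, 0), noise_sd = 0.02, noise_scale = 1) {
  if (length(theta) != 2L) stop("simulate_conversion expects two rates")
  if (any(!is.finite(theta)) || any(theta <= 0)) stop("rates must be positive")
  total <- sum(x0)
  deriv <- function(t, y, parms) {
    list(-parms[1L] * y[1L] + parms[2L] * (total - y[1L]))
  }
  sol <- deSolve::ode(y = x0[1L], times = c(0, times), func = deriv,
                      parms = theta, rtol = 1e-8, atol = 1e-10)
  x2 <- total - sol[-1L, 2L]
  as.numeric(x2 + stats::rnorm(length(times), 0, noise_sd * noise_scale))
}
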