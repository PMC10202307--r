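# ABC-SMC engine: calibration, adaptive median thresholds, Gaussian-mixture
# proposals with twice the weighted empirical covariance, importance
# weighting, budget accounting, and orchestration of the adaptive-distance /
# summary-statistics / sensitivity-weight modes.

#' Calibrate the initial generation
#'
#' Samples `n_particles` parameters from the prior, simulates each (hard
#' simulator errors are resampled and counted against the budget), computes
#' the initial scale weights from these samples and sets the first threshold
#' to the median of the weighted distances. All calibration particles carry
#' importance weight `1/N`.
#'
#' @param problem A populated `abc_problem`.
#' @param n_particles Population size `N`.
#' @param p Minkowski order.
#' @param scale Scale estimator: `"mad"`, `"pcmad"` or `"none"`.
#' @return List with `thetas`, `data`, `distances`, `state`, `epsilon`,
#'   `weights` and `n_sims`.
#' @export
calibrate <- function(problem, n_particles, p = 1,
                      scale = c("mad", "pcmad", "none")) {
  scale <- match.arg(scale)
  problem <- get_problem(problem)
  if (is.null(problem$observed)) stop("problem has no observed data; use make_observed()")
  N <- as.integer(n_particles)
  stopifnot(N >= 2L)

  Theta <- sample_prior(problem$prior, N)
  sims <- 0L
  Y <- matrix(NA_real_, N, problem$n_y)
  for (i in seq_len(N)) {
    repeat {
      y <- tryCatch(problem$simulator(Theta[i, ]), error = function(e) NULL)
      sims <- sims + 1L
      if (!is.null(y)) break
      Theta[i, ] <- sample_prior(problem$prior, 1L)  # resample hard failures
    }
    Y[i, ] <- as.numeric(y)
  }

  sigma <- switch(scale,
    mad   = mad_scale(Y[rowSums(!is.finite(Y)) == 0L, , drop = FALSE]),
    pcmad = pcmad_scale(Y[rowSums(!is.finite(Y)) == 0L, , drop = FALSE], problem$observed),
    none  = rep(1, problem$n_y)
  )
  state <- distance_state(p = p, sigma = sigma, scale_kind = scale, t = 1L)
  d <- batch_distances(Y, problem$observed, state)
  eps <- next_epsilon(d)
  list(thetas = Theta, data = Y, distances = d, state = state,
       epsilon = eps, weights = rep(1 / N, N), n_sims = sims)
}

#' Next acceptance threshold
#'
#' The median of the (re-scored) accepted distances of the previous
#' generation; infinite sentinel distances are excluded.
#'
#' @param distances Non-empty numeric vector of distances.
#' @return The new threshold.
#' @export
next_epsilon <- function(distances) {
  d <- distances[is.finite(distances)]
  if (length(d) == 0L) stop("no finite distances to derive a threshold from")
  stats::median(d)
}

#' Build the Gaussian-mixture proposal from an accepted population
#'
#' The proposal is a mixture of Gaussian kernels centered at the accepted
#' parameters, with mixture weights equal to their normalized importance
#' weights and shared covariance equal to twice the weighted empirical
#' covariance of the population. A diagonal jitter of `1e-10 * max(trace, 1)`
#' is added (repeatedly if necessary) whenever the covariance is singular.
#'
#' @param thetas Matrix of accepted parameters (rows = particles).
#' @param weights Normalized importance weights (non-negative, positive sum).
#' @return Object of class `abc_proposal`.
#' @export
build_proposal <- function(thetas, weights) {
  thetas <- as.matrix(thetas)
  stopifnot(nrow(thetas) >= 2L, length(weights) == nrow(thetas),
            all(weights >= 0), sum(weights) > 0)
  W <- weights / sum(weights)
  mu <- colSums(W * thetas)
  Cn <- sweep(thetas, 2L, mu, `-`)
  Sigma <- 2 * crossprod(sqrt(W) * Cn)
  d <- ncol(thetas)
  jitter <- 1e-10 * max(sum(diag(Sigma)), 1)
  U <- NULL
  for (tries in 1:8) {
    U <- tryCatch(chol(Sigma + diag(jitter, d)), error = function(e) NULL)
    if (!is.null(U)) break
    jitter <- jitter * 100
  }
  if (is.null(U)) stop("proposal covariance could not be factorized")
  Sigma <- Sigma + diag(jitter, d)
  Sinv <- chol2inv(U)
  structure(list(centers = thetas, weights = W, Sigma = Sigma,
                 chol = U, Sinv = Sinv,
                 logdet = 2 * sum(log(diag(U))), d = d),
            class = "abc_proposal")
}

#' Log density of the mixture proposal
#'
#' @param proposal An `abc_proposal`.
#' @param thetas Parameter vector or matrix (rows = points).
#' @return Vector of log densities.
#' @export
proposal_log_density <- function(proposal, thetas) {
  stopifnot(inherits(proposal, "abc_proposal"))
  if (is.null(dim(thetas))) thetas <- matrix(thetas, nrow = 1L)
  B <- nrow(thetas)
  m <- nrow(proposal$centers)
  const <- -0.5 * (proposal$d * log(2 * pi) + proposal$logdet)
  logW <- log(proposal$weights)
  M <- matrix(NA_real_, B, m)
  for (j in seq_len(m)) {
    delta <- sweep(thetas, 2L, proposal$centers[j, ], `-`)
    maha <- rowSums((delta %*% proposal$Sinv) * delta)
    M[, j] <- logW[j] + const - 0.5 * maha
  }
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

# batch draw from the mixture with rejection outside the prior support;
# support rejections do not count as simulations
propose_batch <- function(proposal, prior, n, max_rejections = 1e6) {
  out <- matrix(NA_real_, n, proposal$d)
  need <- seq_len(n)
  rejected <- 0
  while (length(need) > 0L) {
    k <- length(need)
    idx <- sample.int(nrow(proposal$centers), k, replace = TRUE,
                      prob = proposal$weights)
    Z <- matrix(stats::rnorm(k * proposal$d), k, proposal$d) %*% proposal$chol
    cand <- proposal$centers[idx, , drop = FALSE] + Z
    ok <- prior_density(prior, cand) > 0
    out[need[ok], ] <- cand[ok, , drop = FALSE]
    rejected <- rejected + sum(!ok)
    if (rejected > max_rejections) {
      stop("too many proposals outside the prior support; prior/proposal mismatch")
    }
    need <- need[!ok]
  }
  out
}

#' Draw one parameter from the proposal and compute its importance weight
#'
#' Draws a mixture component by weight, perturbs it with the shared Gaussian
#' kernel, redraws until the prior density is positive, and returns the
#' parameter together with its unnormalized importance weight
#' `w = pi(theta) / g_t(theta)` (the mixture density is used untruncated). In
#' the first generation the proposal is the prior itself and `w = 1` exactly.
#'
#' @param proposal An `abc_proposal`, or `NULL` for the prior (generation 1).
#' @param prior An `abc_prior`.
#' @return List with elements `theta` and `weight`.
#' @export
propose_and_weight <- function(proposal, prior) {
  if (is.null(proposal)) {
    return(list(theta = as.numeric(sample_prior(prior, 1L)), weight = 1))
  }
  th <- propose_batch(proposal, prior, 1L)
  lw <- prior_density(prior, th, log = TRUE) - proposal_log_density(proposal, th)
  list(theta = as.numeric(th), weight = as.numeric(exp(lw)))
}

# simulate one row per parameter; hard errors become all-NA rows (infinite
# distance downstream)
simulate_rows <- function(simulator, Theta, n_y) {
  n <- nrow(Theta)
  Y <- matrix(NA_real_, n, n_y)
  for (i in seq_len(n)) {
    y <- tryCatch(simulator(Theta[i, ]), error = function(e) rep(NA_real_, n_y))
    Y[i, ] <- as.numeric(y)
  }
  Y
}

#' Run the ABC-SMC analysis
#'
#' Executes generations until the simulation budget is exhausted, the maximum
#' generation count is reached, or the threshold stagnates. Per generation the
#' engine (i) recomputes the scale weights from all particles (accepted and
#' rejected) of the previous generation, (ii) trains the inverse regression
#' model once the configured fraction of the budget is consumed and switches
#' to summary-statistic comparisons or attaches sensitivity weights, (iii)
#' re-scores the previous accepted particles under the new distance and sets
#' the threshold to their median, (iv) samples until `n_particles` acceptances
#' and (v) computes normalized importance weights.
#'
#' @param problem A populated `abc_problem` or a registered problem name (the
#'   latter must carry fixed observed data).
#' @param n_particles Population size `N` (accepted particles per generation).
#' @param budget Maximum total number of simulator calls.
#' @param p Minkowski order of the distance.
#' @param scale Adaptive scale estimator: `"mad"`, `"pcmad"` or `"none"`.
#' @param regression Optional [regression_spec()] enabling summary-statistics
#'   or sensitivity-weight mode.
#' @param seed Master seed; every source of randomness in the run derives
#'   from it, so identical configurations reproduce bit-identically.
#' @param max_generations Safety cap on the number of generations.
#' @param verbose Print one summary line per generation?
#' @return Object of class `abc_smc_result`: per-generation history (all
#'   particles, thresholds, weight vectors, simulation counts), the final
#'   weighted posterior sample (last complete generation), the trained
#'   regressor (if any) and accounting totals.
#' @export
abc_smc <- function(problem, n_particles, budget, p = 1,
                    scale = c("mad", "pcmad", "none"), regression = NULL,
                    seed = 1L, max_generations = 20L, verbose = FALSE) {
  scale <- match.arg(scale)
  problem <- get_problem(problem)
  if (is.null(problem$observed)) {
    stop("problem has no observed data; populate it with make_observed()")
  }
  if (!is.null(regression)) stopifnot(inherits(regression, "abc_regression_spec"))
  N <- as.integer(n_particles)
  budget <- as.integer(budget)
  stopifnot(N >= 2L, budget >= N)

  y_obs <- problem$observed
  prior <- problem$prior
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, max_generations + 1L)

  # generation 0: calibration
  set.seed(stage_seeds[1L])
  cal <- calibrate(problem, N, p = p, scale = scale)
  sims_total <- cal$n_sims
  history <- list(list(
    t = 0L, epsilon = cal$epsilon, sigma = cal$state$sigma, q = NULL,
    r = effective_weights(cal$state), scale_kind = scale, mode = "raw",
    n_sims = cal$n_sims, n_accepted = N, acceptance_rate = 1,
    thetas = cal$thetas, weights = cal$weights, distances = cal$distances,
    thetas_all = cal$thetas, distances_all = cal$distances,
    accepted = rep(TRUE, N), partial = FALSE
  ))
  prev <- list(Theta_all = cal$thetas, Y_all = cal$data,
               Theta_acc = cal$thetas, Y_acc = cal$data,
               W = cal$weights)
  proposal <- NULL
  reg <- NULL
  qvec <- NULL
  mode <- "raw"
  s_obs <- NULL
  trained <- FALSE
  eps_hist <- numeric(0)
  final_gen <- 0L
  partial_run <- FALSE

  scale_of <- function(M, ref) {
    ok <- rowSums(!is.finite(M)) == 0L
    Mf <- M[ok, , drop = FALSE]
    switch(scale,
      mad   = mad_scale(Mf),
      pcmad = pcmad_scale(Mf, ref),
      none  = rep(1, ncol(M)))
  }

  for (t in seq_len(max_generations)) {
    if (sims_total >= budget) break
    set.seed(stage_seeds[t + 1L])

    # (ii) one-shot regression training at the budget boundary
    if (!trained && !is.null(regression) &&
        should_train(sims_total, budget, regression)) {
      ok <- rowSums(!is.finite(prev$Y_all)) == 0L
      sigma_train <- mad_scale(prev$Y_all[ok, , drop = FALSE])
      reg <- fit_regressor(prev$Y_all, prev$Theta_all, regression,
                           sigma_train, generation = t)
      trained <- TRUE
      if (regression$mode == "statistics") {
        mode <- "stats"
        s_obs <- predict(reg, y_obs)
      } else {
        mode <- "sensi"
        sens_state <- compute_sensitivity_state(reg, y_obs, sigma_train,
                                                scale_kind = scale, p = p)
        qvec <- sens_state$q  # NULL on degenerate fallback
      }
    }

    # (i) scale update from ALL previous-generation particles
    if (mode == "stats") {
      ok <- rowSums(!is.finite(prev$Y_all)) == 0L
      S_all <- predict(reg, prev$Y_all[ok, , drop = FALSE])
      sigma <- scale_of(S_all, s_obs)
      state <- suppressWarnings(distance_state(p = p, sigma = sigma,
                                               scale_kind = scale, t = t))
      ref <- s_obs
      X_acc_prev <- predict(reg, prev$Y_acc)
    } else {
      sigma <- scale_of(prev$Y_all, y_obs)
      state <- suppressWarnings(distance_state(p = p, sigma = sigma, q = qvec,
                                               scale_kind = scale, t = t))
      ref <- y_obs
      X_acc_prev <- prev$Y_acc
    }

    # (iii) threshold: re-score previous accepted under the new distance
    eps <- next_epsilon(batch_distances(X_acc_prev, ref, state))

    # (iv) sample until N acceptances or budget exhaustion
    acc_theta <- matrix(NA_real_, N, n_par(prior))
    acc_Y <- matrix(NA_real_, N, problem$n_y)
    acc_d <- numeric(N)
    n_acc <- 0L
    gen_sims <- 0L
    all_theta <- list(); all_d <- list(); all_acc <- list(); all_Y <- list()

    while (n_acc < N && sims_total < budget) {
      rate_est <- if (gen_sims > 0L) max(n_acc / gen_sims, 0.02) else 0.5
      B <- ceiling((N - n_acc) / rate_est * 1.2)
      B <- min(max(B, 50L), 5000L, budget - sims_total)
      Theta_b <- if (is.null(proposal)) sample_prior(prior, B) else
        propose_batch(proposal, prior, B)
      Y_b <- simulate_rows(problem$simulator, Theta_b, problem$n_y)
      sims_total <- sims_total + B
      gen_sims <- gen_sims + B
      X_b <- if (mode == "stats") predict(reg, Y_b) else Y_b
      d_b <- batch_distances(X_b, ref, state)
      hit <- which(d_b <= eps & is.finite(d_b))
      take <- hit[seq_len(min(length(hit), N - n_acc))]
      acc_flag <- rep(FALSE, B)
      acc_flag[take] <- TRUE
      if (length(take) > 0L) {
        rows <- n_acc + seq_along(take)
        acc_theta[rows, ] <- Theta_b[take, , drop = FALSE]
        acc_Y[rows, ] <- Y_b[take, , drop = FALSE]
        acc_d[rows] <- d_b[take]
        n_acc <- n_acc + length(take)
      }
      all_theta[[length(all_theta) + 1L]] <- Theta_b
      all_Y[[length(all_Y) + 1L]] <- Y_b
      all_d[[length(all_d) + 1L]] <- d_b
      all_acc[[length(all_acc) + 1L]] <- acc_flag
    }

    Theta_all <- do.call(rbind, all_theta)
    Y_all <- do.call(rbind, all_Y)
    d_all <- unlist(all_d)
    acc_all <- unlist(all_acc)
    partial <- n_acc < N
    if (partial) {
      acc_theta <- acc_theta[seq_len(n_acc), , drop = FALSE]
      acc_Y <- acc_Y[seq_len(n_acc), , drop = FALSE]
      acc_d <- acc_d[seq_len(n_acc)]
    }

    # (v) importance weights: pi(theta) / g_t(theta), normalized
    W <- if (n_acc == 0L) numeric(0)
    else if (is.null(proposal)) rep(1 / n_acc, n_acc)
    else {
      lw <- prior_density(prior, acc_theta, log = TRUE) -
        proposal_log_density(proposal, acc_theta)
      w <- exp(lw - max(lw))
      w / sum(w)
    }

    history[[length(history) + 1L]] <- list(
      t = t, epsilon = eps, sigma = state$sigma, q = qvec,
      r = effective_weights(state), scale_kind = scale, mode = mode,
      n_sims = gen_sims, n_accepted = n_acc,
      acceptance_rate = if (gen_sims > 0L) n_acc / gen_sims else NA_real_,
      thetas = acc_theta, weights = W, distances = acc_d,
      thetas_all = Theta_all, distances_all = d_all, accepted = acc_all,
      partial = partial
    )
    if (verbose) {
      message(sprintf("gen %2d | eps %.6g | accepted %d/%d | acc rate %.3f | sims %d/%d%s",
                      t, eps, n_acc, N,
                      if (gen_sims > 0L) n_acc / gen_sims else NA_real_,
                      sims_total, budget, if (partial) " [partial]" else ""))
    }

    if (partial) { partial_run <- TRUE; break }
    final_gen <- t
    prev <- list(Theta_all = Theta_all, Y_all = Y_all,
                 Theta_acc = acc_theta, Y_acc = acc_Y, W = W)
    proposal <- build_proposal(acc_theta, W)

    eps_hist <- c(eps_hist, eps)
    nh <- length(eps_hist)
    if (nh >= 3L && all(abs(diff(eps_hist[(nh - 2L):nh])) <= 1e-12)) {
      warning("threshold stagnated for 3 generations; stopping early")
      break
    }
  }

  fin <- history[[final_gen + 1L]]
  structure(list(
    problem = problem$name,
    config = list(n_particles = N, budget = budget, p = p, scale = scale,
                  regression = regression, seed = seed,
                  max_generations = max_generations),
    history = history,
    epsilon_trajectory = vapply(history, `[[`, numeric(1L), "epsilon"),
    final = list(thetas = fin$thetas, weights = fin$weights,
                 generation = final_gen),
    regressor = reg,
    total_simulations = sims_total,
    n_generations = length(history) - 1L,
    partial = partial_run,
    ground_truth = problem$ground_truth,
    observed = y_obs
  ), class = "abc_smc_result")
}

#' Final weighted posterior sample of a run
#'
#' @param result An `abc_smc_result`.
#' @return List with `thetas` (matrix) and `weights` (normalized).
#' @export
final_sample <- function(result) {
  stopifnot(inherits(result, "abc_smc_result"))
  result$final
}

#' Importance-weighted posterior mean
#'
#' @param result An `abc_smc_result`.
#' @param transform Optional function applied to the parameter matrix before
#'   averaging (e.g. `function(th) th^2`).
#' @return Numeric vector of weighted means, one per parameter.
#' @export
posterior_mean <- function(result, transform = identity) {
  fin <- final_sample(result)
  M <- transform(fin$thetas)
  as.numeric(colSums(fin$weights * M))
}

#' @export
print.abc_smc_result <- function(x, ...) {
  cat(sprintf("ABC-SMC run on '%s': %d generations, %d simulations%s\n",
              x$problem, x$n_generations, x$total_simulations,
              if (x$partial) " (budget exhausted mid-generation)" else ""))
  cat("  epsilon trajectory:",
      paste(signif(x$epsilon_trajectory, 4), collapse = " -> "), "\n")
  cat(sprintf("  final sample: %d particles (generation %d)\n",
              nrow(x$final$thetas), x$final$generation))
  cat("  weighted posterior mean:",
      paste(signif(posterior_mean(x), 4), collapse = ", "), "\n")
  invisible(x)
}
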