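# Sensitivity weights: finite-difference Jacobian of the trained inverse
# regression map at the (normalized) observed data, column-normalized and
# summed per data coordinate. The weights quantify how informative each data
# coordinate is of (transformations of) the parameters and multiply the
# adaptive scale weights in the distance.

#' Central-difference Jacobian with automatic step selection
#'
#' Entry `(i, j)` approximates `df_j / dx_i` via central differences
#' `(f(x + h e_i) - f(x - h e_i)) / (2h)`. Per coordinate the difference
#' quotient is evaluated on a geometric step ladder
#' `h = h_factors * max(1, |x0_i|)`; the estimate kept is the smaller-step
#' member of the adjacent pair with the smallest relative discrepancy, a rule
#' robust to both truncation error (steps too large) and regressor noise
#' (steps too small).
#'
#' @param f Vector-valued function evaluable near `x0`.
#' @param x0 Point of evaluation.
#' @param h_factors Decreasing ladder of relative step sizes.
#' @return Object of class `abc_sensitivity_matrix`: list with `S`
#'   (`length(x0)` x `n_out` matrix, rows = inputs) and `steps` (chosen step
#'   per coordinate).
#' @export
central_jacobian <- function(f, x0, h_factors = c(1e-1, 1e-2, 1e-3)) {
  stopifnot(is.function(f), length(x0) >= 1L, length(h_factors) >= 1L)
  f0 <- f(x0)
  n_out <- length(f0)
  n_in <- length(x0)
  S <- matrix(NA_real_, n_in, n_out)
  steps <- numeric(n_in)

  for (i in seq_len(n_in)) {
    hs <- h_factors * max(1, abs(x0[i]))
    ests <- vector("list", length(hs))
    for (j in seq_along(hs)) {
      xp <- x0; xp[i] <- x0[i] + hs[j]
      xm <- x0; xm[i] <- x0[i] - hs[j]
      est <- (f(xp) - f(xm)) / (2 * hs[j])
      if (all(is.finite(est))) ests[[j]] <- est
    }
    valid <- which(!vapply(ests, is.null, logical(1L)))
    if (length(valid) == 0L) {
      stop(sprintf("function not finite at any trial step for coordinate %d", i))
    }
    if (length(valid) == 1L) {
      S[i, ] <- ests[[valid]]
      steps[i] <- hs[valid]
    } else {
      pairs <- valid[-length(valid)]
      disc <- vapply(seq_along(pairs), function(kk) {
        a <- ests[[valid[kk]]]; b <- ests[[valid[kk + 1L]]]
        sum(abs(a - b)) / (sum(abs(a)) + sum(abs(b)) + 1e-300)
      }, numeric(1L))
      best <- which.min(disc)
      pick <- valid[best + 1L]  # smaller step of the best adjacent pair
      S[i, ] <- ests[[pick]]
      steps[i] <- hs[pick]
    }
  }
  structure(list(S = S, steps = steps), class = "abc_sensitivity_matrix")
}

#' Per-coordinate sensitivity weights from a sensitivity matrix
#'
#' With `S` the input-by-target matrix of partial derivatives, the weight of
#' data coordinate `i` is the sum over targets of `|S|` normalized per target
#' (column) to unit absolute sum:
#' `q_i = sum_l |S_il| / sum_j |S_jl|`. Targets with zero total absolute
#' sensitivity are skipped (they contribute 0), which keeps the weights
#' conservative when the regression model finds no signal for a target. With
#' `normalize = FALSE` the raw row sums of `|S|` are returned instead.
#'
#' @param S An `abc_sensitivity_matrix` or a plain numeric matrix (rows =
#'   data coordinates, columns = targets).
#' @param normalize Normalize each target column to unit absolute sum?
#' @return Non-negative weight vector (one entry per data coordinate). All-zero
#'   sensitivities give an all-zero vector with a warning.
#' @export
sensitivity_weights <- function(S, normalize = TRUE) {
  if (inherits(S, "abc_sensitivity_matrix")) S <- S$S
  A <- abs(as.matrix(S))
  if (any(!is.finite(A))) stop("sensitivity matrix must be finite")
  if (normalize) {
    cs <- colSums(A)
    nz <- cs > 0
    A[, nz] <- sweep(A[, nz, drop = FALSE], 2L, cs[nz], `/`)
    A[, !nz] <- 0
  }
  q <- rowSums(A)
  if (all(q == 0)) warning("all sensitivities are zero; weights are degenerate")
  q
}

#' Sensitivity-weighted distance state
#'
#' Builds the map `f = predict o input-normalization`, evaluates its
#' central-difference Jacobian at the normalized observed data, derives the
#' sensitivity weights `q`, and returns a distance state with effective
#' weights `r = q / sigma`. `q` stays fixed for the rest of the run while
#' `sigma` keeps adapting per generation; dropped (zero-scale) regressor
#' coordinates get `q = 0`. When the distance uses PCMAD, PCMAD enters only
#' the `sigma` of `r`; the regressor inputs remain MAD-normalized, so outlier
#' correction does not inversely re-scale the sensitivities. If all
#' sensitivities are zero (degenerate regressor) the state falls back to
#' scale-only weights with a warning.
#'
#' @param reg A trained `abc_regressor`.
#' @param y_obs Observed data vector of length `n_y`.
#' @param sigma Current scale vector (MAD or PCMAD of the current generation).
#' @param scale_kind Scale estimator label carried by the state.
#' @param p Minkowski order.
#' @param normalize Per-target normalization of the sensitivities (see
#'   [sensitivity_weights()]).
#' @return An `abc_distance_state` with `q` attached (and attributes
#'   `sensitivity` = the [central_jacobian()] result).
#' @export
compute_sensitivity_state <- function(reg, y_obs, sigma,
                                      scale_kind = c("mad", "pcmad", "none"),
                                      p = 1, normalize = TRUE) {
  stopifnot(inherits(reg, "abc_regressor"))
  scale_kind <- match.arg(scale_kind)
  if (length(y_obs) != length(reg$input_scale)) {
    stop("y_obs length must match the regressor input dimension")
  }
  keep <- reg$keep
  x0 <- y_obs[keep] / reg$input_scale[keep]
  f <- function(z) predict_normalized(reg, z)
  jac <- central_jacobian(f, x0)

  S_full <- matrix(0, length(y_obs), reg$n_lambda)
  S_full[keep, ] <- jac$S
  q <- suppressWarnings(sensitivity_weights(S_full, normalize = normalize))
  if (all(q == 0)) {
    warning("degenerate regressor: all sensitivity weights are zero; falling back to scale-only weights")
    q <- NULL
  }
  st <- distance_state(p = p, sigma = sigma, q = q, scale_kind = scale_kind)
  attr(st, "sensitivity") <- structure(list(S = S_full, steps = jac$steps),
                                       class = "abc_sensitivity_matrix")
  st
}
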