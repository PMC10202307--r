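# Weighted Minkowski distances with adaptively updated scale weights.
# Effective per-coordinate weight: r_i = q_i / sigma_i (q_i = 1 when no
# sensitivity weights are in use); coordinates with zero scale get r_i = 0 and
# are thereby ignored in the comparison.

#' Weighted Minkowski distance
#'
#' Computes `( sum_i |r_i * (y_i - y_obs_i)|^p )^(1/p)` for order `p >= 1`.
#' Non-finite inputs yield `Inf` (a rejection sentinel) rather than an error,
#' so failed simulations are never accepted.
#'
#' @param y,y_obs Numeric vectors of equal length.
#' @param r Non-negative weight vector (recycled if scalar).
#' @param p Minkowski order, `p >= 1`.
#' @return A non-negative scalar distance (`Inf` for non-finite input).
#' @export
minkowski_distance <- function(y, y_obs, r = 1, p = 1) {
  if (length(y) != length(y_obs)) stop("y and y_obs must have equal length")
  if (p < 1) stop("Minkowski order p must be >= 1")
  if (length(r) == 1L) r <- rep(r, length(y))
  if (length(r) != length(y)) stop("weight vector r has wrong length")
  if (any(r < 0)) stop("weights must be non-negative")
  if (any(!is.finite(y)) || any(!is.finite(y_obs))) return(Inf)
  a <- abs(r * (y - y_obs))
  if (p == 1) sum(a) else sum(a^p)^(1 / p)
}

# vectorized distances of the rows of Y to y_obs under a distance state;
# non-finite rows map to Inf
batch_distances <- function(Y, y_obs, state) {
  r <- effective_weights(state)
  A <- abs(sweep(sweep(Y, 2L, y_obs, `-`), 2L, r, `*`))
  d <- if (state$p == 1) rowSums(A) else rowSums(A^state$p)^(1 / state$p)
  d[!is.finite(d)] <- Inf
  d
}

# column medians with the midpoint convention for even counts (stats::median)
.col_medians <- function(X) apply(X, 2L, stats::median)

#' Median absolute deviation per coordinate
#'
#' For each column of `samples`, the median of absolute deviations from the
#' column median (midpoint convention for even counts, no consistency
#' constant).
#'
#' @param samples Numeric matrix (rows = samples, columns = data coordinates);
#'   at least two rows.
#' @return Numeric vector of per-column MAD values.
#' @export
mad_scale <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L) stop("MAD needs at least two samples")
  apply(samples, 2L, function(x) stats::median(abs(x - stats::median(x))))
}

#' Outlier-robust combined scale (PCMAD) per coordinate
#'
#' Combines the within-sample MAD with MADO, the median absolute deviation of
#' the samples from the observed value, which measures bias towards the
#' observation. Per coordinate: `sigma = MAD` if `MADO <= MAD`, else
#' `MAD + MADO`. When simulations cannot reach an (outlier) observation, MADO
#' dominates and inflates the scale, damping that coordinate's weight.
#'
#' @inheritParams mad_scale
#' @param y_obs Observed data vector (one entry per column of `samples`).
#' @return Numeric vector of per-column PCMAD values, always `>=` [mad_scale()].
#' @export
pcmad_scale <- function(samples, y_obs) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L) stop("PCMAD needs at least two samples")
  if (length(y_obs) != ncol(samples)) stop("y_obs length must match the columns of samples")
  mad_v <- mad_scale(samples)
  mado <- vapply(seq_len(ncol(samples)), function(j) {
    stats::median(abs(samples[, j] - y_obs[j]))
  }, numeric(1L))
  ifelse(mado <= mad_v, mad_v, mad_v + mado)
}

#' Distance state: order, scale weights, sensitivity weights
#'
#' Bundles everything needed to evaluate the adaptive weighted distance of one
#' SMC generation: the Minkowski order `p`, the per-coordinate scale vector
#' `sigma`, optional sensitivity weights `q`, the scale estimator in use, and
#' the generation index.
#'
#' @param p Minkowski order (`>= 1`).
#' @param sigma Non-negative per-coordinate scale vector.
#' @param q Optional non-negative sensitivity weight vector (same length).
#' @param scale_kind One of `"mad"`, `"pcmad"`, `"none"`.
#' @param t Generation index.
#' @return Object of class `abc_distance_state`.
#' @export
distance_state <- function(p = 1, sigma, q = NULL,
                           scale_kind = c("mad", "pcmad", "none"), t = 0L) {
  scale_kind <- match.arg(scale_kind)
  stopifnot(p >= 1, is.numeric(sigma), all(sigma >= 0 | !is.finite(sigma)))
  if (!is.null(q)) {
    stopifnot(length(q) == length(sigma), all(q >= 0))
  }
  if (any(sigma == 0)) {
    warning(sprintf("%d coordinate(s) with zero scale get weight 0 and are ignored",
                    sum(sigma == 0)))
  }
  structure(list(p = p, sigma = as.numeric(sigma), q = q,
                 scale_kind = scale_kind, t = as.integer(t)),
            class = "abc_distance_state")
}

#' Effective distance weights of a state
#'
#' Returns `r = q / sigma` (with `q = 1` absent sensitivity weights);
#' coordinates with zero scale get `r = 0`.
#'
#' @param state An `abc_distance_state`.
#' @return Non-negative finite weight vector.
#' @export
effective_weights <- function(state) {
  stopifnot(inherits(state, "abc_distance_state"))
  q <- if (is.null(state$q)) rep(1, length(state$sigma)) else state$q
  ifelse(state$sigma > 0 & is.finite(state$sigma), q / state$sigma, 0)
}

#' Recompute scale weights from the previous generation
#'
#' Recomputes `sigma` from all simulated data vectors of the previous
#' generation (accepted and rejected particles alike) with the state's scale
#' estimator, keeping the sensitivity weights `q` fixed, and advances the
#' generation index.
#'
#' @param samples Matrix of all previous-generation simulations (rows =
#'   particles); non-finite rows are ignored.
#' @param y_obs Observed data vector.
#' @param state The current `abc_distance_state`.
#' @return The updated `abc_distance_state`.
#' @export
update_scale_weights <- function(samples, y_obs, state) {
  stopifnot(inherits(state, "abc_distance_state"))
  samples <- as.matrix(samples)
  ok <- rowSums(!is.finite(samples)) == 0L
  S <- samples[ok, , drop = FALSE]
  sigma <- switch(state$scale_kind,
    mad   = mad_scale(S),
    pcmad = pcmad_scale(S, y_obs),
    none  = rep(1, ncol(samples))
  )
  distance_state(p = state$p, sigma = sigma, q = state$q,
                 scale_kind = state$scale_kind, t = state$t + 1L)
}

#' @export
print.abc_distance_state <- function(x, ...) {
  cat(sprintf("Distance state (generation %d): L%g, scale = %s%s\n",
              x$t, x$p, x$scale_kind,
              if (is.null(x$q)) "" else ", with sensitivity weights"))
  cat("  effective weights r:", paste(signif(utils::head(effective_weights(x), 8L), 3),
                                      collapse = ", "),
      if (length(x$sigma) > 8L) "...\n" else "\n")
  invisible(x)
}
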