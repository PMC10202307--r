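# Inverse regression of (augmented) parameters on scale-normalized data.
# The fitted map serves either as summary statistics (its outputs replace the
# data in the distance) or as the function differentiated at the observed data
# to obtain sensitivity weights. Training happens once per run, at a
# configurable fraction of the simulation budget.

#' Regression model specification
#'
#' @param family `"linear"` (multi-output least squares) or `"nn"` (single
#'   hidden layer, ReLU activation, trained with ADAM and early stopping).
#' @param k Target augmentation degree: targets are the componentwise powers
#'   `(theta^1, ..., theta^k)`. `k = 1` regresses the plain parameters; `k = 4`
#'   is the "P4" augmentation that makes sign-symmetric parameters learnable
#'   through their even powers.
#' @param train_fraction Fraction of the total simulation budget after which
#'   the model is trained (0 = before the first generation, from calibration
#'   samples; default 0.4).
#' @param mode `"statistics"`: use model outputs as summary statistics;
#'   `"sensitivity"`: use the model only to derive sensitivity weights on the
#'   raw data.
#' @return Object of class `abc_regression_spec`.
#' @export
regression_spec <- function(family = c("linear", "nn"), k = 1L,
                            train_fraction = 0.4,
                            mode = c("statistics", "sensitivity")) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  stopifnot(k >= 1, k == floor(k), train_fraction >= 0, train_fraction < 1)
  structure(list(family = family, k = as.integer(k),
                 train_fraction = train_fraction, mode = mode),
            class = "abc_regression_spec")
}

#' Augment regression targets with componentwise powers
#'
#' Maps an `m x n_theta` matrix of parameters to the `m x (k * n_theta)` matrix
#' of componentwise powers, blocks ordered by power:
#' `(theta^1 | theta^2 | ... | theta^k)`.
#'
#' @param thetas Parameter matrix (rows = samples) or a single vector.
#' @param k Augmentation degree (`>= 1`).
#' @return Augmented target matrix.
#' @export
augment_targets <- function(thetas, k) {
  stopifnot(k >= 1, k == floor(k))
  if (is.null(dim(thetas))) thetas <- matrix(thetas, nrow = 1L)
  do.call(cbind, lapply(seq_len(k), function(j) thetas^j))
}

#' Should the regression model be trained at this generation boundary?
#'
#' True once the simulations used reach `train_fraction * budget` (and with
#' `train_fraction = 0` immediately, before the first generation). The caller
#' is responsible for training at most once per run.
#'
#' @param simulations_used Simulations consumed so far.
#' @param budget Total simulation budget (`> 0`).
#' @param spec An [regression_spec()] (or `NULL`, returning `FALSE`).
#' @return Logical.
#' @export
should_train <- function(simulations_used, budget, spec) {
  if (is.null(spec)) return(FALSE)
  stopifnot(budget > 0, simulations_used >= 0)
  simulations_used >= spec$train_fraction * budget
}

#' Fit the inverse regression model
#'
#' Fits one multi-output model jointly for all (augmented) targets. Inputs are
#' the raw simulations divided per coordinate by `sigma` (the MAD scale vector
#' of the training generation); coordinates with zero scale are dropped from
#' the regressor input and recorded. Targets are z-scored; a degenerate target
#' (zero spread) gets standard deviation 1 so that it contributes nothing
#' informative instead of producing NaNs. Rows with non-finite data are
#' dropped with a warning.
#'
#' @param Y Matrix of simulations (rows = particles, accepted and rejected).
#' @param thetas Matrix of the corresponding parameters.
#' @param spec An [regression_spec()].
#' @param sigma Scale vector of the training generation (length `ncol(Y)`).
#' @param generation Training generation index (metadata).
#' @return Object of class `abc_regressor` with a [predict()] method returning
#'   predictions on the z-scored target scale.
#' @export
fit_regressor <- function(Y, thetas, spec, sigma, generation = NA_integer_) {
  stopifnot(inherits(spec, "abc_regression_spec"))
  Y <- as.matrix(Y)
  thetas <- as.matrix(thetas)
  stopifnot(nrow(Y) == nrow(thetas), length(sigma) == ncol(Y))
  keep <- is.finite(sigma) & sigma > 0
  if (!any(keep)) stop("all data coordinates have zero scale; cannot train")

  L <- augment_targets(thetas, spec$k)
  ok <- rowSums(!is.finite(Y)) == 0L & rowSums(!is.finite(L)) == 0L
  if (!all(ok)) {
    warning(sprintf("dropping %d training row(s) with non-finite values", sum(!ok)))
    Y <- Y[ok, , drop = FALSE]
    L <- L[ok, , drop = FALSE]
  }
  if (nrow(Y) < 2L) stop("too few training samples after filtering")

  X <- sweep(Y[, keep, drop = FALSE], 2L, sigma[keep], `/`)
  target_mean <- colMeans(L)
  target_sd <- apply(L, 2L, stats::sd)
  target_sd[!is.finite(target_sd) | target_sd == 0] <- 1  # degenerate-target guard
  Z <- sweep(sweep(L, 2L, target_mean, `-`), 2L, target_sd, `/`)

  n_lambda <- ncol(Z)
  if (spec$family == "linear") {
    fit <- stats::lm.fit(cbind(1, X), Z)
    coefs <- as.matrix(fit$coefficients)
    coefs[is.na(coefs)] <- 0
    model <- list(coef = coefs)
  } else {
    # width floor guards low-dimensional problems against degenerate
    # single-unit networks
    hidden <- max(ceiling((ncol(Y) + n_lambda) / 2), 4L)
    model <- fit_mlp(X, Z, hidden = hidden)
  }

  fitted <- .predict_core(list(family = spec$family, model = model), X)
  rss <- colSums((Z - fitted)^2)
  tss <- colSums(sweep(Z, 2L, colMeans(Z))^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, NA_real_)

  structure(list(
    family = spec$family, k = spec$k, mode = spec$mode,
    n_y = ncol(Y) + 0L, n_theta = ncol(thetas), n_lambda = n_lambda,
    keep = keep, input_scale = as.numeric(sigma),
    target_mean = target_mean, target_sd = target_sd,
    model = model,
    meta = list(generation = generation, n_train = nrow(Y), r2 = r2)
  ), class = "abc_regressor")
}

# forward pass on already-normalized inputs (matrix in, matrix out)
.predict_core <- function(reg, X) {
  if (reg$family == "linear") {
    cbind(1, X) %*% reg$model$coef
  } else {
    mlp_forward(reg$model, X)
  }
}

#' Predict summary statistics from data
#'
#' Applies the trained inverse regression model to raw data vectors. Inputs
#' are normalized by the stored training scale (dropped coordinates ignored);
#' outputs stay on the z-scored target scale, which is the scale the adaptive
#' distance and the sensitivity analysis operate on.
#'
#' @param object An `abc_regressor`.
#' @param newdata A data vector of length `n_y`, or a matrix with one vector
#'   per row.
#' @param ... Unused.
#' @return Prediction vector of length `n_lambda` (or a matrix of them).
#' @export
predict.abc_regressor <- function(object, newdata, ...) {
  single <- is.null(dim(newdata))
  if (single) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(object$input_scale)) {
    stop(sprintf("data has %d coordinates, regressor expects %d",
                 ncol(newdata), length(object$input_scale)))
  }
  X <- sweep(newdata[, object$keep, drop = FALSE], 2L,
             object$input_scale[object$keep], `/`)
  out <- .predict_core(object, X)
  if (single) as.numeric(out) else out
}

# predictions from inputs already on the normalized (kept-coordinate) scale;
# used by the finite-difference sensitivity analysis
predict_normalized <- function(reg, x) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1L)
  out <- .predict_core(reg, x)
  if (single) as.numeric(out) else out
}

#' @export
print.abc_regressor <- function(x, ...) {
  cat(sprintf("Inverse regression model (%s): %d inputs (%d used) -> %d targets (k = %d)\n",
              x$family, x$n_y, sum(x$keep), x$n_lambda, x$k))
  cat(sprintf("  trained on %d samples (generation %s); training R2: %s\n",
              x$meta$n_train, x$meta$generation,
              paste(signif(x$meta$r2, 3), collapse = ", ")))
  invisible(x)
}

#' Serializable summary of a trained regressor
#'
#' Flattens the trained model (family, dimensions, coefficients or layer
#' shapes, per-target training R-squared) into plain lists for the JSON
#' results store.
#'
#' @param reg An `abc_regressor`.
#' @return A named list.
#' @export
regressor_summary <- function(reg) {
  stopifnot(inherits(reg, "abc_regressor"))
  out <- list(family = reg$family, k = reg$k, mode = reg$mode,
              n_y = reg$n_y, n_used = sum(reg$keep), n_lambda = reg$n_lambda,
              n_train = reg$meta$n_train, generation = reg$meta$generation,
              train_r2 = as.numeric(reg$meta$r2))
  if (reg$family == "linear") {
    out$coefficients <- unname(as.matrix(reg$model$coef))
  } else {
    out$layer_shapes <- list(dim(reg$model$W1), dim(reg$model$W2))
  }
  out
}
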