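#' Independent marginal priors
#'
#' A prior is a product of independent one-dimensional marginals, each either
#' uniform or Gaussian. `prior_uniform()` and `prior_normal()` build one
#' marginal; `prior_spec()` assembles marginals into a prior over the full
#' parameter vector.
#'
#' @param lower,upper Support bounds of a uniform marginal (`lower < upper`).
#' @param mean Mean of a Gaussian marginal.
#' @param var Variance (not standard deviation) of a Gaussian marginal; must be
#'   positive.
#' @return An object of class `abc_margin` (one marginal) or `abc_prior`.
#' @examples
#' pr <- prior_spec(prior_uniform(-1, 1), prior_normal(0, 4))
#' th <- sample_prior(pr, 5)
#' prior_density(pr, th)
#' @export
prior_uniform <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1L,
            length(upper) == 1L, is.finite(lower), is.finite(upper))
  if (!(lower < upper)) stop("uniform marginal requires lower < upper")
  structure(list(family = "uniform", a = lower, b = upper), class = "abc_margin")
}

#' @rdname prior_uniform
#' @export
prior_normal <- function(mean, var) {
  stopifnot(is.numeric(mean), is.numeric(var), length(mean) == 1L,
            length(var) == 1L, is.finite(mean), is.finite(var))
  if (!(var > 0)) stop("normal marginal requires variance > 0")
  structure(list(family = "normal", a = mean, b = var), class = "abc_margin")
}

#' @param ... Marginals created by [prior_uniform()] or [prior_normal()], or a
#'   single list of such marginals.
#' @rdname prior_uniform
#' @export
prior_spec <- function(...) {
  margins <- list(...)
  if (length(margins) == 1L && is.list(margins[[1L]]) &&
      !inherits(margins[[1L]], "abc_margin")) {
    margins <- margins[[1L]]
  }
  if (length(margins) == 0L) stop("prior needs at least one marginal")
  ok <- vapply(margins, inherits, logical(1L), what = "abc_margin")
  if (!all(ok)) stop("all prior components must be abc_margin objects")
  structure(list(margins = margins, n_par = length(margins)), class = "abc_prior")
}

#' Number of parameters of a prior
#' @param prior An `abc_prior`.
#' @export
n_par <- function(prior) {
  stopifnot(inherits(prior, "abc_prior"))
  prior$n_par
}

#' Sample parameter vectors from a prior
#'
#' @param prior An `abc_prior`.
#' @param n Number of draws.
#' @return An `n` x `n_par` numeric matrix, one draw per row.
#' @export
sample_prior <- function(prior, n) {
  stopifnot(inherits(prior, "abc_prior"), n >= 1)
  cols <- lapply(prior$margins, function(m) {
    switch(m$family,
      uniform = stats::runif(n, m$a, m$b),
      normal  = stats::rnorm(n, m$a, sqrt(m$b))
    )
  })
  matrix(unlist(cols), nrow = n, ncol = prior$n_par)
}

#' Evaluate a prior density
#'
#' @param prior An `abc_prior`.
#' @param theta A parameter vector, or a matrix with one parameter vector per
#'   row.
#' @param log Return the log density?
#' @return A numeric vector of (log) densities, zero (`-Inf`) outside uniform
#'   support.
#' @export
prior_density <- function(prior, theta, log = FALSE) {
  stopifnot(inherits(prior, "abc_prior"))
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1L)
  if (ncol(theta) != prior$n_par) {
    stop(sprintf("theta has %d columns, prior has %d parameters",
                 ncol(theta), prior$n_par))
  }
  ld <- numeric(nrow(theta))
  for (j in seq_len(prior$n_par)) {
    m <- prior$margins[[j]]
    ld <- ld + switch(m$family,
      uniform = stats::dunif(theta[, j], m$a, m$b, log = TRUE),
      normal  = stats::dnorm(theta[, j], m$a, sqrt(m$b), log = TRUE)
    )
  }
  if (log) ld else exp(ld)
}

#' @export
print.abc_prior <- function(x, ...) {
  cat(sprintf("Independent prior over %d parameter(s):\n", x$n_par))
  for (j in seq_along(x$margins)) {
    m <- x$margins[[j]]
    if (m$family == "uniform") {
      cat(sprintf("  theta%d ~ U[%g, %g]\n", j, m$a, m$b))
    } else {
      cat(sprintf("  theta%d ~ N(%g, %g)\n", j, m$a, m$b))
    }
  }
  invisible(x)
}
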