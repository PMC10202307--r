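# Registry of benchmark inference problems. Each problem bundles a prior, a
# stochastic simulator theta -> data vector of fixed length n_y, the observed
# data (fixed by construction or generated from a ground truth), and optional
# ground-truth parameters.

#' Construct a problem specification
#'
#' @param name Identifier string.
#' @param prior An [prior_spec()] object.
#' @param simulator Function `theta -> numeric(n_y)`.
#' @param n_y Data dimension.
#' @param observed Observed data vector of length `n_y`, or `NULL` if it is to
#'   be generated via [make_observed()].
#' @param ground_truth Optional true parameter vector (length `n_par(prior)`).
#' @param fixed_observed Is the observed vector part of the problem definition
#'   (as opposed to simulated from the ground truth)?
#' @return An object of class `abc_problem`.
#' @export
problem_spec <- function(name, prior, simulator, n_y, observed = NULL,
                         ground_truth = NULL, fixed_observed = FALSE) {
  stopifnot(is.character(name), inherits(prior, "abc_prior"),
            is.function(simulator), n_y >= 1)
  if (!is.null(observed) && length(observed) != n_y) {
    stop(sprintf("observed has length %d, expected n_y = %d", length(observed), n_y))
  }
  if (!is.null(ground_truth) && length(ground_truth) != n_par(prior)) {
    stop("ground_truth length must match the prior dimension")
  }
  structure(list(name = name, prior = prior, simulator = simulator,
                 n_y = as.integer(n_y), observed = observed,
                 ground_truth = ground_truth,
                 fixed_observed = isTRUE(fixed_observed)),
            class = "abc_problem")
}

#' @export
print.abc_problem <- function(x, ...) {
  cat(sprintf("ABC problem '%s': n_theta = %d, n_y = %d\n",
              x$name, n_par(x$prior), x$n_y))
  if (!is.null(x$ground_truth)) {
    cat("  ground truth:", paste(signif(x$ground_truth, 4), collapse = ", "), "\n")
  }
  cat(if (is.null(x$observed)) "  observed: <not yet generated>\n" else
        sprintf("  observed: %d values (%s)\n", x$n_y,
                if (x$fixed_observed) "fixed" else "simulated"))
  invisible(x)
}

# builders for the registered problems; each returns an abc_problem with
# observed = NULL unless the observed vector is part of the definition
.problem_builders <- list(
  demo = function() {
    problem_spec(
      name = "demo",
      prior = prior_spec(prior_uniform(-7, 7), prior_uniform(-700, 700),
                         prior_uniform(-700, 700), prior_uniform(-1, 1)),
      simulator = function(theta) simulate_demo(theta),
      n_y = 17L,
      observed = c(0, 0, rep(0, 4), 0.7, rep(0, 10)),
      fixed_observed = TRUE
    )
  },
  quadratic = function() {
    problem_spec(
      name = "quadratic",
      prior = prior_spec(prior_uniform(-1, 1)),
      simulator = function(theta) simulate_quadratic(theta),
      n_y = 1L,
      observed = 0.7,
      fixed_observed = TRUE
    )
  },
  gauss = function() {
    # conjugate Gaussian toy: prior N(0,1), y ~ N(theta, 1), y_obs = 1,
    # analytic posterior N(0.5, 0.5); used for engine validation
    problem_spec(
      name = "gauss",
      prior = prior_spec(prior_normal(0, 1)),
      simulator = function(theta) stats::rnorm(1L, theta, 1),
      n_y = 1L,
      observed = 1,
      fixed_observed = TRUE
    )
  },
  T1 = function() {
    problem_spec(
      name = "T1",
      prior = prior_spec(prior_uniform(0, 0.4), prior_uniform(0, 0.4)),
      simulator = function(theta) simulate_conversion(theta),
      n_y = 10L,
      ground_truth = c(0.08, 0.12)
    )
  },
  T2 = function() {
    problem_spec(
      name = "T2",
      prior = prior_spec(prior_normal(0, 100^2)),
      simulator = function(theta) simulate_t2(theta),
      n_y = 2L,
      ground_truth = 3
    )
  },
  T3 = function() {
    problem_spec(
      name = "T3",
      prior = prior_spec(prior_uniform(0, 10), prior_uniform(0, 10),
                         prior_uniform(0, 10), prior_uniform(0, 10)),
      simulator = function(theta) simulate_gk_order_stats(theta, 1000L, 7L),
      n_y = 7L,
      ground_truth = c(3, 1, 2, 0.5)
    )
  },
  T4 = function() {
    problem_spec(
      name = "T4",
      prior = prior_spec(prior_uniform(0, 2), prior_uniform(0, 0.1),
                         prior_uniform(0, 1)),
      simulator = function(theta) {
        gillespie_lv(theta, x0 = c(50, 100),
                     obs_times = seq_len(16L) * 20 / 16, max_events = 1e6)
      },
      n_y = 32L,
      ground_truth = c(0.5, 0.0025, 0.3)
    )
  },
  T5 = function() {
    problem_spec(
      name = "T5",
      prior = prior_spec(prior_uniform(0, 10), prior_uniform(0, 10),
                         prior_uniform(0, 10), prior_uniform(0, 10)),
      simulator = function(theta) simulate_gk_order_stats(theta, 10000L, 100L),
      n_y = 100L,
      ground_truth = c(3, 1, 2, 0.5)
    )
  },
  T6 = function() {
    problem_spec(
      name = "T6",
      prior = prior_spec(prior_uniform(0, 2), prior_uniform(0, 0.1),
                         prior_uniform(0, 1)),
      simulator = function(theta) {
        gillespie_lv(theta, x0 = c(50, 100),
                     obs_times = seq_len(100L) / 5, max_events = 1e6)
      },
      n_y = 200L,
      ground_truth = c(0.5, 0.0025, 0.3)
    )
  }
)

#' List registered benchmark problems
#' @return Character vector of problem names.
#' @export
list_problems <- function() names(.problem_builders)

#' Retrieve a registered problem definition
#'
#' Returns the problem with its fixed observed data if the problem defines one
#' (demo, quadratic, gauss), otherwise with `observed = NULL`; use
#' [make_observed()] to populate it.
#'
#' @param name Problem name (see [list_problems()]).
#' @return An `abc_problem`.
#' @export
get_problem <- function(name) {
  if (inherits(name, "abc_problem")) return(name)
  if (!is.character(name) || length(name) != 1L || !name %in% names(.problem_builders)) {
    stop(sprintf("unknown problem '%s'; registered problems: %s",
                 paste(name, collapse = ","),
                 paste(list_problems(), collapse = ", ")))
  }
  .problem_builders[[name]]()
}

#' Populate a problem with observed data
#'
#' For problems whose observed vector is part of the definition the fixed
#' vector is returned unchanged. Otherwise the observed data are one simulator
#' draw at `theta_true` (default: the registered ground truth) under `seed`,
#' and the ground truth is recorded in the returned problem.
#'
#' @param name Problem name or `abc_problem`.
#' @param theta_true Optional true parameter vector; must lie in the prior
#'   support.
#' @param seed Seed for the observed-data draw.
#' @return A fully populated `abc_problem`.
#' @export
make_observed <- function(name, theta_true = NULL, seed = 1L) {
  prob <- get_problem(name)
  if (prob$fixed_observed) return(prob)
  if (is.null(theta_true)) theta_true <- prob$ground_truth
  if (is.null(theta_true)) stop("problem has no registered ground truth; supply theta_true")
  if (length(theta_true) != n_par(prob$prior)) {
    stop("theta_true length must match the prior dimension")
  }
  if (prior_density(prob$prior, theta_true) <= 0) {
    stop("theta_true lies outside the prior support")
  }
  set.seed(seed)
  y <- prob$simulator(theta_true)
  if (length(y) != prob$n_y || any(!is.finite(y))) {
    stop("simulator did not return n_y finite values at theta_true")
  }
  prob$observed <- as.numeric(y)
  prob$ground_truth <- as.numeric(theta_true)
  prob
}

#' Export observed data and ground truth as CSV
#'
#' Writes a one-row CSV with header `y1, ..., y<n_y>` (and a second file
#' `<path>_truth.csv` when a ground truth is recorded).
#'
#' @param problem A populated `abc_problem`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_observed <- function(problem, path) {
  stopifnot(inherits(problem, "abc_problem"), !is.null(problem$observed))
  obs <- as.data.frame(as.list(stats::setNames(problem$observed,
                                               paste0("y", seq_len(problem$n_y)))))
  utils::write.csv(obs, path, row.names = FALSE)
  if (!is.null(problem$ground_truth)) {
    tr <- as.data.frame(as.list(stats::setNames(
      problem$ground_truth, paste0("theta", seq_along(problem$ground_truth)))))
    utils::write.csv(tr, sub("\\.csv$", "_truth.csv", path), row.names = FALSE)
  }
  invisible(path)
}
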