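# Experiment workbench: method-name grammar, configuration handling, results
# storage (diffable CSV + JSON), replicate orchestration and the weighted
# RMSE evaluation metric.

#' Weighted root-mean-square error against ground truth
#'
#' Per parameter `j`: `sqrt( sum_i w_i * (theta_ij - truth_j)^2 )` over the
#' weighted posterior sample.
#'
#' @param samples `m x n_theta` matrix of posterior draws.
#' @param weights Non-negative weights summing to 1 (tolerance `1e-6`).
#' @param theta_true True parameter vector.
#' @return Non-negative RMSE vector, one entry per parameter.
#' @export
weighted_rmse <- function(samples, weights, theta_true) {
  samples <- as.matrix(samples)
  stopifnot(nrow(samples) == length(weights),
            ncol(samples) == length(theta_true), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-6) {
    stop(sprintf("weights must sum to 1 (got %.8f)", sum(weights)))
  }
  sq <- sweep(samples, 2L, theta_true, `-`)^2
  sqrt(as.numeric(colSums(weights * sq)))
}

#' Parse a method-name string
#'
#' Method labels compose from the tokens `L<p>` (Minkowski order),
#' `Ada.+MAD` / `Ada.+PCMAD` (adaptive scale normalization), `Stat{LR,NN}`
#' (regression-based summary statistics), `Sensi{LR,NN}` (regression-based
#' sensitivity weights), `P4` (augmented regression targets
#' `(theta^1, ..., theta^4)`) and `Init` (train before the first generation
#' instead of after 40% of the budget). Examples:
#' `"L1+Ada.+MAD"`, `"L1+StatLR"`, `"L1+Ada.+MAD+SensiLR+P4"`,
#' `"L1+Ada.+PCMAD+StatNN+Init"`.
#'
#' @param method Method label string.
#' @return List with `p`, `scale` (`"mad"`, `"pcmad"`, `"none"`) and
#'   `regression` (a [regression_spec()] or `NULL`).
#' @export
parse_method <- function(method) {
  stopifnot(is.character(method), length(method) == 1L)
  tokens <- strsplit(method, "+", fixed = TRUE)[[1L]]
  fail <- function() {
    stop(sprintf(paste0(
      "cannot parse method '%s'; valid labels compose L<p> [+Ada.+MAD|+Ada.+PCMAD]",
      " [+Stat{LR,NN}|+Sensi{LR,NN}] [+P4] [+Init], e.g. \"L1+Ada.+MAD\",",
      " \"L1+StatLR\", \"L1+Ada.+MAD+SensiLR+P4\""), method))
  }
  if (length(tokens) == 0L || !grepl("^L[0-9]+$", tokens[1L])) fail()
  p <- as.numeric(sub("^L", "", tokens[1L]))
  if (p < 1) fail()
  tokens <- tokens[-1L]

  scale <- "none"
  mode <- NULL; family <- NULL; k <- 1L; train_fraction <- 0.4
  i <- 1L
  while (i <= length(tokens)) {
    tok <- tokens[i]
    if (tok == "Ada.") {
      if (i == length(tokens) || !tokens[i + 1L] %in% c("MAD", "PCMAD")) fail()
      scale <- tolower(tokens[i + 1L])
      i <- i + 2L
    } else if (grepl("^(Stat|Sensi)(LR|NN)$", tok)) {
      if (!is.null(mode)) fail()
      mode <- if (startsWith(tok, "Stat")) "statistics" else "sensitivity"
      family <- if (endsWith(tok, "LR")) "linear" else "nn"
      i <- i + 1L
    } else if (grepl("^P[0-9]+$", tok)) {
      k <- as.integer(sub("^P", "", tok))
      if (k < 1L) fail()
      i <- i + 1L
    } else if (tok == "Init") {
      train_fraction <- 0
      i <- i + 1L
    } else {
      fail()
    }
  }
  if (is.null(mode) && (k > 1L || train_fraction == 0)) fail()
  regression <- if (is.null(mode)) NULL else {
    regression_spec(family = family, k = k, train_fraction = train_fraction,
                    mode = mode)
  }
  list(p = p, scale = scale, regression = regression)
}

#' List example method labels
#' @return Character vector of representative method names.
#' @export
list_methods <- function() {
  c("L1", "L1+Ada.+MAD", "L1+Ada.+PCMAD",
    "L1+StatLR", "L1+StatNN",
    "L1+Ada.+MAD+StatLR", "L1+Ada.+MAD+StatNN",
    "L1+Ada.+MAD+StatLR+P4", "L1+Ada.+MAD+StatNN+P4",
    "L1+Ada.+MAD+SensiLR", "L1+Ada.+MAD+SensiNN",
    "L1+Ada.+MAD+SensiLR+P4", "L1+Ada.+MAD+SensiNN+P4",
    "L1+Ada.+MAD+StatLR+Init", "L1+Ada.+MAD+SensiLR+Init")
}

.known_config_keys <- c("problem", "method", "n_particles", "budget", "seed",
                        "data_seed", "theta_true", "max_generations", "outdir",
                        "verbose")

# normalize a config given as list or YAML path; unknown keys are an error
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s (known: %s)",
                 paste(unknown, collapse = ", "),
                 paste(.known_config_keys, collapse = ", ")))
  }
  required <- c("problem", "method", "n_particles", "budget", "seed")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0L) {
    stop(sprintf("config is missing required key(s): %s",
                 paste(missing, collapse = ", ")))
  }
  if (is.null(config$max_generations)) config$max_generations <- 20L
  if (is.null(config$data_seed)) {
    config$data_seed <- (as.integer(config$seed) %% 2147483646L) + 1L
  }
  config
}

#' Run a configured experiment
#'
#' Resolves the problem (generating observed data from the ground truth under
#' `data_seed` unless the problem fixes them), parses the method label, runs
#' [abc_smc()], evaluates the weighted RMSE when a ground truth is available,
#' and, if `outdir` is set, writes a results store: one CSV per generation
#' (particle id, parameters, weight, distance, accepted flag), JSON metadata
#' (config echo, thresholds, scale/sensitivity/effective weight vectors,
#' simulation counts, regressor summary) and a plain-text log with one line
#' per generation and one per weight-vector update.
#'
#' @param config A named list or path to a YAML file with keys `problem`,
#'   `method`, `n_particles`, `budget`, `seed` and optionally `data_seed`,
#'   `theta_true`, `max_generations`, `outdir`, `verbose`.
#' @param outdir Output directory (overrides the config entry); `NULL` skips
#'   writing.
#' @return Object of class `abc_run`: the [abc_smc()] result plus `rmse` and
#'   the echoed config.
#' @export
run_experiment <- function(config, outdir = NULL) {
  config <- read_run_config(config)
  if (!is.null(outdir)) config$outdir <- outdir
  parsed <- parse_method(config$method)
  problem <- get_problem(config$problem)
  if (is.null(problem$observed)) {
    problem <- make_observed(problem, theta_true = config$theta_true,
                             seed = config$data_seed)
  }
  res <- abc_smc(problem,
                 n_particles = config$n_particles, budget = config$budget,
                 p = parsed$p, scale = parsed$scale,
                 regression = parsed$regression,
                 seed = config$seed,
                 max_generations = config$max_generations,
                 verbose = isTRUE(config$verbose))
  rmse <- if (!is.null(res$ground_truth)) {
    weighted_rmse(res$final$thetas, res$final$weights, res$ground_truth)
  } else NULL
  run <- structure(list(config = config, result = res, rmse = rmse),
                   class = "abc_run")
  if (!is.null(config$outdir)) write_result_store(run, config$outdir)
  run
}

#' @export
print.abc_run <- function(x, ...) {
  cat(sprintf("Experiment: problem '%s', method '%s'\n",
              x$config$problem, x$config$method))
  print(x$result)
  if (!is.null(x$rmse)) {
    cat("  weighted RMSE vs ground truth:",
        paste(signif(x$rmse, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

# full-precision numeric formatting so the CSV store round-trips bit-exactly
.fmt <- function(x) vapply(x, function(v) {
  if (is.na(v)) NA_character_ else sprintf("%.17g", v)
}, character(1L))

#' Write a run to a results store directory
#'
#' @param run An `abc_run` from [run_experiment()].
#' @param outdir Directory to create/populate.
#' @return `outdir`, invisibly.
#' @export
write_result_store <- function(run, outdir) {
  stopifnot(inherits(run, "abc_run"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- run$result
  log_lines <- character(0)
  d <- ncol(res$final$thetas)
  for (gen in res$history) {
    Theta <- as.matrix(gen$thetas_all)
    acc <- gen$accepted
    wt <- rep(NA_real_, nrow(Theta))
    if (gen$n_accepted > 0L) {
      # accepted rows in simulation order correspond to weight entries in order
      wt[which(acc)] <- gen$weights
    }
    df <- data.frame(particle = seq_len(nrow(Theta)))
    for (j in seq_len(d)) df[[paste0("theta", j)]] <- .fmt(Theta[, j])
    df$weight <- .fmt(wt)
    df$distance <- .fmt(gen$distances_all)
    df$accepted <- acc
    utils::write.csv(df, file.path(outdir, sprintf("generation_%02d.csv", gen$t)),
                     row.names = FALSE)
    log_lines <- c(log_lines,
      sprintf("gen %d: eps=%.8g accepted=%d sims=%d acc_rate=%.4f mode=%s%s",
              gen$t, gen$epsilon, gen$n_accepted, gen$n_sims,
              gen$acceptance_rate, gen$mode,
              if (isTRUE(gen$partial)) " [partial]" else ""),
      sprintf("gen %d: weights updated (scale=%s, zero-scale coords=%d)%s",
              gen$t, gen$scale_kind, sum(gen$sigma == 0),
              if (is.null(gen$q)) "" else " [sensitivity weights active]"))
  }
  meta <- list(
    config = run$config[setdiff(names(run$config), "outdir")],
    problem = res$problem,
    epsilon_trajectory = res$epsilon_trajectory,
    generations = lapply(res$history, function(g) {
      list(t = g$t, epsilon = g$epsilon, n_sims = g$n_sims,
           n_accepted = g$n_accepted, acceptance_rate = g$acceptance_rate,
           mode = g$mode, sigma = g$sigma, q = g$q, r = g$r,
           partial = g$partial)
    }),
    total_simulations = res$total_simulations,
    final_generation = res$final$generation,
    partial = res$partial,
    ground_truth = res$ground_truth,
    rmse = run$rmse,
    regressor = if (is.null(res$regressor)) NULL else regressor_summary(res$regressor)
  )
  jsonlite::write_json(meta, file.path(outdir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, file.path(outdir, "log.txt"))
  invisible(outdir)
}

#' Reload the final weighted sample from a results store
#'
#' @param outdir A directory written by [write_result_store()].
#' @return List with `thetas`, `weights`, `metadata`.
#' @export
load_result <- function(outdir) {
  meta <- jsonlite::read_json(file.path(outdir, "metadata.json"),
                              simplifyVector = TRUE)
  gen <- meta$final_generation
  df <- utils::read.csv(file.path(outdir, sprintf("generation_%02d.csv", gen)))
  acc <- df[df$accepted, , drop = FALSE]
  th_cols <- grep("^theta", names(df), value = TRUE)
  thetas <- vapply(acc[, th_cols, drop = FALSE], as.numeric, numeric(nrow(acc)))
  thetas <- matrix(as.numeric(thetas), nrow = nrow(acc))
  list(thetas = thetas, weights = as.numeric(acc$weight), metadata = meta)
}

#' Replicate an experiment across seeds and data sets
#'
#' Runs the configured experiment once per replicate, each on freshly
#' generated observed data (the replicate seed is used both as sampler seed
#' and data seed, so replicates vary data set and sampler stream), and
#' aggregates per-parameter RMSE across replicates by the median and the
#' median absolute deviation.
#'
#' @param config As in [run_experiment()] (the problem must have a ground
#'   truth, i.e. not the fixed-data problems).
#' @param n_replicates Number of replicates (`>= 1`).
#' @param seeds Optional vector of seeds, one per replicate (default:
#'   `config$seed + 0:(n-1)`).
#' @return List with `table` (one row per (method, problem, parameter):
#'   median RMSE and MAD across replicates) and `rmse` (the replicate-by-
#'   parameter RMSE matrix).
#' @export
replicate_runs <- function(config, n_replicates, seeds = NULL) {
  stopifnot(n_replicates >= 1L)
  config <- read_run_config(config)
  if (is.null(seeds)) seeds <- as.integer(config$seed) + seq_len(n_replicates) - 1L
  stopifnot(length(seeds) == n_replicates)
  rmse <- NULL
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- seeds[i]
    cfg$data_seed <- seeds[i]
    cfg$outdir <- NULL
    run <- run_experiment(cfg)
    if (is.null(run$rmse)) stop("replicate_runs requires a problem with ground truth")
    rmse <- rbind(rmse, run$rmse)
  }
  med <- apply(rmse, 2L, stats::median)
  mad_repl <- apply(rmse, 2L, function(x) stats::median(abs(x - stats::median(x))))
  tab <- data.frame(
    method = config$method, problem = config$problem,
    parameter = paste0("theta", seq_len(ncol(rmse))),
    median_rmse = as.numeric(med), mad_rmse = as.numeric(mad_repl),
    n_replicates = n_replicates, stringsAsFactors = FALSE
  )
  list(table = tab, rmse = unname(rmse))
}
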