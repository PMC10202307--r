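test_that("weighted RMSE evaluates the defining formula", {
  expect_equal(weighted_rmse(matrix(c(0, 2)), c(0.5, 0.5), 1), 1)
  expect_equal(weighted_rmse(matrix(c(1, 1, 1)), rep(1 / 3, 3), 1), 0)
  expect_equal(weighted_rmse(matrix(c(3, 99)), c(1, 0), 1), 2)
  # multi-parameter case against direct evaluation
  S <- matrix(c(0, 2, 1, 5), 2, 2)
  w <- c(0.25, 0.75)
  expect_equal(weighted_rmse(S, w, c(1, 2)),
               sqrt(c(0.25 * 1 + 0.75 * 1, 0.25 * 1 + 0.75 * 9)))
  expect_error(weighted_rmse(matrix(c(0, 2)), c(0.6, 0.6), 1), "sum to 1")
})

test_that("the method-name grammar parses the published labels", {
  m <- parse_method("L1+Ada.+MAD+SensiLR+P4")
  expect_equal(m$p, 1)
  expect_equal(m$scale, "mad")
  expect_equal(m$regression$mode, "sensitivity")
  expect_equal(m$regression$family, "linear")
  expect_equal(m$regression$k, 4L)
  expect_equal(m$regression$train_fraction, 0.4)

  m2 <- parse_method("L1+StatLR")
  expect_equal(m2$scale, "none")
  expect_equal(m2$regression$mode, "statistics")
  expect_equal(m2$regression$k, 1L)

  m3 <- parse_method("L1+Ada.+PCMAD+StatNN+Init")
  expect_equal(m3$scale, "pcmad")
  expect_equal(m3$regression$family, "nn")
  expect_equal(m3$regression$train_fraction, 0)

  m4 <- parse_method("L2+Ada.+MAD")
  expect_equal(m4$p, 2)
  expect_null(m4$regression)

  expect_error(parse_method("L1+Bogus"), "valid labels")
  expect_error(parse_method("L1+P4"), "valid labels")      # P4 needs a regressor
  expect_error(parse_method("Ada.+MAD"), "valid labels")   # missing norm token
  expect_true(all(vapply(list_methods(),
                         function(s) is.list(parse_method(s)), logical(1))))
})

test_that("experiments run from config, store, and reload bit-identically", {
  outdir <- file.path(tempdir(), "wb_store")
  unlink(outdir, recursive = TRUE)
  cfg <- list(problem = "quadratic", method = "L1+Ada.+MAD",
              n_particles = 60, budget = 1000, seed = 17)
  run <- run_experiment(cfg, outdir = outdir)
  expect_s3_class(run, "abc_run")
  # store layout
  expect_true(file.exists(file.path(outdir, "metadata.json")))
  expect_true(file.exists(file.path(outdir, "log.txt")))
  gen_files <- list.files(outdir, pattern = "^generation_\\d+\\.csv$")
  expect_equal(length(gen_files), run$result$n_generations + 1L)
  # log: one summary and one weight-update line per generation
  log <- readLines(file.path(outdir, "log.txt"))
  expect_equal(sum(grepl("eps=", log)), run$result$n_generations + 1L)
  expect_equal(sum(grepl("weights updated", log)), run$result$n_generations + 1L)
  # round trip: stored final population reloads bit-identically
  back <- load_result(outdir)
  expect_identical(back$thetas, unname(run$result$final$thetas))
  expect_identical(back$weights, unname(run$result$final$weights))
  # rerun with the same config reproduces the stored populations
  run2 <- run_experiment(cfg)
  expect_identical(run2$result$final$thetas, run$result$final$thetas)
  # config validation
  expect_error(run_experiment(c(cfg, list(bogus = 1))), "unknown config key")
  expect_error(run_experiment(cfg[-1]), "missing required")
  expect_error(run_experiment(within(cfg, method <- "L9+Magic")), "valid labels")
})

test_that("YAML config files drive the same run", {
  path <- file.path(tempdir(), "run.yaml")
  writeLines(c("problem: quadratic", "method: L1+Ada.+MAD",
               "n_particles: 60", "budget: 1000", "seed: 17"), path)
  run_yaml <- run_experiment(path)
  run_list <- run_experiment(list(problem = "quadratic", method = "L1+Ada.+MAD",
                                  n_particles = 60, budget = 1000, seed = 17))
  expect_identical(run_yaml$result$final, run_list$result$final)
})

test_that("replicates vary the data set and aggregate by median and MAD", {
  cfg <- list(problem = "T2", method = "L1+Ada.+MAD",
              n_particles = 60, budget = 1200, seed = 5)
  agg <- replicate_runs(cfg, n_replicates = 3)
  expect_equal(dim(agg$rmse), c(3L, 1L))
  expect_equal(nrow(agg$table), 1L)   # one row per (method, problem, parameter)
  expect_equal(agg$table$parameter, "theta1")
  expect_equal(agg$table$median_rmse, stats::median(agg$rmse[, 1]))
  expect_equal(agg$table$mad_rmse,
               oracle_median(abs(agg$rmse[, 1] - oracle_median(agg$rmse[, 1]))))
  # a single replicate aggregates to that run's RMSE
  one <- replicate_runs(cfg, n_replicates = 1)
  single <- run_experiment(within(cfg, data_seed <- 5))
  expect_equal(one$table$median_rmse, as.numeric(single$rmse))
  expect_true(all(agg$table$median_rmse >= 0))
})
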