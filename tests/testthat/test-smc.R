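test_that("calibration sets the threshold to the median weighted distance", {
  set.seed(81)
  cal <- calibrate("gauss", n_particles = 100, p = 1, scale = "mad")
  expect_equal(cal$epsilon, stats::median(cal$distances))
  expect_equal(cal$weights, rep(1 / 100, 100))
  expect_equal(cal$n_sims, 100L)
  set.seed(81)
  cal2 <- calibrate("gauss", n_particles = 100, p = 1, scale = "mad")
  expect_identical(cal$distances, cal2$distances)
})

test_that("threshold updates use the midpoint median convention", {
  expect_equal(next_epsilon(c(1, 2, 3)), 2)
  expect_equal(next_epsilon(c(1, 2, 3, 4)), 2.5)
  expect_equal(next_epsilon(c(7, 7, 7)), 7)
  expect_equal(next_epsilon(c(2, Inf, 4)), 3)  # sentinels excluded
  expect_error(next_epsilon(rep(Inf, 3)), "finite")
})

test_that("the proposal is a Gaussian mixture with twice the weighted covariance", {
  # two equally weighted 1-D particles at 0 and 2: weighted var 1, Sigma = 2
  pr <- build_proposal(matrix(c(0, 2)), c(0.5, 0.5))
  expect_equal(pr$Sigma[1, 1], 2, tolerance = 1e-8)
  # identical particles: jitter-only diagonal, still factorizable
  prj <- build_proposal(matrix(c(1, 1, 1)), rep(1 / 3, 3))
  expect_lt(prj$Sigma[1, 1], 1e-8)
  expect_true(is.finite(proposal_log_density(prj, 1)))
  # mixture density integrates to 1 (1-D quadrature)
  set.seed(82)
  pr2 <- build_proposal(matrix(rnorm(30)), runif(30))
  dens <- function(x) exp(proposal_log_density(pr2, matrix(x, ncol = 1)))
  expect_equal(stats::integrate(function(x) vapply(x, dens, numeric(1)),
                                -15, 15)$value, 1, tolerance = 1e-5)
})

test_that("proposal draws respect the prior support and the importance identity", {
  set.seed(83)
  prior <- prior_spec(prior_uniform(0, 1))
  centers <- matrix(runif(40, 0.4, 0.6))
  pr <- build_proposal(centers, rep(1 / 40, 40))
  draws <- replicate(300, propose_and_weight(pr, prior)$theta)
  expect_true(all(draws >= 0 & draws <= 1))
  # generation 1: proposal is the prior itself and w = 1 exactly
  expect_identical(propose_and_weight(NULL, prior)$weight, 1)
  # E_g[pi/g] = 1 for a proper prior when g covers the prior mass
  set.seed(84)
  prior_n <- prior_spec(prior_normal(0, 1))
  centers_n <- matrix(rnorm(100, 0, 1.4))
  pr_n <- build_proposal(centers_n, rep(0.01, 100))
  w <- vapply(seq_len(4000), function(i) propose_and_weight(pr_n, prior_n)$weight,
              numeric(1))
  expect_equal(mean(w), 1, tolerance = 0.1)
})

test_that("the engine recovers the conjugate Gaussian posterior", {
  r <- abc_smc("gauss", n_particles = 1000, budget = 10000, seed = 3)
  m <- posterior_mean(r)
  v <- posterior_mean(r, function(t) t^2) - m^2
  expect_equal(m, 0.5, tolerance = 0.05)   # analytic posterior N(0.5, 0.5)
  expect_equal(v, 0.5, tolerance = 0.15)
})

test_that("engine bookkeeping: budget, weights, threshold decay, reproducibility", {
  r1 <- abc_smc("gauss", n_particles = 150, budget = 4000, seed = 11)
  r2 <- abc_smc("gauss", n_particles = 150, budget = 4000, seed = 11)
  # bit-exact reproducibility under a fixed seed
  expect_identical(r1$final, r2$final)
  expect_identical(r1$epsilon_trajectory, r2$epsilon_trajectory)
  # exact simulation accounting
  expect_equal(sum(vapply(r1$history, `[[`, numeric(1), "n_sims")),
               r1$total_simulations)
  expect_lte(r1$total_simulations, 4000)
  # normalized importance weights sum to one
  for (gen in r1$history) {
    if (gen$n_accepted > 0) expect_lt(abs(sum(gen$weights) - 1), 1e-12)
    expect_equal(sum(gen$accepted), gen$n_accepted)
    # calibration (t = 0) has no threshold constraint; later generations do
    if (gen$t > 0 && !gen$partial) expect_true(all(gen$distances <= gen$epsilon))
  }
  # thresholds decrease on a continuous-distance problem (generation 1 shares
  # the calibration threshold by construction)
  expect_true(all(diff(r1$epsilon_trajectory[-1]) < 0))
  # a different seed gives a different run
  r3 <- abc_smc("gauss", n_particles = 150, budget = 4000, seed = 12)
  expect_false(identical(r1$final$thetas, r3$final$thetas))
})

test_that("mid-run statistics training switches the comparison space", {
  spec <- regression_spec("linear", k = 1, train_fraction = 0.4,
                          mode = "statistics")
  prob <- make_observed("T2", seed = 9)
  r <- abc_smc(prob, n_particles = 150, budget = 6000, regression = spec, seed = 4)
  modes <- vapply(r$history, `[[`, character(1), "mode")
  expect_true("raw" %in% modes && "stats" %in% modes)
  expect_false(is.null(r$regressor))
  # statistics distances live in the 1-dimensional target space
  last <- r$history[[length(r$history)]]
  expect_length(last$sigma, 1L)
  # the run still concentrates near the true parameter
  expect_lt(abs(posterior_mean(r) - prob$ground_truth), 1.5)
})

test_that("sensitivity mode attaches fixed q while sigma keeps adapting", {
  spec <- regression_spec("linear", k = 1, train_fraction = 0.3,
                          mode = "sensitivity")
  prob <- make_observed("T2", seed = 9)
  r <- abc_smc(prob, n_particles = 150, budget = 6000, regression = spec, seed = 4)
  qs <- lapply(r$history, `[[`, "q")
  active <- which(!vapply(qs, is.null, logical(1)))
  expect_gt(length(active), 1L)
  # q is frozen after training
  for (i in active[-1]) expect_identical(qs[[i]], qs[[active[1]]])
  # sigma still adapts between those generations
  sig <- lapply(r$history, `[[`, "sigma")
  expect_false(identical(sig[[active[1]]], sig[[active[2]]]))
  # the informative coordinate dominates the effective weights
  rlast <- r$history[[length(r$history)]]$r
  expect_gt(rlast[1], rlast[2])
})

test_that("budget exhaustion mid-generation is flagged and the run degrades gracefully", {
  r <- suppressWarnings(abc_smc("quadratic", n_particles = 200, budget = 500, seed = 5))
  expect_lte(r$total_simulations, 500)
  # final sample comes from the last complete generation
  expect_equal(nrow(r$final$thetas), 200L)
  expect_lt(abs(sum(r$final$weights) - 1), 1e-12)
})
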