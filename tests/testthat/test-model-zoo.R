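test_that("registered problems have the advertised dimensions", {
  dims <- list(demo = c(4L, 17L), quadratic = c(1L, 1L), T1 = c(2L, 10L),
               T2 = c(1L, 2L), T3 = c(4L, 7L), T4 = c(3L, 32L),
               T5 = c(4L, 100L), T6 = c(3L, 200L))
  for (nm in names(dims)) {
    prob <- get_problem(nm)
    expect_equal(n_par(prob$prior), dims[[nm]][1L], info = nm)
    expect_equal(prob$n_y, dims[[nm]][2L], info = nm)
  }
  expect_error(get_problem("nope"), "unknown problem")
})

test_that("demonstration simulator matches its block structure", {
  set.seed(1)
  expect_length(simulate_demo(c(0, 0, 0, 0)), 17L)
  expect_error(simulate_demo(c(1, 2, 3)), "length 4")
  # noise-free limit exposes the means of every block
  y <- simulate_demo(c(1, 2, 3, 0.5), noise_scale = 0)
  expect_equal(y, c(1, 2, 3, 3, 3, 3, 0.25, rep(0, 10)))
  # y4 is centered at theta4^2 (Monte-Carlo check at theta4 = 0.5)
  y4 <- replicate(5000, simulate_demo(c(0, 0, 0, 0.5))[7L])
  se <- 0.1 / sqrt(5000)
  expect_lt(abs(mean(y4) - 0.25), 3 * se)
  # y3 block has sd 200 and y5 sd sqrt(10) (variance notation)
  Y <- t(replicate(4000, simulate_demo(c(0, 0, 0, 0))))
  expect_equal(stats::sd(Y[, 3]), 200, tolerance = 0.1)
  expect_equal(stats::sd(Y[, 10]), sqrt(10), tolerance = 0.1)
})

test_that("quadratic toy is sign-symmetric with observed value 0.7", {
  expect_equal(simulate_quadratic(0.5, noise_scale = 0), 0.25)
  expect_equal(simulate_quadratic(-0.5, noise_scale = 0), 0.25)
  prob <- get_problem("quadratic")
  expect_equal(prob$observed, 0.7)
})

test_that("T2 simulator separates informative and uninformative coordinates", {
  expect_equal(simulate_t2(3, noise_scale = 0), c(3, 0))
  set.seed(4)
  y2 <- replicate(20000, simulate_t2(0)[2L])
  # variance of the background coordinate is 1 within Monte-Carlo error
  se <- sqrt(2 / 20000)  # var of sample variance of N(0,1)
  expect_lt(abs(stats::var(y2) - 1), 3 * se)
  expect_length(get_problem("T2")$simulator(0.5), 2L)
})

test_that("g-and-k quantile function reduces correctly and matches direct evaluation", {
  expect_equal(gk_quantile(0.5, A = 3, B = 1, g = 2, k = 0.5), 3)
  # g = k = 0 collapses to the normal quantile A + B z
  p <- c(0.1, 0.25, 0.9)
  expect_equal(gk_quantile(p, A = 2, B = 3, g = 0, k = 0),
               2 + 3 * qnorm(p), tolerance = 1e-12)
  # direct evaluation of the quantile formula at z = 1
  z <- 1
  expected <- 3 + 1 * (1 + 0.8 * (1 - exp(-2 * z)) / (1 + exp(-2 * z))) *
    (1 + z^2)^0.5 * z
  expect_equal(gk_quantile(pnorm(1), A = 3, B = 1, g = 2, k = 0.5), expected)
  expect_equal(expected, 5.276, tolerance = 1e-3)
  expect_error(gk_quantile(0, 1, 1, 0, 0), "strictly in")
  expect_error(gk_quantile(0.5, 1, -1, 0, 0), "positive")
})

test_that("g-and-k order statistics are sorted, sized, and normal at g = k = 0", {
  set.seed(7)
  y <- get_problem("T5")$simulator(c(3, 1, 2, 0.5))
  expect_length(y, 100L)
  expect_true(!is.unsorted(y))
  expect_error(simulate_gk_order_stats(c(3, 1, 0, 0), 10, 20), "exceed")
  # at (3,1,0,0) the median order statistic concentrates at 3
  med <- replicate(200, simulate_gk_order_stats(c(3, 1, 0, 0), 1001L, 1L))
  expect_equal(mean(med), 3, tolerance = 0.05)
  # KS: g = k = 0 draws are N(A, B^2)
  x <- gk_quantile(stats::runif(10000), A = 3, B = 2, g = 0, k = 0)
  expect_gt(stats::ks.test(x, "pnorm", 3, 2)$p.value, 0.01)
})

test_that("Gillespie Lotka-Volterra simulation is exact", {
  # all-zero rates freeze the state
  y <- gillespie_lv(c(0, 0, 0), c(5, 7), obs_times = c(1, 2, 3))
  expect_equal(y, c(5, 5, 5, 7, 7, 7))
  # pure-death expectation 100 * exp(-0.3) at t = 1
  set.seed(2)
  m <- mean(replicate(4000, gillespie_lv(c(0, 0, 0.3), c(0, 100), obs_times = 1)[2L]))
  se <- sqrt(100 * exp(-0.3) * (1 - exp(-0.3)) / 4000)
  expect_lt(abs(m - 100 * exp(-0.3)), 3 * se)
  # T6 registration: 200 non-negative integer counts
  set.seed(3)
  y6 <- get_problem("T6")$simulator(c(0.5, 0.0025, 0.3))
  expect_length(y6, 200L)
  expect_true(all(y6 >= 0) && all(y6 == floor(y6)))
  expect_error(gillespie_lv(c(-1, 0, 0)), "non-negative")
  # event cap returns the NA sentinel rather than hanging
  capped <- gillespie_lv(c(2, 0, 0), c(50, 0), obs_times = 20, max_events = 100)
  expect_true(all(is.na(capped)))
  expect_true(isTRUE(attr(capped, "capped")))
})

test_that("conversion ODE simulator follows the closed-form solution", {
  times <- seq(3, 30, by = 3)
  y <- simulate_conversion(c(0.1, 0.1), noise_scale = 0)
  expect_length(y, 10L)
  expect_equal(y, 0.5 * (1 - exp(-0.2 * times)), tolerance = 1e-6)
  # one-way conversion: x2(t) = 1 - exp(-theta1 t) in the theta2 -> 0 limit
  y1 <- simulate_conversion(c(0.2, 1e-12), noise_scale = 0)
  expect_equal(y1, 1 - exp(-0.2 * times), tolerance = 1e-4)
  th <- c(0.07, 0.21)
  expect_equal(simulate_conversion(th, noise_scale = 0),
               oracle_conversion_x2(th, times), tolerance = 1e-6)
  expect_error(simulate_conversion(c(0, 0.1)), "positive")
})

test_that("make_observed fixes, reproduces and validates observed data", {
  demo <- make_observed("demo")
  expect_equal(demo$observed, c(rep(0, 6), 0.7, rep(0, 10)))
  a <- make_observed("T2", seed = 5)
  b <- make_observed("T2", seed = 5)
  expect_identical(a$observed, b$observed)
  expect_false(identical(a$observed, make_observed("T2", seed = 6)$observed))
  t6 <- make_observed("T6", theta_true = c(0.5, 0.0025, 0.3), seed = 1)
  expect_length(t6$observed, 200L)
  expect_true(all(t6$observed >= 0))
  expect_error(make_observed("T2", theta_true = c(1, 2)), "length")
  expect_error(make_observed("T1", theta_true = c(1, 1)), "support")
})

test_that("observed data export writes a one-row CSV with coordinate names", {
  prob <- make_observed("T2", seed = 5)
  path <- file.path(tempdir(), "t2_obs.csv")
  export_observed(prob, path)
  df <- read.csv(path)
  expect_equal(names(df), c("y1", "y2"))
  expect_equal(as.numeric(df[1, ]), prob$observed, tolerance = 1e-12)
  tr <- read.csv(file.path(tempdir(), "t2_obs_truth.csv"))
  expect_equal(as.numeric(tr[1, ]), 3)
})
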