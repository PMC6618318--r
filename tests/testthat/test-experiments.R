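test_that("bootstrap intervals behave at the degenerate and nominal ends", {
  set.seed(1)
  ci1 <- bootstrap_ci(5)
  expect_equal(unname(ci1), c(5, 5, 5))
  expect_true(all(is.na(bootstrap_ci(NA_real_))))
  x <- rnorm(50, mean = 3)
  for (type in c("basic", "percentile")) {
    ci <- bootstrap_ci(x, type = type)
    expect_lte(ci[["lower"]], ci[["mean"]])
    expect_gte(ci[["upper"]], ci[["mean"]])
  }
})

test_that("bootstrap CI coverage of a known mean is near nominal", {
  set.seed(99)
  n_trials <- 500
  hits <- 0L
  for (i in seq_len(n_trials)) {
    x <- rnorm(40, mean = 2, sd = 1)
    ci <- bootstrap_ci(x, n_boot = 400)
    if (ci[["lower"]] <= 2 && 2 <= ci[["upper"]]) hits <- hits + 1L
  }
  expect_gte(hits / n_trials, 0.93)
  expect_lte(hits / n_trials, 0.97)
})

test_that("Monte-Carlo summaries aggregate replicate life histories", {
  env <- environment_spec(R_hat = 2.0, A = 0.3)
  mc1 <- run_monte_carlo(p_default, env, n_reps = 1, seed = 5,
                         n_boot = 50, keep_records = TRUE)
  one <- mc1$records[[1]]
  s <- mc1$summary
  expect_equal(s$mean[s$statistic == "R0"], one$LRO)
  expect_equal(s$mean[s$statistic == "life_expectancy_yr"],
               one$death_age_yr)
  expect_equal(s$lower[s$statistic == "R0"], s$upper[s$statistic == "R0"])
  # extreme disturbance: nothing weaned, degenerate CI at zero
  dead <- run_monte_carlo(p_default,
                          environment_spec(R_hat = 1.8,
                                           disturbance_days = 200),
                          n_reps = 4, seed = 5, n_boot = 50)
  r0 <- dead$summary[dead$summary$statistic == "R0", ]
  expect_equal(r0$mean, 0)
  expect_equal(r0$lower, 0)
  expect_equal(r0$upper, 0)
})

test_that("age at first reproduction does not vary across random replicates", {
  env <- environment_spec(R_hat = 2.0, A = 0.3)
  mc <- run_monte_carlo(p_default, env, n_reps = 15, seed = 3, n_boot = 50)
  afr <- mc$replicates$AfR_yr
  afr <- afr[!is.na(afr)]       # females dying before first birth excluded
  expect_gt(length(afr), 5)
  expect_equal(stats::var(afr), 0)
})

test_that("Monte-Carlo runs are reproducible and order-independent", {
  env <- environment_spec(R_hat = 2.0, A = 0.3, disturbance_days = 15,
                          disturbance_season = "winter")
  a <- run_monte_carlo(p_default, env, n_reps = 6, seed = 21, n_boot = 50)
  b <- run_monte_carlo(p_default, env, n_reps = 6, seed = 21, n_boot = 50)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$summary, b$summary)
  # replicate streams depend on (seed, cell, rep) only: the first replicates
  # of a longer run coincide with those of a shorter run
  c4 <- run_monte_carlo(p_default, env, n_reps = 4, seed = 21, n_boot = 50)
  expect_identical(c4$replicates[, -1], a$replicates[1:4, -1])
})

test_that("threshold estimator finds the replacement crossing", {
  d <- seq(0, 50, by = 5)
  # exact line R0 = 2 - d/10 crosses 1 at d = 10
  th <- estimate_threshold(d, 2 - d / 10)
  expect_equal(th$threshold_days, 10, tolerance = 0.01)
  # all means above replacement: sentinel
  expect_true(is.na(estimate_threshold(d, 2 + d * 0)$threshold_days))
  # known noiseless monotone curve: recovered within half the grid step
  r0 <- 2.2 / (1 + exp((d - 22) / 6))
  true_cross <- 22 + 6 * log(2.2 - 1)
  th2 <- estimate_threshold(d, r0)
  expect_lt(abs(th2$threshold_days - true_cross), 2.5)
  expect_error(estimate_threshold(c(0, 10, 5, 20), c(2, 1.5, 1.8, 0.5)),
               "sorted")
  expect_error(estimate_threshold(c(0, 5, 10), c(2, 1.5, 1)), "4 grid")
})

test_that("mini factorial sweep produces per-cell rows and thresholds", {
  res <- run_sweep(p_default, R_hat = 2.0, A = 0.3,
                   durations = c(0, 40), seasons = "winter",
                   n_reps = 2, seed = 9, n_boot = 20)
  expect_equal(nrow(res$summary), 2 * 6)   # 2 cells x 6 statistics
  expect_setequal(unique(res$summary$duration), c(0, 40))
  # too few durations for a spline: threshold is the NA sentinel
  expect_equal(nrow(res$thresholds), 1)
  expect_true(is.na(res$thresholds$threshold_days))
  # identical reruns
  res2 <- run_sweep(p_default, R_hat = 2.0, A = 0.3,
                    durations = c(0, 40), seasons = "winter",
                    n_reps = 2, seed = 9, n_boot = 20)
  expect_identical(res$summary, res2$summary)
})

test_that("derived substream seeds stay in range and separate coordinates", {
  s <- vapply(0:200, function(r) derive_seed(1, 3, r), 0L)
  expect_true(all(s >= 1 & s <= 2147483646))
  expect_equal(anyDuplicated(s), 0L)
  expect_false(derive_seed(1, 1, 2) == derive_seed(1, 2, 1))
})
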