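test_that("undisturbed fixed-mode life weans 11 calves; rich resources add one", {
  life <- baseline_life()
  expect_equal(life$n_weaned, 11)
  expect_equal(life$LRO, 5.5)
  rich <- simulate_life(p_default, environment_spec(R_hat = 5.0))
  expect_equal(rich$n_weaned, 12)
  # permanent disturbance: no intake, death long before any weaning
  starved <- simulate_life(p_default,
                           environment_spec(R_hat = 1.8,
                                            disturbance_days = 365))
  expect_equal(starved$n_weaned, 0)
  expect_lt(starved$death_age_yr, 10)
})

test_that("reproductive timing: waiting, gestation and the 81-d gap", {
  life <- baseline_life()
  # first conception T_D after the first threshold crossing, birth T_P later
  expect_equal(life$AfR,
               life$first_crossing_age_yr + (p_default$T_D + p_default$T_P) / 365,
               tolerance = 1e-5)
  # adult cycles: conception follows the previous weaning by exactly 81 d
  conceptions <- life$birth_ages_yr[-1] * 365 - p_default$T_P
  weanings <- life$weaning_ages_yr[seq_along(conceptions)]
  gaps <- conceptions - weanings * 365
  expect_equal(gaps[-1], rep(81, length(gaps) - 1), tolerance = 1e-3)
  # minimum inter-birth interval (81 + 365 + 1223)/365 yr
  expect_equal(min(life$IBI), (81 + 365 + 1223) / 365, tolerance = 1e-4)
  expect_true(all(life$IBI >= (81 + 365 + 1223) / 365 - 1e-6))
  # weaning follows birth by the lactation period
  expect_equal(life$weaning_ages_yr - life$birth_ages_yr[1:11],
               rep(p_default$T_L / 365, 11), tolerance = 1e-5)
})

test_that("step refinement leaves outcomes and event times unchanged", {
  life1 <- simulate_life(p_default, env_baseline, dt = 0.25)
  life2 <- simulate_life(p_default, env_baseline, dt = 0.125)
  expect_equal(life1$n_weaned, life2$n_weaned)
  tol_yr <- 0.1 / 365
  expect_lt(max(abs(life1$birth_ages_yr - life2$birth_ages_yr)), tol_yr)
  expect_lt(max(abs(life1$weaning_ages_yr - life2$weaning_ages_yr)), tol_yr)
  expect_lt(abs(life1$death_age_yr - life2$death_age_yr), tol_yr)
})

test_that("daily explicit-Euler oracle reproduces the compiled integrator", {
  for (d in c(0, 15, 20)) {
    eu <- euler_life(p_default, dist_days = d)
    rk <- simulate_life(p_default,
                        environment_spec(R_hat = 1.8, disturbance_days = d))
    expect_lte(abs(eu$n_weaned - rk$n_weaned), 1)
    expect_lt(abs(eu$death_age_yr - rk$death_age_yr), 1)
  }
})

test_that("adult reserve trajectory settles into a periodic orbit", {
  life <- baseline_life()
  tr <- life$trajectory
  F_at_birth <- stats::approx(tr$age_yr, tr$F,
                              xout = life$birth_ages_yr)$y
  gaps <- abs(diff(F_at_birth))
  # contraction from cycle to cycle, and late cycles essentially periodic
  expect_true(all(diff(gaps) < 1e-3))
  expect_lt(gaps[5], gaps[1] / 10)
  expect_lt(max(tail(gaps, 2)), 0.1)
})

test_that("calves run a higher body condition than their mother", {
  tr <- baseline_life()$trajectory
  lact <- !is.na(tr$calf_condition) & tr$calf_age_d > 60
  expect_gt(mean(tr$calf_condition[lact] > tr$condition[lact]), 0.95)
  expect_equal(max(tr$calf_condition, na.rm = TRUE), 0.305,
               tolerance = 0.01)
})

test_that("random-mode simulations are exactly reproducible by seed", {
  env <- environment_spec(R_hat = 2.0, A = 0.3, disturbance_days = 20,
                          disturbance_season = "winter")
  a <- simulate_life(p_default, env, mode = "random", seed = 42)
  b <- simulate_life(p_default, env, mode = "random", seed = 42)
  expect_identical(a$death_age_yr, b$death_age_yr)
  expect_identical(a$birth_ages_yr, b$birth_ages_yr)
  expect_identical(a$n_weaned, b$n_weaned)
  c <- simulate_life(p_default, env, mode = "random", seed = 43)
  expect_false(identical(a$death_age_yr, c$death_age_yr))
  expect_error(simulate_life(p_default, env, mode = "random"), "seed")
})

test_that("trajectory records phases, flows and calf columns", {
  life <- baseline_life()
  tr <- life$trajectory
  expect_true(all(c("t", "age_yr", "phase", "F", "condition", "survival",
                    "I_R", "C_M", "C_G", "C_P", "C_L", "net",
                    "calf_F", "calf_I_L", "R_eff") %in% names(tr)))
  expect_setequal(as.character(unique(tr$phase)),
                  c("RESTING", "WAITING", "PREGNANT", "LACTATING",
                    "LACTATING_WAITING"))
  expect_true(all(diff(tr$survival) <= 1e-12))   # survival nonincreasing
  expect_true(all(tr$C_P[tr$phase == "PREGNANT"] >= 0))
  expect_true(all(is.na(tr$calf_F[tr$phase %in% c("RESTING", "WAITING")])))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(life, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(tr))
  expect_error(write_trajectory(simulate_life(p_default, env_baseline),
                                path), "record")
})
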