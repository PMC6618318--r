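test_that("feeding effort is a condition-anchored sigmoid", {
  p <- p_default
  W <- 932
  expect_equal(feeding_effort(p$rho * W, W, p), 0.5)
  expect_equal(feeding_effort(1e-9, W, p), 1, tolerance = 1e-6)
  expect_equal(feeding_effort(0, W, p), 1)
  F <- seq(150, 500, by = 10)
  expect_true(all(diff(feeding_effort(F, W, p)) < 0))
  # frozen-steepness check: condition at twice the target
  p15 <- modify_parameters(p, eta = 15)
  expect_equal(feeding_effort(0.6 * W, W, p15), 1 / (1 + exp(15 / 2)),
               tolerance = 1e-12)
  expect_equal(1 / (1 + exp(15 / 2)), 5.53e-4, tolerance = 1e-2)
})

test_that("age efficiency is a Hill curve through its half-saturation", {
  p3 <- modify_parameters(p_default, gamma = 3)
  expect_equal(age_efficiency(0, p3), 0)
  expect_equal(age_efficiency(p3$T_R, p3), 0.5)
  expect_equal(age_efficiency(3 * p3$T_R, p3), 27 / 28)
  expect_lt(age_efficiency(1e6, p3), 1)
  expect_error(age_efficiency(-1, p3), "nonnegative")
})

test_that("resource assimilation composes its four factors", {
  p <- p_default
  expect_equal(resource_assimilation(5000, 672, 100, 772, 0, p), 0)
  # adult at target condition: phi_R * R * S^(2/3) / 2 (age efficiency ~ 1)
  a <- 80 * 365
  S <- 672; F <- p$rho / (1 - p$rho) * S; W <- S + F
  expect_equal(resource_assimilation(a, S, F, W, 1.8, p),
               p$phi_R * 1.8 * S^(2 / 3) / 2 * age_efficiency(a, p),
               tolerance = 1e-12)
  expect_gt(age_efficiency(a, p), 0.999)
  expect_error(resource_assimilation(100, -1, 10, 10, 1, p), "negative")
})

test_that("milk-age factor is flat to T_N then falls to zero at weaning", {
  p <- p_default
  expect_equal(milk_age_factor(0, p), 1)
  expect_equal(milk_age_factor(p$T_N, p), 1)
  expect_equal(milk_age_factor(p$T_L, p), 0)
  a <- seq(0, p$T_L, by = 1)
  f <- milk_age_factor(a, p)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f[a >= p$T_N]) <= 1e-12))
  # linear when the shape constant vanishes
  p0 <- modify_parameters(p, xi_c = 0)
  expect_equal(milk_age_factor((p$T_N + p$T_L) / 2, p0), 0.5)
})

test_that("milk provisioning spans [rho_s, rho] in maternal condition", {
  p <- p_default
  W <- 900
  expect_equal(milk_provisioning_factor(p$rho * W, W, p), 1)
  expect_equal(milk_provisioning_factor(p$rho_s * W, W, p), 0)
  expect_equal(milk_provisioning_factor(0.05 * W, W, p), 0)   # clamped
  expect_equal(milk_provisioning_factor(0.5 * W, W, p), 1)    # capped
  F <- seq(0.1, 0.35, by = 0.005) * W
  f <- milk_provisioning_factor(F, W, p)
  expect_true(all(diff(f) >= 0))
  p0 <- modify_parameters(p, xi_m = 0)
  expect_equal(milk_provisioning_factor((p$rho + p$rho_s) / 2 * W, W, p0),
               0.5)
})

test_that("milk assimilation links calf demand and maternal supply", {
  p <- p_default
  S_c <- 100; F_c <- p$rho / (1 - p$rho) * S_c; W_c <- S_c + F_c
  # mother at the starvation threshold: no milk
  expect_equal(milk_assimilation(100, S_c, F_c, W_c, 0.15 * 900, 900, p), 0)
  # calf at target condition, mother at target, before T_N
  il <- milk_assimilation(100, S_c, F_c, W_c, 0.3 * 900, 900, p)
  expect_equal(il, p$phi_L * S_c^(2 / 3) * 0.5, tolerance = 1e-12)
})

test_that("metabolic cost follows three-quarter scaling", {
  p <- p_default
  expect_equal(metabolic_cost(722, p), p$sigma_M * 722^0.75)
  expect_equal(metabolic_cost(722, p), 103, tolerance = 0.02)
  expect_equal(metabolic_cost(0, p), 0)
  expect_equal(metabolic_cost(2 * 722, p) / metabolic_cost(722, p),
               2^0.75)
})

test_that("growth and fetal costs equal sigma_G times mass growth rates", {
  p <- p_default
  expect_equal(growth_cost(p$l_inf, p), 0)
  a <- c(1, 500, 2000, 8000)
  h <- 1e-3
  dSda <- (structural_mass(length_at_age(a + h, p), p) -
             structural_mass(length_at_age(a - h, p), p)) / (2 * h)
  expect_equal(growth_cost(length_at_age(a, p), p), p$sigma_G * dSda,
               tolerance = 1e-6)
  expect_true(all(growth_cost(seq(177, 450, by = 1), p) >= 0))
  # fetal cost: chain rule against fetal structural growth
  tau <- c(10, 100, 250, 364)
  dSdt <- (structural_mass(fetal_length(tau + h, p), p) -
             structural_mass(fetal_length(tau - h, p), p)) / (2 * h)
  expect_equal(fetal_cost(tau, p), p$sigma_G * dSdt, tolerance = 1e-6)
  expect_equal(fetal_cost(0, p), 0)
  # total fetal investment: closed form sigma_G * omega1 * l_b^omega2
  total <- stats::integrate(function(x) fetal_cost(x, p), 0, p$T_P,
                            rel.tol = 1e-10)$value
  expect_equal(total, p$sigma_G * p$omega1 * p$l_b^p$omega2,
               tolerance = 1e-6)
  # daily maximum at term, ~13 MJ/d
  expect_equal(fetal_cost(p$T_P, p), 12.70, tolerance = 1e-3)
})

test_that("reserve balance converts by the sign of the net rate", {
  p <- p_default
  expect_equal(lactation_cost(86, p), 100)
  expect_equal(lactation_cost(0, p), 0)
  expect_equal(reserve_balance(0, p), 0)
  expect_equal(reserve_balance(p$eps_plus, p), 1)
  expect_equal(reserve_balance(-p$eps_minus, p), -1)
  # store X MJ then mobilize the stored mass: recover eps_minus/eps_plus X
  X <- 100
  stored_kg <- reserve_balance(X, p)
  expect_equal(stored_kg * p$eps_minus, X * p$eps_minus / p$eps_plus)
  expect_lt(p$eps_minus / p$eps_plus, 1)
  # case logic: lactation only burdens the female, milk only feeds the calf
  expect_equal(net_energy(100, 5, 80, "calf", I_L = 30), 45)
  expect_equal(net_energy(100, 5, 80, "pregnant", C_P = 10), 5)
  expect_equal(net_energy(100, 5, 80, "lactating", C_L = 30 / p$sigma_L),
               100 - 5 - 80 - 30 / p$sigma_L)
  expect_equal(net_energy(100, 5, 80, "other"), 15)
})

test_that("non-reproductive adult reserves attract to a unique equilibrium", {
  p <- p_default
  Feq <- equilibrium_reserves(p, 1.8)
  expect_equal(Feq, 260, tolerance = 1e-4)
  # ODE relaxation from reserves anywhere between the starvation and
  # far-above-target levels lands on the same attractor
  ends <- vapply(c(135, 200, 350), function(F0) {
    life <- simulate_life(p, environment_spec(R_hat = 1.8),
                          reproduce = FALSE, a0 = 60 * 365, F0 = F0,
                          t_max_yr = 3, record = TRUE)
    tr <- life$trajectory
    tr$F[nrow(tr)]
  }, 0)
  expect_equal(ends, rep(Feq, 3), tolerance = 0.005)
  expect_lt(max(ends) - min(ends), 0.05)
})
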