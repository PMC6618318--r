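test_that("defaults carry the observable life-history constants", {
  p <- p_default
  expect_equal(p$l_b, 177)
  expect_equal(p$l_inf, 450)
  expect_equal(p$k, 0.00045)
  expect_equal(p$T_P, 365)
  expect_equal(p$T_L, 1223)
  expect_equal(p$T_D, 445)
  expect_equal(p$rho, 0.3)
  expect_equal(p$rho_s, 0.15)
  expect_silent(validate_parameters(p))
})

test_that("invariant violations are rejected with the offending symbol named", {
  expect_error(load_parameters(list(rho_s = 0.4)), "rho_s < rho")
  expect_error(load_parameters(list(T_D = 300)), "T_D > T_P")
  expect_error(load_parameters(list(sigma_L = 1.4)), "sigma_L")
  expect_error(load_parameters(list(T_N = 1300)), "T_N < T_L")
  expect_error(load_parameters(list(l_inf = -1)), "l_inf")
  expect_error(load_parameters(list(eps_minus = 80)), "eps_minus/eps_plus")
  expect_error(deb_parameters(nonsense = 1), "unknown parameter")
})

test_that("F_neonate derives from its two components", {
  p <- p_default
  S_b <- p$omega1 * p$l_b^p$omega2
  expect_equal(derive_f_neonate(p), 61.45, tolerance = 0.005)
  # reserve-endowment component alone: rho_s * S_b / (1 - rho_s)
  expect_equal(p$rho_s * S_b / (1 - p$rho_s), 10.4906, tolerance = 1e-4)
  # both components vanish in the no-endowment, free-catabolism limit
  p0 <- modify_parameters(p, rho_s = 1e-12, eps_minus = 1e12,
                          F_neonate = 1)  # F_neonate unused by the derivation
  expect_lt(derive_f_neonate(p0), 1e-6)
})

test_that("eps_minus inverts the F_neonate identity", {
  p <- p_default
  expect_equal(derive_eps_minus(p), 35.0, tolerance = 1e-3)
  # storing the derived value reproduces F_neonate
  expect_equal(derive_f_neonate(p), p$F_neonate, tolerance = 1e-6)
  # degenerate: F_neonate equal to the endowment component alone
  S_b <- p$omega1 * p$l_b^p$omega2
  bad <- modify_parameters(p, F_neonate = p$rho_s * S_b / (1 - p$rho_s))
  expect_error(derive_eps_minus(bad), "inconsistent")
  # at fixed F_neonate, eps_minus is proportional to sigma_G
  p2 <- modify_parameters(p, sigma_G = 2 * p$sigma_G)
  expect_equal(derive_eps_minus(p2), 2 * derive_eps_minus(p),
               tolerance = 1e-9)
})

test_that("configuration round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  dump_defaults(path, p_default)
  p2 <- load_parameters(path)
  expect_equal(unclass(p2), unclass(p_default), tolerance = 1e-9,
               ignore_attr = TRUE)
  # overrides only for supplied keys
  p3 <- load_parameters(list(mu_s = 1))
  expect_equal(p3$mu_s, 1)
  expect_equal(p3$l_b, 177)
  expect_equal(attr(p3, "provenance")[["mu_s"]], "override")
})

test_that("provenance report lists every symbol exactly once", {
  df <- parameter_provenance(p_default)
  expect_equal(anyDuplicated(df$symbol), 0L)
  expect_setequal(df$symbol, names(unclass(p_default)))
  expect_true(all(df$provenance %in%
                    c("literature", "calibrated", "derived", "override")))
})

test_that("mortality coefficients satisfy both survivorship anchors", {
  p <- p_default
  cum <- stats::integrate(function(a) age_mortality(a, p), 0, 60 * 365,
                          rel.tol = 1e-10)$value
  expect_equal(cum, -log(p$survival_threshold), tolerance = 1e-3)
  cum2 <- stats::integrate(function(a) age_mortality(a, p), p$T_L,
                           60.3 * 365, rel.tol = 1e-10)$value
  expect_equal(cum2, -log(p$survival_threshold), tolerance = 1e-3)
  # the helper reproduces the frozen defaults
  m <- fit_age_mortality()
  expect_equal(m$alpha1, p$alpha1, tolerance = 1e-6)
  expect_equal(m$alpha2, p$alpha2, tolerance = 1e-6)
  # infeasible shape rates are reported
  expect_error(fit_age_mortality(beta2 = 1 / (40 * 365)), "positive")
})
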