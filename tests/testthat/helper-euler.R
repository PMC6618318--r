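# Independent daily-step explicit-Euler reference implementation of the
# female + calf life history, written directly from the model equations.
# Used as a cross-implementation oracle for the compiled integrator: it
# shares no code with the package's simulation path (plain R, fixed 1-d
# steps, events handled on day boundaries).

euler_life <- function(p, R_hat = 1.8, A = 0, dist_days = 0,
                       dist_start = 273, t_end_yr = 120) {
  lof <- function(a) p$l_inf - (p$l_inf - p$l_b) * exp(-p$k * a)
  Sof <- function(l) p$omega1 * l^p$omega2
  eff <- function(Fv, Wv) if (Fv <= 0) 1 else
    1 / (1 + exp(-p$eta * (p$rho * Wv / Fv - 1)))
  ae <- function(a) a^p$gamma / (p$T_R^p$gamma + a^p$gamma)
  Dage <- function(a) p$alpha1 * exp(-p$beta1 * a) +
    p$alpha2 * exp(p$beta2 * a)

  a0 <- p$T_L
  Ff <- p$rho * Sof(lof(a0)) / (1 - p$rho)
  lnP <- 0
  phase <- "REST"; wait0 <- NA; conc0 <- NA; birth0 <- NA
  Fc <- 0; lnPc <- 0
  nw <- 0L; births <- numeric(0)
  lnth <- log(p$survival_threshold)
  woff <- p$T_L - p$T_P + 1
  gpreg <- function(t, Fv) {
    S <- Sof(lof(a0 + t)); Fv - (p$rho_s * (S + Fv) + p$F_neonate)
  }
  death_age <- NA_real_

  for (t in 0:(t_end_yr * 365 - 1)) {
    # start-of-day phase-clock events (weaning, birth, implantation, window)
    if (phase %in% c("LACT", "LW") && (t - birth0) >= p$T_L) {
      nw <- nw + 1L
      phase <- if (phase == "LW") "WAIT" else "REST"
      Fc <- 0; lnPc <- 0; birth0 <- NA
    }
    if (phase == "PREG" && (t - conc0) >= p$T_P) {
      Sb <- Sof(p$l_b)
      Fc <- p$rho_s * Sb / (1 - p$rho_s); lnPc <- 0
      birth0 <- t; phase <- "LACT"
      births <- c(births, (a0 + t) / 365)
    }
    if (phase == "WAIT" && (t - wait0) >= p$T_D) { phase <- "PREG"; conc0 <- t }
    if (phase == "REST" && gpreg(t, Ff) >= 0) { phase <- "WAIT"; wait0 <- t }
    if (phase == "LACT" && (t - birth0) >= woff && gpreg(t, Ff) >= 0) {
      phase <- "LW"; wait0 <- t
    }

    # daily rates
    af <- a0 + t; lf <- lof(af); Sf <- Sof(lf)
    doy <- t %% 365
    e2 <- dist_start + dist_days
    dist <- dist_days > 0 &&
      (if (e2 <= 365) doy >= dist_start && doy < e2
       else doy >= dist_start || doy < e2 - 365)
    Rr <- if (dist) 0 else R_hat * (1 + A * sin(2 * pi * t / 365))
    Sfet <- 0; CP <- 0
    if (phase == "PREG") {
      tau <- t - conc0
      Sfet <- Sof(p$l_b * tau / p$T_P)
      CP <- if (tau > 0)
        p$sigma_G * p$omega1 * p$omega2 * (p$l_b / p$T_P)^p$omega2 *
          tau^(p$omega2 - 1) else 0
    }
    Wf <- Sf + Ff + Sfet; WMf <- Sf + p$theta_F * Ff + Sfet
    IR <- p$phi_R * Rr * Sf^(2 / 3) * eff(Ff, Wf) * ae(af)
    CM <- p$sigma_M * WMf^0.75
    CG <- p$sigma_G * p$omega1 * p$k * (p$l_inf - lf) * p$omega2 *
      lf^(p$omega2 - 1)
    IL <- 0; CL <- 0
    lactating <- phase %in% c("LACT", "LW")
    if (lactating) {
      ac <- t - birth0; lc <- lof(ac); Sc <- Sof(lc); Wc <- Sc + Fc
      x <- (ac - p$T_N) / (p$T_L - p$T_N)
      mage <- if (x <= 0) 1 else max(0, min(1, (1 - x) / (1 - p$xi_c * x)))
      xm <- max(0, Ff - p$rho_s * Wf)
      prov <- max(0, min(1, (1 - p$xi_m) * xm /
                           ((p$rho - p$rho_s) * Wf - p$xi_m * xm)))
      IL <- p$phi_L * Sc^(2 / 3) * eff(Fc, Wc) * mage * prov
      IRc <- p$phi_R * Rr * Sc^(2 / 3) * eff(Fc, Wc) * ae(ac)
      CMc <- p$sigma_M * (Sc + p$theta_F * Fc)^0.75
      CGc <- p$sigma_G * p$omega1 * p$k * (p$l_inf - lc) * p$omega2 *
        lc^(p$omega2 - 1)
      Bc <- IRc + IL - CGc - CMc
      Fc <- Fc + (if (Bc > 0) Bc / p$eps_plus else Bc / p$eps_minus)
      Dsc <- if (Fc < p$rho_s * Wc)
        p$mu_s * (p$rho_s * Wc / max(Fc, 1e-12) - 1) else 0
      lnPc <- lnPc - (Dage(ac) + Dsc)
      CL <- IL / p$sigma_L
    }
    Bf <- IR - CG - CM - CP - CL
    Dsf <- if (Ff < p$rho_s * Wf)
      p$mu_s * (p$rho_s * Wf / max(Ff, 1e-12) - 1) else 0
    Ff <- Ff + (if (Bf > 0) Bf / p$eps_plus else Bf / p$eps_minus)
    lnP <- lnP - (Dage(af) + Dsf)

    # end-of-day death checks
    if (lactating) {
      Wc1 <- Sof(lof(t + 1 - birth0)) + Fc
      if (lnPc < lnth || Fc / Wc1 < p$condition_floor) {
        phase <- if (phase == "LW") "WAIT" else "REST"
        Fc <- 0; lnPc <- 0; birth0 <- NA
      }
    }
    Wf1 <- Sof(lof(a0 + t + 1)) + Ff
    if (lnP < lnth || Ff / Wf1 < p$condition_floor) {
      death_age <- (a0 + t + 1) / 365
      break
    }
  }
  list(death_age_yr = death_age, n_weaned = nw, birth_ages_yr = births)
}
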