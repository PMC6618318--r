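# Mortality hazards, survival bookkeeping and death rules.

#' Age-dependent mortality hazard
#'
#' `D(a) = alpha1*exp(-beta1*a) + alpha2*exp(beta2*a)`: a U-shaped hazard
#' combining juvenile mortality that declines with age and senescence
#' mortality that increases with age (constant background mortality is
#' absorbed by the two exponentials).
#'
#' @param a age, d (vectorized).
#' @param p a [deb_parameters()] object.
#' @return Hazard, 1/d.
#' @export
age_mortality <- function(a, p) {
  p$alpha1 * exp(-p$beta1 * a) + p$alpha2 * exp(p$beta2 * a)
}

#' Starvation-induced mortality hazard
#'
#' Zero at or above the starvation condition threshold `rho_s`; below it the
#' hazard rises hyperbolically, `mu_s * (rho_s*W/F - 1)`, diverging as
#' reserves vanish.
#'
#' @param F reserve mass, kg (vectorized).
#' @param W total mass, kg.
#' @param p a [deb_parameters()] object.
#' @return Hazard, 1/d.
#' @export
starvation_mortality <- function(F, W, p) {
  ifelse(F >= p$rho_s * W, 0, p$mu_s * (p$rho_s * W / pmax(F, .Machine$double.xmin) - 1))
}

#' Survival probability over a piecewise-constant hazard history
#'
#' Multiplies exponential survival over consecutive subwindows:
#' `prod(exp(-h_i * dt_i))`. Exact for piecewise-constant hazards; within
#' the simulator the same quantity is carried as a log-survival state
#' integrated alongside the masses.
#'
#' @param hazard hazard values, 1/d, one per subwindow.
#' @param dt subwindow lengths, d (recycled if scalar).
#' @return Survival probability in `(0, 1]`.
#' @export
integrate_survival <- function(hazard, dt) {
  if (any(hazard < 0) || any(dt < 0))
    stop("hazards and window lengths must be nonnegative", call. = FALSE)
  exp(-sum(hazard * dt))
}

#' Apply the death rules
#'
#' An individual is dead when its survival probability has fallen below its
#' death threshold (fixed mode: 2.266e-7; random mode: a uniform draw made
#' when tracking starts), or immediately when body condition falls below the
#' certain-death floor (0.005).
#'
#' @param survival current survival probability.
#' @param death_threshold the individual's threshold.
#' @param condition current body condition `F/W`.
#' @param p a [deb_parameters()] object.
#' @return A list with `alive` (logical) and `cause` (`NA`, `"mortality"`
#'   or `"starvation-floor"`).
#' @export
check_death <- function(survival, death_threshold, condition, p) {
  if (condition < p$condition_floor)
    list(alive = FALSE, cause = "starvation-floor")
  else if (survival < death_threshold)
    list(alive = FALSE, cause = "mortality")
  else list(alive = TRUE, cause = NA_character_)
}

#' Equilibrium reserve mass of a non-reproductive fully grown female
#'
#' Solves the steady intake-expenditure balance
#' `phi_R * R * S^(2/3) * feeding_effort(F) = sigma_M * (S + theta_F*F)^(3/4)`
#' for a female at asymptotic length (growth cost zero, age efficiency at its
#' limit of 1) at constant resource density `R`. This is the reserve level
#' the female would settle at if she never reproduced.
#'
#' @param p a [deb_parameters()] object.
#' @param R constant resource density, MJ/m^3.
#' @return Equilibrium reserve mass, kg.
#' @export
equilibrium_reserves <- function(p, R) {
  S <- structural_mass(p$l_inf, p)
  bal <- function(F) {
    W <- S + F
    p$phi_R * R * S^(2 / 3) * feeding_effort(F, W, p) -
      metabolic_cost(S + p$theta_F * F, p)
  }
  lo <- 1e-6
  hi <- p$rho * S / (1 - p$rho) * 3
  if (bal(lo) <= 0)
    stop("resource density too low: no positive reserve equilibrium",
         call. = FALSE)
  while (bal(hi) > 0) hi <- hi * 2
  stats::uniroot(bal, c(lo, hi), tol = 1e-10)$root
}
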