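# Intake and expenditure rates, and the reserve balance with
# anabolic/catabolic conversion.

#' Feeding effort as a function of body condition
#'
#' Sigmoid behavioural response `1 / (1 + exp(-eta * (rho*W/F - 1)))`:
#' exactly 0.5 at the target condition `F = rho*W`, approaching 1 as
#' condition falls (compensatory feeding) and 0 as reserves grow far beyond
#' the target. The `F -> 0` limit is 1.
#'
#' @param F reserve mass, kg (vectorized).
#' @param W total mass, kg.
#' @param p a [deb_parameters()] object.
#' @return Fraction in `[0, 1]`.
#' @export
feeding_effort <- function(F, W, p) {
  if (any(W <= 0)) stop("total mass must be positive", call. = FALSE)
  if (any(F < 0)) stop("reserve mass must be nonnegative", call. = FALSE)
  ifelse(F == 0, 1, 1 / (1 + exp(-p$eta * (p$rho * W / F - 1))))
}

#' Age-dependent foraging efficiency
#'
#' Hill function `a^gamma / (T_R^gamma + a^gamma)`: inexperienced foragers
#' start at 0 at birth, reach half-efficiency at age `T_R` and approach 1
#' asymptotically.
#'
#' @param a age, d (vectorized).
#' @param p a [deb_parameters()] object.
#' @return Fraction in `[0, 1)`.
#' @export
age_efficiency <- function(a, p) {
  if (any(a < 0)) stop("age must be nonnegative", call. = FALSE)
  ag <- a^p$gamma
  ag / (p$T_R^p$gamma + ag)
}

#' Energy assimilation from resource feeding
#'
#' `I_R = phi_R * R * S^(2/3) * feeding_effort(F, W) * age_efficiency(a)`.
#' The product `phi_R * R * S^(2/3)` is the maximum assimilation rate of an
#' individual of structural mass `S` at resource density `R` (linear
#' functional response); effort and age efficiency modulate it in `[0, 1]`.
#'
#' @param a age, d.
#' @param S structural mass, kg.
#' @param F reserve mass, kg.
#' @param W total mass, kg.
#' @param R_eff effective resource density, MJ/m^3 (0 while disturbed).
#' @param p a [deb_parameters()] object.
#' @return Assimilation rate, MJ/d.
#' @export
resource_assimilation <- function(a, S, F, W, R_eff, p) {
  if (any(R_eff < 0) || any(S < 0))
    stop("negative input", call. = FALSE)
  p$phi_R * R_eff * S^(2 / 3) * feeding_effort(F, W, p) *
    age_efficiency(a, p)
}

#' Milk-intake decline with calf age
#'
#' 1 while the calf is younger than `T_N`; thereafter the scaled-time decline
#' `(1 - x) / (1 - xi_c * x)` with `x = (a - T_N)/(T_L - T_N)`, clamped to
#' `[0, 1]`, reaching exactly 0 at weaning age `T_L`. Linear when
#' `xi_c = 0`.
#'
#' @param a calf age, d (vectorized).
#' @param p a [deb_parameters()] object.
#' @return Fraction in `[0, 1]`.
#' @export
milk_age_factor <- function(a, p) {
  x <- (a - p$T_N) / (p$T_L - p$T_N)
  f <- ifelse(x <= 0, 1, (1 - x) / (1 - p$xi_c * x))
  pmin(1, pmax(0, f))
}

#' Milk provisioning as a function of maternal condition
#'
#' The mother's willingness to lactate:
#' `(1 - xi_m) * (F_m - rho_s*W_m) / ((rho - rho_s)*W_m - xi_m*(F_m -
#' rho_s*W_m))`, clamped to `[0, 1]`. Equals 1 at the target condition
#' `rho`, 0 at the starvation threshold `rho_s` (milk supply ceases), and is
#' nondecreasing in maternal reserves; linear between the two when
#' `xi_m = 0`.
#'
#' @param F_m maternal reserve mass, kg (vectorized).
#' @param W_m maternal total mass, kg.
#' @param p a [deb_parameters()] object.
#' @return Fraction in `[0, 1]`.
#' @export
milk_provisioning_factor <- function(F_m, W_m, p) {
  x <- pmax(0, F_m - p$rho_s * W_m)
  f <- (1 - p$xi_m) * x / ((p$rho - p$rho_s) * W_m - p$xi_m * x)
  pmin(1, pmax(0, f))
}

#' Energy assimilation from milk feeding
#'
#' `I_L = phi_L * S_c^(2/3) * feeding_effort(F_c, W_c) *
#' milk_age_factor(a_c) * milk_provisioning_factor(F_m, W_m)`. Suckling
#' scales with calf structural surface area and the calf's own appetite
#' (condition-dependent effort); the mother throttles supply through her
#' condition. Zero when there is no living calf.
#'
#' @param a_c calf age, d.
#' @param S_c,F_c,W_c calf structural, reserve and total mass, kg.
#' @param F_m,W_m maternal reserve and total mass, kg.
#' @param p a [deb_parameters()] object.
#' @return Assimilation rate, MJ/d.
#' @export
milk_assimilation <- function(a_c, S_c, F_c, W_c, F_m, W_m, p) {
  p$phi_L * S_c^(2 / 3) * feeding_effort(F_c, W_c, p) *
    milk_age_factor(a_c, p) * milk_provisioning_factor(F_m, W_m, p)
}

#' Field metabolic cost
#'
#' Kleiber allometry on maintenance mass: `C_M = sigma_M * W_M^(3/4)`,
#' covering maintenance and routine activity.
#'
#' @param W_M maintenance body mass, kg (vectorized).
#' @param p a [deb_parameters()] object.
#' @return Cost, MJ/d.
#' @export
metabolic_cost <- function(W_M, p) {
  if (any(W_M < 0)) stop("maintenance mass must be nonnegative",
                         call. = FALSE)
  p$sigma_M * W_M^(3 / 4)
}

#' Structural growth cost
#'
#' `C_G = sigma_G * omega1 * k * (l_inf - l) * omega2 * l^(omega2-1)`, i.e.
#' `sigma_G` times the time derivative of structural mass along the Von
#' Bertalanffy curve; zero for a fully grown individual.
#'
#' @param l length, cm (vectorized).
#' @param p a [deb_parameters()] object.
#' @return Cost, MJ/d.
#' @export
growth_cost <- function(l, p) {
  p$sigma_G * p$omega1 * p$k * (p$l_inf - l) * p$omega2 * l^(p$omega2 - 1)
}

#' Fetal development cost
#'
#' `C_P = sigma_G * omega1 * omega2 * (l_b/T_P)^omega2 * tau_p^(omega2-1)`
#' for `0 <= tau_p <= T_P`: `sigma_G` times the growth rate of fetal
#' structural mass under linear fetal length growth. Its integral over
#' gestation equals `sigma_G * omega1 * l_b^omega2`, the full structural
#' cost of one fetus.
#'
#' @param tau_p time since conception, d (vectorized).
#' @param p a [deb_parameters()] object.
#' @return Cost, MJ/d.
#' @export
fetal_cost <- function(tau_p, p) {
  if (any(tau_p < 0 | tau_p > p$T_P))
    stop("tau_p must lie in [0, T_P]", call. = FALSE)
  p$sigma_G * p$omega1 * p$omega2 * (p$l_b / p$T_P)^p$omega2 *
    tau_p^(p$omega2 - 1)
}

#' Lactation cost to the mother
#'
#' `C_L = I_L / sigma_L`: the milk energy assimilated by the calf divided by
#' the combined efficiency of milk synthesis and assimilation.
#'
#' @param I_L calf milk assimilation, MJ/d (vectorized).
#' @param p a [deb_parameters()] object.
#' @return Cost, MJ/d.
#' @export
lactation_cost <- function(I_L, p) I_L / p$sigma_L

#' Assemble the case-specific net energy balance
#'
#' Net rate (MJ/d) per the individual's reproductive case: calves gain
#' resource plus milk energy and pay growth and metabolism; pregnant females
#' additionally pay fetal development; lactating females additionally pay
#' lactation; all others balance resource intake against growth and
#' metabolism.
#'
#' @param I_R resource assimilation, MJ/d.
#' @param C_G,C_M growth and metabolic costs, MJ/d.
#' @param case one of `"calf"`, `"pregnant"`, `"lactating"`, `"other"`.
#' @param I_L milk assimilation, MJ/d (calf case).
#' @param C_P fetal cost, MJ/d (pregnant case).
#' @param C_L lactation cost, MJ/d (lactating case).
#' @return Net energy rate B, MJ/d.
#' @export
net_energy <- function(I_R, C_G, C_M,
                       case = c("other", "calf", "pregnant", "lactating"),
                       I_L = 0, C_P = 0, C_L = 0) {
  case <- match.arg(case)
  switch(case,
         calf = I_R + I_L - C_G - C_M,
         pregnant = I_R - C_G - C_M - C_P,
         lactating = I_R - C_G - C_M - C_L,
         other = I_R - C_G - C_M)
}

#' Reserve-mass rate of change from a net energy balance
#'
#' `dF/da = B / eps_plus` when the balance `B` is positive (anabolic:
#' storing costs `eps_plus` MJ per kg of reserves) and `B / eps_minus` when
#' negative (catabolic: mobilizing yields `eps_minus` MJ per kg). The
#' switch is by the sign of the instantaneous net rate, with no hysteresis;
#' both branches give 0 at `B = 0`. Since `eps_minus/eps_plus < 1`, a
#' store-then-mobilize round trip recovers only that fraction of the energy.
#'
#' @param B net energy rate, MJ/d (vectorized).
#' @param p a [deb_parameters()] object.
#' @return Reserve rate of change, kg/d.
#' @export
reserve_balance <- function(B, p) {
  ifelse(B > 0, B / p$eps_plus, B / p$eps_minus)
}
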