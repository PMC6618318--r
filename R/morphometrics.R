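# Deterministic size functions. Growth is of demand type: length follows the
# Von Bertalanffy curve regardless of energy intake, and never shrinks.

#' Structural length at age
#'
#' Von Bertalanffy length-age relationship for free-living individuals:
#' `l(a) = l_inf - (l_inf - l_b) * exp(-k * a)`.
#'
#' @param a age in days (vectorized, `>= 0`).
#' @param p a [deb_parameters()] object.
#' @return Length in cm.
#' @export
length_at_age <- function(a, p) {
  if (any(a < 0)) stop("age must be nonnegative", call. = FALSE)
  p$l_inf - (p$l_inf - p$l_b) * exp(-p$k * a)
}

#' Fetal length at time since conception
#'
#' Linear fetal growth reaching the length at birth at the end of gestation:
#' `l_p(tau_p) = l_b * tau_p / T_P` for `0 <= tau_p <= T_P`.
#'
#' @param tau_p time since conception, d (vectorized).
#' @param p a [deb_parameters()] object.
#' @return Fetal length in cm.
#' @export
fetal_length <- function(tau_p, p) {
  if (any(tau_p < 0 | tau_p > p$T_P))
    stop("tau_p must lie in [0, T_P]", call. = FALSE)
  p$l_b * tau_p / p$T_P
}

#' Structural mass from length
#'
#' Power-law mass-length relationship `S(l) = omega1 * l^omega2`.
#'
#' @param l length in cm (vectorized, `>= 0`).
#' @param p a [deb_parameters()] object.
#' @return Structural mass in kg.
#' @export
structural_mass <- function(l, p) {
  if (any(l < 0)) stop("length must be nonnegative", call. = FALSE)
  p$omega1 * l^p$omega2
}

#' Total body mass
#'
#' `W = S + F`, plus the structural mass of the fetus when pregnant. The
#' fetus carries no reserves of its own during gestation.
#'
#' @param S structural mass, kg.
#' @param F reserve mass, kg.
#' @param l_p fetal length, cm (ignored unless `pregnant`).
#' @param pregnant logical flag.
#' @param p a [deb_parameters()] object.
#' @return Total mass in kg.
#' @export
total_mass <- function(S, F, l_p = 0, pregnant = FALSE, p) {
  W <- S + F
  if (any(pregnant)) W <- W + ifelse(pregnant, structural_mass(l_p, p), 0)
  W
}

#' Maintenance body mass
#'
#' `W_M = S + theta_F * F` (+ fetal structural mass when pregnant): the mass
#' on which field metabolic costs are charged, discounting reserves by
#' `theta_F` since fat is cheaper to maintain than structure.
#'
#' @inheritParams total_mass
#' @return Maintenance mass in kg.
#' @export
maintenance_mass <- function(S, F, l_p = 0, pregnant = FALSE, p) {
  WM <- S + p$theta_F * F
  if (any(pregnant)) WM <- WM + ifelse(pregnant, structural_mass(l_p, p), 0)
  WM
}

#' Body condition
#'
#' Relative reserve mass `F/W`, the state variable that drives feeding
#' effort, milk provisioning and starvation mortality.
#'
#' @param F reserve mass, kg.
#' @param W total mass, kg (`> 0`).
#' @return Dimensionless condition in `[0, 1)`.
#' @export
body_condition <- function(F, W) {
  if (any(W <= 0)) stop("total mass must be positive", call. = FALSE)
  F / W
}
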