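# Model constants, validation, derived quantities and configuration I/O.
#
# Time is in days throughout; years appear only in reports (1 yr = 365 d).
# Masses kg, lengths cm, energies MJ, rates per day.

# Default parameter table: value, unit, provenance, description.
# Provenance is "literature" for directly observed/published values and
# "calibrated" for values fixed by the calibration anchors documented in the
# methods vignette (see calibrate_foraging(), calibrate_milk_ontogeny() and
# fit_age_mortality()). "derived" values are recomputed from the others at
# construction time.
.deb_default_table <- function() {
  d <- function(value, unit, provenance, description)
    list(value = value, unit = unit, provenance = provenance,
         description = description)
  list(
    l_b      = d(177,       "cm",       "literature", "structural length at birth"),
    l_inf    = d(450,       "cm",       "literature", "asymptotic structural length"),
    k        = d(0.00045,   "1/d",      "literature", "Von Bertalanffy growth rate"),
    omega1   = d(8.5e-5,    "kg/cm^omega2", "literature", "mass-length scaling constant"),
    omega2   = d(2.6,       "-",        "literature", "mass-length scaling exponent"),
    T_P      = d(365,       "d",        "literature", "gestation period"),
    T_L      = d(1223,      "d",        "literature", "lactation period"),
    T_D      = d(445,       "d",        "literature", "waiting period before implantation"),
    T_N      = d(365,       "d",        "literature", "calf age up to which milk intake is maximal"),
    rho      = d(0.3,       "-",        "literature", "target body condition"),
    rho_s    = d(0.15,      "-",        "literature", "starvation body-condition threshold"),
    theta_F  = d(0.2,       "-",        "literature", "relative maintenance cost of reserve mass"),
    phi_R    = d(1.0729524,  "MJ/(d kg^(2/3)) per unit R", "calibrated",
                 "resource-assimilation scalar (joint anchor with eta)"),
    phi_L    = d(2.7,       "MJ/(d kg^(2/3))", "literature", "milk-assimilation scalar"),
    eta      = d(10.5,  "-",        "calibrated", "steepness of the feeding-effort sigmoid"),
    gamma    = d(2,         "-",        "calibrated", "shape of age-dependent foraging efficiency"),
    T_R      = d(583.391363,  "d",        "calibrated", "half-saturation age of foraging efficiency"),
    xi_c     = d(0.9,     "-",        "calibrated", "shape of milk-intake decline with calf age"),
    xi_m     = d(-0.5,       "-",        "calibrated", "shape of milk provisioning vs maternal condition"),
    sigma_M  = d(0.7322500, "MJ/(d kg^(3/4))", "calibrated",
                 "field-metabolic scalar (2.5 x Kleiber)"),
    sigma_G  = d(30,        "MJ/kg",    "literature", "energetic cost of structural mass"),
    sigma_L  = d(0.86,      "-",        "literature", "lactation conversion efficiency"),
    eps_plus = d(55,        "MJ/kg",    "calibrated", "energy per kg reserve stored (anabolic)"),
    eps_minus= d(NA_real_,  "MJ/kg",    "derived",    "energy per kg reserve mobilized (catabolic)"),
    alpha1   = d(1.13919975e-3, "1/d",    "calibrated", "juvenile mortality coefficient"),
    beta1    = d(1.826484e-3, "1/d",    "calibrated", "juvenile mortality age-decline rate"),
    alpha2   = d(2.78142519e-6, "1/d",    "calibrated", "senescence mortality coefficient"),
    beta2    = d(3.42465753e-4, "1/d",    "calibrated", "senescence mortality age-increase rate"),
    mu_s     = d(45,       "1/d",      "calibrated", "starvation-mortality scalar"),
    F_neonate= d(61.45,     "kg",       "literature", "reserve mass needed to create a newborn"),
    survival_threshold = d(2.266e-7, "-", "literature",
                 "survival probability at death (fixed life-expectancy mode)"),
    condition_floor    = d(0.005,    "-", "literature", "body condition at certain death")
  )
}

#' Construct a validated model parameter set
#'
#' Builds the full constant set of the pilot-whale Dynamic Energy Budget model.
#' Defaults combine directly observable life-history values (growth curve,
#' reproductive-phase durations, condition thresholds) with calibrated
#' energetic and mortality coefficients; any value can be overridden by name.
#' `eps_minus`, the catabolic energy density of reserves, is derived from
#' `F_neonate` via [derive_eps_minus()] unless overridden.
#'
#' @param ... named numeric overrides of default parameter values
#'   (e.g. `rho = 0.3`, `mu_s = 0.1`).
#' @param .validate logical; check all invariants (default `TRUE`).
#' @return An object of class `deb_parameters`: a named list of numeric
#'   constants with a `provenance` attribute marking each symbol as
#'   `"literature"`, `"calibrated"`, `"derived"` or `"override"`.
#' @examples
#' p <- deb_parameters()
#' p$l_b                     # 177 cm
#' derive_f_neonate(p)       # ~61.45 kg
#' @seealso [load_parameters()], [validate_parameters()]
#' @export
deb_parameters <- function(..., .validate = TRUE) {
  tab <- .deb_default_table()
  p <- lapply(tab, `[[`, "value")
  prov <- vapply(tab, `[[`, "", "provenance")
  overrides <- list(...)
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == ""))
      stop("all parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(nm, names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (s in nm) {
      v <- overrides[[s]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
        stop("parameter '", s, "' must be a single finite number",
             call. = FALSE)
      p[[s]] <- as.numeric(v)
      prov[[s]] <- "override"
    }
  }
  if (is.na(p$eps_minus)) {
    p$eps_minus <- .derive_eps_minus_impl(p)
    prov[["eps_minus"]] <- "derived"
  }
  structure(p, provenance = prov, class = "deb_parameters")
}

#' @export
print.deb_parameters <- function(x, ...) {
  cat("<deb_parameters>: ", length(unclass(x)), " constants\n", sep = "")
  prov <- attr(x, "provenance")
  df <- parameter_provenance(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named values replaced (marked as
#' overrides in the provenance) and `eps_minus` re-derived unless it is
#' itself overridden.
#'
#' @param p a [deb_parameters()] object.
#' @param ... named numeric replacements.
#' @return A new `deb_parameters` object (not revalidated).
#' @export
modify_parameters <- function(p, ...) {
  stopifnot(inherits(p, "deb_parameters"))
  repl <- list(...)
  prov <- attr(p, "provenance")
  out <- unclass(p)
  for (s in names(repl)) {
    if (!s %in% names(out))
      stop("unknown parameter '", s, "'", call. = FALSE)
    out[[s]] <- as.numeric(repl[[s]])
    prov[[s]] <- "override"
  }
  structure(out, provenance = prov, class = "deb_parameters")
}

#' Parameter provenance report
#'
#' One row per model constant with its current value, unit and provenance
#' (`literature`, `calibrated`, `derived` or `override`).
#'
#' @param p a [deb_parameters()] object.
#' @return A `data.frame` with columns `symbol`, `value`, `unit`,
#'   `provenance`, `description`, listing every symbol exactly once.
#' @export
parameter_provenance <- function(p) {
  stopifnot(inherits(p, "deb_parameters"))
  tab <- .deb_default_table()
  prov <- attr(p, "provenance")
  data.frame(
    symbol = names(tab),
    value = vapply(names(tab), function(s) p[[s]], 0),
    unit = vapply(tab, `[[`, "", "unit"),
    provenance = vapply(names(tab), function(s) prov[[s]], ""),
    description = vapply(tab, `[[`, "", "description"),
    stringsAsFactors = FALSE
  )
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model constants: positivity of
#' masses, lengths, rates and periods; the ordering
#' `0 < rho_s < rho < 1`; `0 <= sigma_L <= 1`; `T_N < T_L`; `T_D > T_P`
#' (which prevents simultaneous pregnancy and a second implantation);
#' `eps_minus/eps_plus < 1` (net cost of storing then mobilizing energy);
#' and consistency of the stored `F_neonate` with the value derived from the
#' morphometric constants (within 0.5%).
#'
#' @param p a [deb_parameters()] object.
#' @return `p`, invisibly, if valid; otherwise an error naming the offending
#'   symbol.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "deb_parameters"))
  pos <- c("l_b", "l_inf", "k", "omega1", "omega2", "T_P", "T_L", "T_D",
           "T_N", "phi_R", "phi_L", "eta", "gamma", "T_R", "sigma_M",
           "sigma_G", "eps_plus", "eps_minus", "mu_s", "F_neonate",
           "survival_threshold", "theta_F")
  for (s in pos)
    if (!is.finite(p[[s]]) || p[[s]] <= 0)
      stop("parameter '", s, "' must be strictly positive", call. = FALSE)
  nonneg <- c("alpha1", "beta1", "alpha2", "beta2", "condition_floor")
  for (s in nonneg)
    if (!is.finite(p[[s]]) || p[[s]] < 0)
      stop("parameter '", s, "' must be nonnegative", call. = FALSE)
  if (!(p$rho_s > 0 && p$rho_s < p$rho && p$rho < 1))
    stop("invariant '0 < rho_s < rho < 1' violated (rho_s < rho required)",
         call. = FALSE)
  if (p$sigma_L < 0 || p$sigma_L > 1)
    stop("invariant '0 <= sigma_L <= 1' violated", call. = FALSE)
  if (p$T_N >= p$T_L)
    stop("invariant 'T_N < T_L' violated", call. = FALSE)
  if (p$T_D <= p$T_P)
    stop("invariant 'T_D > T_P' violated: the waiting period must exceed ",
         "gestation to prevent simultaneous pregnancy and lactation onset",
         call. = FALSE)
  if (p$eps_minus / p$eps_plus >= 1)
    stop("invariant 'eps_minus/eps_plus < 1' violated", call. = FALSE)
  if (p$xi_m >= 1)
    stop("parameter 'xi_m' must be < 1", call. = FALSE)
  if (p$xi_c >= 1)
    stop("parameter 'xi_c' must be < 1", call. = FALSE)
  f_n <- derive_f_neonate(p)
  if (abs(f_n - p$F_neonate) / p$F_neonate > 0.005)
    stop("stored F_neonate (", signif(p$F_neonate, 6),
         ") inconsistent with derived value (", signif(f_n, 6),
         "): differ by more than 0.5%", call. = FALSE)
  invisible(p)
}

#' Load parameters from a configuration document
#'
#' Reads a flat key/value configuration (a YAML file path or an already-parsed
#' named list, keys = symbol names) and merges it over the defaults. Absent
#' symbols take their default value; every invariant is then checked.
#'
#' @param config path to a YAML file, a named list of overrides, or `NULL`
#'   (defaults only).
#' @return A validated [deb_parameters()] object.
#' @export
load_parameters <- function(config = NULL) {
  overrides <- list()
  if (is.character(config)) {
    if (!file.exists(config))
      stop("configuration file not found: ", config, call. = FALSE)
    overrides <- yaml::read_yaml(config)
    if (is.null(overrides)) overrides <- list()
  } else if (is.list(config)) {
    overrides <- config
  } else if (!is.null(config)) {
    stop("'config' must be a file path, a named list, or NULL",
         call. = FALSE)
  }
  # keep only parameter keys; scenario keys may share a file with them
  known <- names(.deb_default_table())
  overrides <- overrides[intersect(names(overrides), known)]
  p <- do.call(deb_parameters, c(overrides, list(.validate = FALSE)))
  validate_parameters(p)
  p
}

#' Write the default parameter set to a YAML file
#'
#' Emits the complete default set, one key per symbol, with provenance and
#' description comments. The file round-trips through [load_parameters()].
#'
#' @param path output file path; `""` prints to the console.
#' @param p parameter set to dump (defaults to [deb_parameters()]).
#' @return `path`, invisibly.
#' @export
dump_defaults <- function(path = "", p = deb_parameters()) {
  df <- parameter_provenance(p)
  lines <- c("# pilotwhaleDEB parameter defaults",
             "# units: days, cm, kg, MJ; rates per day")
  for (i in seq_len(nrow(df))) {
    lines <- c(lines,
               sprintf("# %s [%s] (%s)", df$description[i], df$unit[i],
                       df$provenance[i]),
               sprintf("%s: %.10g", df$symbol[i], df$value[i]))
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (identical(path, "")) cat(txt) else writeLines(txt, path)
  invisible(path)
}

.derive_f_neonate_impl <- function(p) {
  S_b <- p$omega1 * p$l_b^p$omega2
  p$sigma_G * S_b / p$eps_minus + p$rho_s * S_b / (1 - p$rho_s)
}

#' Reserve mass required to produce a neonate
#'
#' The pregnancy-threshold component `F_neonate` has two parts: the cost of
#' building the calf's structural mass at birth, expressed in maternal reserve
#' mass (hence divided by the catabolic energy density `eps_minus`), plus the
#' reserve mass handed to the calf at birth, which puts the neonate exactly at
#' the starvation condition threshold `rho_s`:
#' `sigma_G * omega1 * l_b^omega2 / eps_minus +
#'  rho_s * omega1 * l_b^omega2 / (1 - rho_s)`.
#'
#' @param p a [deb_parameters()] object.
#' @return Reserve mass in kg.
#' @export
derive_f_neonate <- function(p) {
  stopifnot(inherits(p, "deb_parameters"))
  .derive_f_neonate_impl(p)
}

.derive_eps_minus_impl <- function(p) {
  S_b <- p$omega1 * p$l_b^p$omega2
  denom <- p$F_neonate - p$rho_s * S_b / (1 - p$rho_s)
  if (!is.finite(denom) || denom <= 0)
    stop("inconsistent parameters: F_neonate does not exceed the neonatal ",
         "reserve endowment, cannot solve for eps_minus", call. = FALSE)
  p$sigma_G * S_b / denom
}

#' Catabolic energy density implied by F_neonate
#'
#' Inverts the `F_neonate` identity to recover `eps_minus`, the energy
#' obtained per kg of mobilized reserves:
#' `eps_minus = sigma_G * omega1 * l_b^omega2 /
#'   (F_neonate - rho_s * omega1 * l_b^omega2 / (1 - rho_s))`.
#'
#' @param p a [deb_parameters()] object (with `F_neonate` set).
#' @return Energy density in MJ/kg.
#' @export
derive_eps_minus <- function(p) {
  stopifnot(inherits(p, "deb_parameters"))
  .derive_eps_minus_impl(p)
}

#' Fit age-dependent mortality coefficients to survivorship anchors
#'
#' The age-dependent hazard is `D(a) = alpha1*exp(-beta1*a) +
#' alpha2*exp(beta2*a)` (declining juvenile mortality plus increasing
#' senescence mortality; constant background mortality is absorbed by the two
#' exponentials). Given the two shape rates `beta1` and `beta2`, the two
#' scale coefficients are solved exactly (a 2x2 linear system) from:
#'
#' * a fixed life expectancy at birth of `fixed_le_yr` years, i.e.
#'   cumulative hazard from birth `integral(D, 0, fixed_le_yr) =
#'   -log(survival_threshold)`; and
#' * a female tracked from weaning (survival reset to 1 at age `T_L`)
#'   reaching the same survival threshold at age `death_age_yr` years.
#'
#' The second anchor encodes the observation that a female initiated at
#' weaning crosses the threshold slightly after `fixed_le_yr`.
#'
#' @param beta1,beta2 juvenile decline and senescence increase rates (1/d).
#' @param survival_threshold survival probability at death.
#' @param fixed_le_yr life expectancy at birth, years (default 60).
#' @param death_age_yr threshold-crossing age of a female tracked from
#'   weaning, years (default 60.3).
#' @param T_L lactation period, d (tracking starts at weaning age `T_L`).
#' @return Named list with `alpha1`, `beta1`, `alpha2`, `beta2` (1/d).
#' @export
fit_age_mortality <- function(beta1 = 1 / 547.5, beta2 = 1 / 2920,
                              survival_threshold = 2.266e-7,
                              fixed_le_yr = 60, death_age_yr = 60.3,
                              T_L = 1223) {
  L <- -log(survival_threshold)
  g1 <- function(a0, a1) (exp(-beta1 * a0) - exp(-beta1 * a1)) / beta1
  g2 <- function(a0, a1) (exp(beta2 * a1) - exp(beta2 * a0)) / beta2
  A <- rbind(c(g1(0, fixed_le_yr * 365), g2(0, fixed_le_yr * 365)),
             c(g1(T_L, death_age_yr * 365), g2(T_L, death_age_yr * 365)))
  ab <- solve(A, c(L, L))
  if (any(ab <= 0))
    stop("no positive (alpha1, alpha2) satisfy the survivorship anchors ",
         "with the supplied shape rates", call. = FALSE)
  list(alpha1 = ab[[1]], beta1 = beta1, alpha2 = ab[[2]], beta2 = beta2)
}
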