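# Simulation of one female life history: R surface over the compiled
# event-driven integrator.

.traj_colnames <- c(
  "t", "age_yr", "phase", "l", "S", "F", "W", "condition", "survival",
  "I_R", "C_M", "C_G", "C_P", "C_L", "net",
  "calf_age_d", "calf_l", "calf_S", "calf_F", "calf_condition",
  "calf_survival", "calf_I_R", "calf_I_L", "calf_net", "R_eff")

.phase_levels <- c("RESTING", "WAITING", "PREGNANT", "LACTATING",
                   "LACTATING_WAITING")

#' Derive a reproducible substream seed
#'
#' Maps a master seed and replicate coordinates to a 31-bit seed by modular
#' mixing, so every replicate's random stream depends only on
#' (master seed, cell index, replicate index) and never on execution order.
#'
#' @param master master seed (integer).
#' @param cell scenario-cell index (integer, default 0).
#' @param rep replicate index (integer, default 0).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, cell = 0, rep = 0) {
  m <- 2147483647
  s <- (abs(master) %% m)
  s <- (s * 48271) %% m
  s <- (s + (cell %% m) * 69621 + (rep %% m) * 16807) %% m
  s <- (s * 48271) %% m
  as.integer(s %% (m - 1) + 1)
}

#' Simulate one female life history
#'
#' Integrates the coupled female-calf Dynamic Energy Budget ODEs from the
#' female's weaning (age `T_L`, simulation time 0 = mid-spring) until her
#' death, interrupting the integration at reproductive-phase transitions,
#' births, weanings, disturbance-window edges and deaths. Reserve masses and
#' log-survival are integrated with a classical Runge-Kutta scheme between
#' breakpoints; state-dependent events (pregnancy-threshold crossings,
#' survival-threshold and condition-floor deaths) are localized by bisection.
#'
#' In `"fixed"` mode both female and calves die when survival drops below
#' `p$survival_threshold` (a 60-yr life expectancy at birth); in `"random"`
#' mode each individual draws a uniform death threshold when its tracking
#' starts (the female at weaning, each calf at birth), which is the
#' Monte-Carlo mode used for estimating R0.
#'
#' @param p a [deb_parameters()] object.
#' @param env a [environment_spec()] object.
#' @param mode `"fixed"` or `"random"` life expectancy.
#' @param seed integer seed (random mode); ignored in fixed mode.
#' @param dt integrator step bound, d.
#' @param t_max_yr simulation horizon, yr (safety cap).
#' @param record logical; keep a trajectory sampled every `dt_record` d.
#' @param dt_record trajectory sampling interval, d.
#' @param ibi_quirk logical; open the within-lactation waiting window one day
#'   into the final gestation-length stretch of lactation, so that the gap
#'   between a weaning and the next conception is `T_D - (T_P - 1)` = 81 d
#'   and the minimum inter-birth interval is 4.57 yr.
#' @param a0 female age at simulation start, d (default: weaning age `T_L`).
#' @param F0 initial reserve mass, kg (default: reserves at the target
#'   condition, `rho * S / (1 - rho)`).
#' @param reproduce logical; `FALSE` simulates a non-reproductive female
#'   (no state-machine transitions), used for equilibration checks.
#' @param uniforms optional vector of uniform draws overriding the seeded
#'   stream (element 1: female threshold; 2...: calf thresholds in birth
#'   order).
#' @return An object of class `deb_life`: a list with the death age and
#'   cause, birth/weaning/calf-death ages (yr), `n_births`, `n_weaned`,
#'   `LRO` (weaned female offspring, `n_weaned/2`), `AfR` (age at first
#'   parturition, yr), `first_crossing_age_yr` (first pregnancy-threshold
#'   crossing), `AfW` (age at first weaning), `IBI` (inter-birth intervals,
#'   yr), `starvation_days`, a per-calf energy table `calves`, and (if
#'   `record`) a `trajectory` data frame.
#' @examples
#' \donttest{
#' p <- deb_parameters()
#' life <- simulate_life(p, environment_spec(R_hat = 1.8))
#' life$n_weaned
#' }
#' @export
simulate_life <- function(p, env, mode = c("fixed", "random"), seed = NULL,
                          dt = 0.25, t_max_yr = 150, record = FALSE,
                          dt_record = 1, ibi_quirk = TRUE, a0 = p$T_L,
                          F0 = NULL, reproduce = TRUE, uniforms = NULL) {
  stopifnot(inherits(p, "deb_parameters"), inherits(env, "deb_environment"))
  mode <- match.arg(mode)
  if (is.null(F0)) {
    S0 <- structural_mass(length_at_age(a0, p), p)
    F0 <- p$rho * S0 / (1 - p$rho)
  }
  if (mode == "random" && is.null(uniforms)) {
    if (is.null(seed)) stop("random mode requires a seed", call. = FALSE)
    old <- .Random.seed_exists()
    set.seed(seed)
    uniforms <- stats::runif(64L)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  if (is.null(uniforms)) uniforms <- numeric(0)

  raw <- .simulate_life_cpp(unclass(p), unclass(env), mode == "fixed",
                            uniforms, dt, t_max_yr * 365, record, dt_record,
                            ibi_quirk, a0, F0, reproduce)

  birth <- raw$birth_ages_yr
  wean <- raw$weaning_ages_yr
  out <- list(
    death_age_yr = raw$death_age_yr,
    death_cause = raw$death_cause,
    n_births = raw$n_births,
    n_weaned = raw$n_weaned,
    LRO = raw$n_weaned / 2,
    AfR = if (length(birth)) birth[[1]] else NA_real_,
    first_crossing_age_yr = raw$first_crossing_age_yr,
    AfW = if (length(wean)) wean[[1]] else NA_real_,
    birth_ages_yr = birth,
    weaning_ages_yr = wean,
    calf_death_female_ages_yr = raw$calf_death_female_ages_yr,
    calf_death_calf_ages_d = raw$calf_death_calf_ages_d,
    IBI = if (length(birth) > 1) diff(birth) else numeric(0),
    starvation_days = raw$starvation_days,
    final_survival = raw$final_survival,
    calves = as.data.frame(raw$calves),
    mode = mode, seed = seed, env = env
  )
  if (record) {
    tr <- as.data.frame(raw$trajectory)
    names(tr) <- .traj_colnames
    tr$phase <- factor(.phase_levels[tr$phase + 1], levels = .phase_levels)
    out$trajectory <- tr
  }
  structure(out, class = "deb_life")
}

# internal: stash of .Random.seed if present (so simulate_life does not
# disturb the caller's RNG state)
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

#' @export
print.deb_life <- function(x, ...) {
  cat("<deb_life> ", x$mode, "-mode life history\n", sep = "")
  cat(sprintf(
    "  LRO %.1f | births %d | weaned %d | AfR %s yr | AfW %s yr | LE %s yr\n",
    x$LRO, x$n_births, x$n_weaned,
    if (is.na(x$AfR)) "-" else sprintf("%.1f", x$AfR),
    if (is.na(x$AfW)) "-" else sprintf("%.1f", x$AfW),
    if (is.na(x$death_age_yr)) "-" else sprintf("%.1f", x$death_age_yr)))
  if (length(x$IBI))
    cat(sprintf("  mean IBI %.2f yr | starvation %.1f d | cause: %s\n",
                mean(x$IBI), x$starvation_days, x$death_cause))
  invisible(x)
}

#' Write a simulated trajectory to CSV
#'
#' One row per output step with time, age, reproductive phase, sizes,
#' condition, survival and all energy flows of female and calf -- sufficient
#' to redraw reserve-mass and energy-budget figures.
#'
#' @param life a [simulate_life()] result with `record = TRUE`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(life, path) {
  stopifnot(inherits(life, "deb_life"))
  if (is.null(life$trajectory))
    stop("life was simulated without record = TRUE", call. = FALSE)
  utils::write.csv(life$trajectory, path, row.names = FALSE)
  invisible(path)
}
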