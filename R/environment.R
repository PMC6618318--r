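# Seasonal resource forcing and the yearly recurrent disturbance window.

#' Specify the environment and disturbance scenario
#'
#' Resource density follows `R_hat * (1 + A * sin(2*pi*t/365))`: mean `R_hat`
#' and rising at `t = 0` (labelled mid-spring, when the simulated female is
#' initiated), peaking in mid-summer (day 91) and lowest in mid-winter
#' (day 273). Disturbance is a yearly recurrent block of
#' `disturbance_days` consecutive days during which resource ingestion of
#' female and calf is zero; milk transfer is unaffected.
#'
#' @param R_hat mean annual resource density, MJ/m^3 (`> 0`).
#' @param A relative seasonal amplitude in `[0, 1)`.
#' @param disturbance_days consecutive days of lost foraging per year
#'   (`0` to `365`).
#' @param disturbance_season `"summer"` (window opens day 91), `"winter"`
#'   (day 273), or a numeric day-of-year in `[0, 365)`. Constant-resource
#'   runs (`A = 0`) default to the winter label.
#' @return An object of class `deb_environment`.
#' @export
environment_spec <- function(R_hat = 1.8, A = 0, disturbance_days = 0,
                             disturbance_season = "winter") {
  if (!is.numeric(R_hat) || length(R_hat) != 1L || R_hat <= 0)
    stop("R_hat must be a single positive number", call. = FALSE)
  if (!is.numeric(A) || length(A) != 1L || A < 0 || A >= 1)
    stop("A must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(disturbance_days) || length(disturbance_days) != 1L ||
      disturbance_days < 0 || disturbance_days > 365)
    stop("disturbance_days must lie in [0, 365]", call. = FALSE)
  start <- if (is.numeric(disturbance_season)) {
    if (disturbance_season < 0 || disturbance_season >= 365)
      stop("numeric disturbance_season must lie in [0, 365)", call. = FALSE)
    disturbance_season
  } else {
    switch(match.arg(disturbance_season, c("summer", "winter")),
           summer = 91, winter = 273)
  }
  structure(list(R_hat = R_hat, A = A,
                 disturbance_days = disturbance_days,
                 disturbance_start = start, period = 365),
            class = "deb_environment")
}

#' @export
print.deb_environment <- function(x, ...) {
  cat(sprintf(
    "<deb_environment> R_hat = %g MJ/m^3, A = %g, disturbance = %g d/yr%s\n",
    x$R_hat, x$A, x$disturbance_days,
    if (x$disturbance_days > 0)
      sprintf(" from day %g", x$disturbance_start) else ""))
  invisible(x)
}

#' Seasonal resource density
#'
#' `R(t) = R_hat * (1 + A * sin(2*pi*t/365))`; periodic with annual mean
#' `R_hat`, at the mean and rising at `t = 0`.
#'
#' @param t simulation time, d (vectorized).
#' @param env a [environment_spec()] object.
#' @return Resource density in MJ/m^3.
#' @export
resource_density <- function(t, env) {
  env$R_hat * (1 + env$A * sin(2 * pi * t / env$period))
}

#' Is a time point inside the disturbance window?
#'
#' TRUE iff `t mod 365` falls in `[start, start + duration)`, wrapping across
#' the year boundary when the window extends past day 365.
#'
#' @inheritParams resource_density
#' @return Logical vector.
#' @export
is_disturbed <- function(t, env) {
  if (env$disturbance_days <= 0) return(rep(FALSE, length(t)))
  doy <- t %% env$period
  s <- env$disturbance_start
  e <- s + env$disturbance_days
  if (e <= env$period) doy >= s & doy < e
  else doy >= s | doy < (e - env$period)
}

#' Resource density as experienced (zero while disturbed)
#'
#' Disturbance acts as a multiplicative feeding switch on resource ingestion
#' of the female and her calf alike; lactation continues during disturbance
#' and metabolic costs are unchanged.
#'
#' @inheritParams resource_density
#' @return Resource density in MJ/m^3, `0` inside the disturbance window.
#' @export
effective_resource <- function(t, env) {
  ifelse(is_disturbed(t, env), 0, resource_density(t, env))
}
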