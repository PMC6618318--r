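# Monte-Carlo estimation of R0 and life-history statistics, bootstrap
# confidence intervals, sweep grids and the disturbance-threshold estimator.

#' Nonparametric bootstrap confidence interval for a mean
#'
#' Resamples `x` with replacement `n_boot` times. The `"basic"` interval is
#' `2*mean(x) - quantile(boot, c(.975, .025))`; the `"percentile"` interval
#' uses the bootstrap quantiles directly.
#'
#' @param x numeric sample (NAs dropped).
#' @param n_boot number of resamples (default 1000).
#' @param type `"basic"` or `"percentile"`.
#' @param conf confidence level (default 0.95).
#' @return Named vector `c(mean, lower, upper)`.
#' @export
bootstrap_ci <- function(x, n_boot = 1000, type = c("basic", "percentile"),
                         conf = 0.95) {
  type <- match.arg(type)
  x <- x[!is.na(x)]
  if (!length(x)) return(c(mean = NA_real_, lower = NA_real_,
                           upper = NA_real_))
  m <- mean(x)
  if (length(x) == 1L) return(c(mean = m, lower = m, upper = m))
  bm <- vapply(seq_len(n_boot), function(i)
    mean(x[sample.int(length(x), replace = TRUE)]), 0)
  a <- (1 - conf) / 2
  q <- stats::quantile(bm, c(a, 1 - a), names = FALSE, type = 7)
  ci <- if (type == "basic") c(2 * m - q[2], 2 * m - q[1]) else q
  c(mean = m, lower = min(ci, m), upper = max(ci, m))
}

.mc_statistics <- c("R0", "life_expectancy_yr", "proportion_weaned",
                    "AfR_yr", "AfW_yr", "IBI_yr")

#' Monte-Carlo life-history statistics under random life expectancy
#'
#' Runs `n_reps` independent random-mode [simulate_life()] replicates and
#' summarizes lifetime reproductive output (R0: weaned female calves, i.e.
#' `n_weaned/2`), life expectancy (mean age at death), proportion of calves
#' surviving to weaning, age at first reproduction, age at first weaning and
#' the mean inter-birth interval, each with a bootstrap confidence interval
#' of the mean. Replicate `i`'s random stream derives from
#' `derive_seed(seed, cell, i)`, independent of execution order.
#'
#' @param p a [deb_parameters()] object.
#' @param env a [environment_spec()] object.
#' @param n_reps number of simulated life histories (default 1000).
#' @param seed master seed.
#' @param n_boot bootstrap resamples for the CIs (default 1000).
#' @param ci_type `"basic"` (default) or `"percentile"`.
#' @param cell scenario-cell index used in stream derivation (default 0).
#' @param dt integrator step bound, d.
#' @param keep_records logical; retain the individual `deb_life` records.
#' @return An object of class `deb_montecarlo`: a list with `summary` (one
#'   row per statistic: mean, lower, upper), the per-replicate `replicates`
#'   data frame, the scenario echo and the seed.
#' @export
run_monte_carlo <- function(p, env, n_reps = 1000, seed = 1,
                            n_boot = 1000, ci_type = "basic", cell = 0,
                            dt = 0.25, keep_records = FALSE) {
  stopifnot(n_reps >= 1)
  recs <- vector("list", n_reps)
  rep_df <- data.frame(rep = seq_len(n_reps), R0 = NA_real_,
                       life_expectancy_yr = NA_real_,
                       proportion_weaned = NA_real_, AfR_yr = NA_real_,
                       AfW_yr = NA_real_, IBI_yr = NA_real_,
                       n_births = NA_integer_, n_weaned = NA_integer_)
  for (i in seq_len(n_reps)) {
    life <- simulate_life(p, env, mode = "random",
                          seed = derive_seed(seed, cell, i), dt = dt)
    rep_df$R0[i] <- life$LRO
    rep_df$life_expectancy_yr[i] <- life$death_age_yr
    rep_df$proportion_weaned[i] <-
      if (life$n_births > 0) life$n_weaned / life$n_births else NA_real_
    rep_df$AfR_yr[i] <- life$AfR
    rep_df$AfW_yr[i] <- life$AfW
    rep_df$IBI_yr[i] <- if (length(life$IBI)) mean(life$IBI) else NA_real_
    rep_df$n_births[i] <- life$n_births
    rep_df$n_weaned[i] <- life$n_weaned
    if (keep_records) recs[[i]] <- life
  }
  # bootstrap streams are derived from the master seed as well
  old <- .Random.seed_exists()
  set.seed(derive_seed(seed, cell, 2147480000))
  summ <- do.call(rbind, lapply(.mc_statistics, function(s) {
    ci <- bootstrap_ci(rep_df[[s]], n_boot = n_boot, type = ci_type)
    data.frame(statistic = s, mean = ci[["mean"]], lower = ci[["lower"]],
               upper = ci[["upper"]], stringsAsFactors = FALSE)
  }))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(summary = summ, replicates = rep_df, env = env,
                 n_reps = n_reps, seed = seed, ci_type = ci_type,
                 records = if (keep_records) recs else NULL),
            class = "deb_montecarlo")
}

#' @export
print.deb_montecarlo <- function(x, ...) {
  cat(sprintf("<deb_montecarlo> %d replicates, R_hat = %g, A = %g, %g d/yr\n",
              x$n_reps, x$env$R_hat, x$env$A, x$env$disturbance_days))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Disturbance duration at which R0 crosses replacement
#'
#' Fits a cubic smoothing spline (GCV-chosen smoothness) to mean lifetime
#' reproductive output as a function of disturbance duration and locates the
#' smallest duration at which the spline crosses `R0 = 1` by bracketed
#' bisection on a fine grid. If the spline is non-monotone and yields
#' multiple crossings, an isotonic (nonincreasing) regression is used as a
#' fallback before root finding. Returns the sentinel `NA` (field
#' `threshold_days`) when R0 never brackets 1 on the grid span.
#'
#' @param durations disturbance durations, d (sorted, distinct, `>= 4`).
#' @param R0 mean lifetime reproductive output at each duration.
#' @param level the crossing level (default 1, the replacement rate).
#' @return An object of class `deb_threshold`: list with `threshold_days`
#'   (or `NA`), the fitted values `fit`, and the inputs.
#' @export
estimate_threshold <- function(durations, R0, level = 1) {
  if (length(durations) < 4) stop("need at least 4 grid points",
                                  call. = FALSE)
  if (is.unsorted(durations, strictly = TRUE))
    stop("durations must be sorted and distinct", call. = FALSE)
  if (length(R0) != length(durations))
    stop("durations and R0 lengths differ", call. = FALSE)

  fit_fun <- local({
    sp <- stats::smooth.spline(durations, R0, cv = FALSE)
    function(x) stats::predict(sp, x)$y
  })
  grid <- seq(min(durations), max(durations), length.out = 2001)
  root_of <- function(f) {
    v <- f(grid) - level
    idx <- which(v[-length(v)] > 0 & v[-1] <= 0)
    if (!length(idx)) return(list(root = NA_real_, n = 0L))
    roots <- vapply(idx, function(i)
      stats::uniroot(function(x) f(x) - level, c(grid[i], grid[i + 1]),
                     tol = 1e-8)$root, 0)
    list(root = min(roots), n = length(roots))
  }
  r <- root_of(fit_fun)
  if (r$n > 1L) {  # spurious wiggles: monotone nonincreasing fallback
    iso <- stats::isoreg(durations, -R0)
    f_iso <- stats::approxfun(durations, -iso$yf, rule = 2)
    fit_fun <- function(x) -f_iso(x)
    r <- root_of(fit_fun)
  }
  structure(list(threshold_days = r$root, durations = durations, R0 = R0,
                 fit = fit_fun(durations), level = level),
            class = "deb_threshold")
}

#' @export
print.deb_threshold <- function(x, ...) {
  cat("<deb_threshold> R0 =", x$level, "at",
      if (is.na(x$threshold_days)) "no crossing on grid"
      else sprintf("%.2f d/yr", x$threshold_days), "\n")
  invisible(x)
}

#' Factorial scenario sweep
#'
#' Runs [run_monte_carlo()] over the full factorial of mean resource
#' densities, seasonal amplitudes, disturbance durations and seasons, and
#' estimates the disturbance-threshold duration (R0 = 1) for every
#' (R_hat, A, season) slice with at least four durations. Each cell's
#' replicate streams derive from (seed, cell index, replicate index), so the
#' results are reproducible regardless of execution order.
#'
#' @param p a [deb_parameters()] object.
#' @param R_hat mean resource densities (paper grid: 1.6--3.0).
#' @param A seasonal amplitudes (paper grid: 0, 0.15, 0.3, 0.45).
#' @param durations disturbance durations, d (paper grid: 0, 5, ..., 50).
#' @param seasons disturbance seasons (`"summer"`, `"winter"`).
#' @param n_reps replicates per cell.
#' @param seed master seed.
#' @param n_boot bootstrap resamples per cell.
#' @param dt integrator step bound, d.
#' @param verbose print progress to stderr.
#' @return A list with `summary` (one row per cell x statistic) and
#'   `thresholds` (one row per (R_hat, A, season)).
#' @export
run_sweep <- function(p, R_hat = c(1.6, 1.7, 1.8, 2.0, 2.2, 2.4, 2.6,
                                   2.8, 3.0),
                      A = c(0, 0.15, 0.3, 0.45),
                      durations = seq(0, 50, by = 5),
                      seasons = c("summer", "winter"),
                      n_reps = 1000, seed = 1, n_boot = 1000, dt = 0.25,
                      verbose = FALSE) {
  cells <- expand.grid(R_hat = R_hat, A = A, duration = durations,
                       season = seasons, stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    env <- environment_spec(R_hat = cl$R_hat, A = cl$A,
                            disturbance_days = cl$duration,
                            disturbance_season = cl$season)
    if (verbose)
      message(sprintf("cell %d/%d: R=%g A=%g d=%g %s", i, nrow(cells),
                      cl$R_hat, cl$A, cl$duration, cl$season))
    mc <- run_monte_carlo(p, env, n_reps = n_reps, seed = seed,
                          n_boot = n_boot, cell = i, dt = dt)
    s <- mc$summary
    s$R_hat <- cl$R_hat; s$A <- cl$A; s$duration <- cl$duration
    s$season <- cl$season
    out[[i]] <- s
  }
  summary <- do.call(rbind, out)

  slices <- unique(cells[, c("R_hat", "A", "season")])
  th <- lapply(seq_len(nrow(slices)), function(j) {
    sl <- slices[j, ]
    sub <- summary[summary$statistic == "R0" & summary$R_hat == sl$R_hat &
                     summary$A == sl$A & summary$season == sl$season, ]
    sub <- sub[order(sub$duration), ]
    thr <- if (nrow(sub) >= 4)
      estimate_threshold(sub$duration, sub$mean)$threshold_days
    else NA_real_
    data.frame(R_hat = sl$R_hat, A = sl$A, season = sl$season,
               threshold_days = thr, stringsAsFactors = FALSE)
  })
  list(summary = summary, thresholds = do.call(rbind, th))
}
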