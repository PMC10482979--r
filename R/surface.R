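# Scaled thermal response surface over MET x instantaneous temperature, and
# warming-scenario calculus (adapted vs non-adapted respiration).

#' Min-max scale predicted rates over a temperature grid
#'
#' scaled = (r - min(r)) / (max(r) - min(r)), applied to model-predicted
#' rates so every curve spans exactly [0, 1] on its grid. Invariant to
#' multiplying all rates by a positive constant.
#'
#' @param fit An `mmrt_fit`, an [mmrt_params()] object, or a numeric vector
#'   of rates.
#' @param temp_grid Temperatures (C) at which to evaluate (ignored for a
#'   numeric vector input).
#' @return Numeric vector of scaled rates in [0, 1].
#' @export
#' @examples
#' scale_curve(c(2, 4, 6))
scale_curve <- function(fit, temp_grid = seq(4, 42, by = 0.1)) {
  r <- if (is.numeric(fit)) {
    fit
  } else if (inherits(fit, "mmrt_fit")) {
    predict(fit, data.frame(temperature_c = temp_grid))
  } else if (inherits(fit, "mmrt_params")) {
    mmrt_rate(celsius_to_kelvin(temp_grid), fit)
  } else {
    stop("unsupported input to scale_curve", call. = FALSE)
  }
  rng <- range(r)
  if (rng[2] - rng[1] <= 0) stop("flat curve cannot be min-max scaled",
                                 call. = FALSE)
  (r - rng[1]) / (rng[2] - rng[1])
}

#' Build the scaled respiration surface over MET x instantaneous temperature
#'
#' Each converged curve is predicted on `temp_grid`, min-max scaled, and, at
#' every instantaneous temperature, a cubic smoothing spline with `df`
#' effective degrees of freedom is fitted to scaled rate against the curves'
#' MET values and evaluated on `met_grid`. Cells are clipped to [0, 1].
#'
#' @param fit_table Converged [fit_cohort()] rows with `met` (and the
#'   thermodynamic parameter columns).
#' @param temp_grid Instantaneous temperatures (C), default 4-42 by 0.1.
#' @param met_grid MET grid (C); default spans the observed MET at 0.1 C.
#' @param df Spline degrees of freedom, default 3. Reduced (with a warning)
#'   if there are fewer than `df + 1` distinct MET values.
#' @return Object of class `thermal_surface`: `met_grid`, `temp_grid`,
#'   `scaled` (matrix, rows = MET, cols = temperature), `df`, `source`
#'   (soil ids used).
#' @export
build_surface <- function(fit_table, temp_grid = seq(4, 42, by = 0.1),
                          met_grid = NULL, df = 3) {
  stopifnot("met" %in% names(fit_table))
  tab <- fit_table[isTRUE_vec(fit_table$converged), , drop = FALSE]
  n_met <- length(unique(tab$met))
  if (nrow(tab) < 4 || n_met < 4) {
    stop("need >= 4 curves with >= 4 distinct MET values", call. = FALSE)
  }
  if (n_met < df + 1) {
    df <- n_met - 1
    warning("fewer MET values than df + 1; df reduced to ", df, call. = FALSE)
  }
  if (is.null(met_grid)) {
    met_grid <- seq(min(tab$met), max(tab$met), by = 0.1)
  }
  scaled_obs <- matrix(NA_real_, nrow(tab), length(temp_grid))
  for (i in seq_len(nrow(tab))) {
    p <- mmrt_params(dH = tab$dH[i], dS = tab$dS[i], A = tab$A[i],
                     B = tab$B[i], T0 = tab$T0[i])
    scaled_obs[i, ] <- scale_curve(p, temp_grid)
  }
  surf <- matrix(NA_real_, length(met_grid), length(temp_grid))
  for (j in seq_along(temp_grid)) {
    sp <- stats::smooth.spline(tab$met, scaled_obs[, j], df = df)
    surf[, j] <- stats::predict(sp, met_grid)$y
  }
  surf[surf < 0] <- 0
  surf[surf > 1] <- 1
  structure(list(met_grid = met_grid, temp_grid = temp_grid, scaled = surf,
                 df = df, source = tab$soil_id),
            class = "thermal_surface")
}

isTRUE_vec <- function(x) if (is.null(x)) TRUE else x %in% TRUE

#' @export
print.thermal_surface <- function(x, ...) {
  cat("Scaled thermal response surface\n")
  cat(sprintf("  MET %g-%g C (%d), temperature %g-%g C (%d), spline df = %g\n",
              min(x$met_grid), max(x$met_grid), length(x$met_grid),
              min(x$temp_grid), max(x$temp_grid), length(x$temp_grid), x$df))
  cat("  built from", length(x$source), "curves\n")
  invisible(x)
}

#' @export
as.data.frame.thermal_surface <- function(x, ...) {
  data.frame(met = rep(x$met_grid, times = length(x$temp_grid)),
             temp = rep(x$temp_grid, each = length(x$met_grid)),
             scaled = as.vector(x$scaled))
}

#' Plot the thermal surface as a filled contour
#'
#' @param x A `thermal_surface`.
#' @param ... Passed to [graphics::filled.contour()].
#' @export
plot.thermal_surface <- function(x, ...) {
  graphics::filled.contour(
    x$met_grid, x$temp_grid, x$scaled,
    color.palette = function(n) grDevices::hcl.colors(n, "RdYlBu", rev = TRUE),
    xlab = "Mean environmental soil temperature (°C)",
    ylab = "Instantaneous temperature (°C)", ...)
  invisible(x)
}

# linear interpolation of a surface row (fixed MET) across the met grid
surface_row <- function(surface, met) {
  if (met < min(surface$met_grid) || met > max(surface$met_grid)) {
    stop("MET ", met, " outside the surface's MET grid", call. = FALSE)
  }
  vapply(seq_along(surface$temp_grid), function(j) {
    stats::approx(surface$met_grid, surface$scaled[, j], xout = met)$y
  }, numeric(1))
}

#' Warming-scenario differences between adapted and non-adapted responses
#'
#' The non-adapted response is the surface row at the baseline MET `met0`
#' (community unchanged by warming); the adapted response is the row at
#' `met0 + delta` (community adapted to the warmed mean). Reports, along the
#' instantaneous temperature grid, the difference adapted vs non-adapted and
#' the change of each response relative to the pre-warming rate at
#' `T = met0`.
#'
#' Because the surface is built from min-max scaled rates, the scaled value
#' is the fraction of a soil's total potential respiration, and differences
#' are naturally expressed in percentage points of that potential
#' (`units = "points"`, the default): a value of 18 means respiration moved
#' by 18 % of the potential maximum. `units = "ratio"` instead reports
#' relative differences, 100 * (adapted - nonadapted) / nonadapted, with
#' cells where the non-adapted rate is below `eps` masked (NA).
#'
#' @param surface A [build_surface()] result.
#' @param met0 Baseline MET (C).
#' @param delta Warming (C); both `met0` and `met0 + delta` must lie inside
#'   the MET grid.
#' @param units `"points"` (percentage points of the potential maximum,
#'   default) or `"ratio"` (relative percent).
#' @param eps Mask threshold on the scaled non-adapted rate for
#'   `units = "ratio"`, default 0.02.
#' @return Object of class `scenario_result`: `met0`, `delta`, `temp_grid`,
#'   `nonadapted`, `adapted`, `pct_diff`, `pct_change_nonadapted`,
#'   `pct_change_adapted` (both relative to the pre-warming rate at
#'   `T = met0`), `units`, `n_masked`.
#' @export
scenario <- function(surface, met0, delta, units = c("points", "ratio"),
                     eps = 0.02) {
  units <- match.arg(units)
  nonad <- surface_row(surface, met0)
  adap <- surface_row(surface, met0 + delta)
  base <- stats::approx(surface$temp_grid, nonad, xout = met0)$y
  n_masked <- 0L
  if (units == "points") {
    pct_diff <- 100 * (adap - nonad)
    chg_non <- 100 * (nonad - base)
    chg_ad <- 100 * (adap - base)
  } else {
    mask <- nonad < eps
    n_masked <- sum(mask)
    pct_diff <- ifelse(mask, NA_real_, 100 * (adap - nonad) / nonad)
    if (!is.finite(base) || base < eps) {
      warning("pre-warming baseline rate at T = met0 is below eps; ",
              "relative change curves unreliable", call. = FALSE)
    }
    chg_non <- 100 * (nonad - base) / base
    chg_ad <- 100 * (adap - base) / base
  }
  structure(
    list(met0 = met0, delta = delta, temp_grid = surface$temp_grid,
         nonadapted = nonad, adapted = adap, pct_diff = pct_diff,
         pct_change_nonadapted = chg_non,
         pct_change_adapted = chg_ad,
         units = units, n_masked = n_masked, eps = eps),
    class = "scenario_result")
}

#' Interpolate a scenario curve at given instantaneous temperatures
#'
#' @param x A [scenario()] result.
#' @param temp Instantaneous temperatures (C).
#' @param what One of `"pct_diff"`, `"pct_change_nonadapted"`,
#'   `"pct_change_adapted"`, `"nonadapted"`, `"adapted"`.
#' @return Numeric vector.
#' @export
scenario_at <- function(x, temp,
                        what = c("pct_diff", "pct_change_nonadapted",
                                 "pct_change_adapted", "nonadapted",
                                 "adapted")) {
  what <- match.arg(what)
  stats::approx(x$temp_grid, x[[what]], xout = temp)$y
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Warming scenario: MET %g C -> %g C (+%g C)\n",
              x$met0, x$met0 + x$delta, x$delta))
  unit_lab <- if (x$units == "points") "points of potential" else "%"
  warmed <- x$met0 + x$delta
  cat(sprintf("  at T = %.1f C: non-adapted %+.1f, adapted %+.1f %s vs pre-warming\n",
              warmed, scenario_at(x, warmed, "pct_change_nonadapted"),
              scenario_at(x, warmed, "pct_change_adapted"), unit_lab))
  if (x$n_masked) cat("  ", x$n_masked, "cells masked (non-adapted rate <",
                      x$eps, ")\n")
  invisible(x)
}

#' @export
plot.scenario_result <- function(x, ...) {
  plot(x$temp_grid, x$pct_diff, type = "l", lwd = 2,
       xlab = "Instantaneous temperature (°C)",
       ylab = "Adapted vs non-adapted (%)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
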