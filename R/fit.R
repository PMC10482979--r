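# Non-linear least-squares fitting of the modified MMRT model to respiration
# curves, AICc model comparison between the varying- and constant-heat-
# capacity variants, and cohort-level fitting.

#' Control parameters for MMRT fitting
#'
#' @param B_starts Starting values for the heat capacity B (J mol^-1 K^-1).
#' @param A_starts Starting values for the heat-capacity slope A
#'   (J mol^-1 K^-2); only used by the varying-heat-capacity variant.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param ftol Relative residual-sum-of-squares convergence tolerance.
#' @param maxfev Maximum objective evaluations per start.
#' @return A list of control settings.
#' @export
mmrt_control <- function(B_starts = c(-500, -1000, -2000, -4000),
                         A_starts = c(0, -5, 5, -20, 20),
                         maxiter = 200, ftol = 1e-10, maxfev = 5000) {
  list(B_starts = B_starts, A_starts = A_starts, maxiter = maxiter,
       ftol = ftol, maxfev = maxfev)
}

# Plain-arithmetic log-rate used inside the nls formula (no validation, so
# the optimiser can probe freely).
mmrt_lnr_raw <- function(temp_k, dH, dS, A, B, T0) {
  kB <- 1.380649e-23; h <- 6.62607015e-34; R <- 8.314462618
  dcp <- A * (temp_k - T0) + B
  log(kB * temp_k / h) - dH / (R * temp_k) -
    dcp * (temp_k - T0) / (R * temp_k) + dS / R +
    dcp * (log(temp_k) - log(T0)) / R
}

# Arrhenius slope of the rising limb -> starting enthalpy; entropy start is
# then chosen so the curve passes through the empirical peak.
starting_dH <- function(temp_k, lnr) {
  peak <- which.max(lnr)
  if (peak >= 4) {
    idx <- seq_len(peak)
    sl <- stats::coef(stats::lm(lnr[idx] ~ I(1 / temp_k[idx])))[2]
    dH0 <- -sl * mmrt_constants()$R
    if (is.finite(dH0) && dH0 > 1e3 && dH0 < 5e5) return(unname(dH0))
  }
  6e4
}

starting_dS <- function(temp_k, lnr, dH, A, B, T0) {
  peak <- which.max(lnr)
  p0 <- mmrt_params(dH = dH, dS = 0, A = A, B = B, T0 = T0)
  unname(mmrt_constants()$R * (lnr[peak] - mmrt_log_rate(temp_k[peak], p0)))
}

#' Fit the modified MMRT model to a temperature response curve
#'
#' Fits ln(rate) against temperature by non-linear least squares
#' (Levenberg-Marquardt, multi-start), either with the activation heat
#' capacity varying linearly with temperature (`variant = "varying_cp"`,
#' 4 curve parameters) or held constant (`"constant_cp"`, A fixed at 0,
#' 3 curve parameters). Starting enthalpies come from the Arrhenius slope of
#' the rising limb; entropy starts are chosen to match the empirical peak
#' height; B (and A) starts are taken from `control`. The best start by
#' residual sum of squares wins.
#'
#' @param formula A formula `rate ~ temperature` naming the rate and the
#'   Celsius temperature columns of `data`, e.g. `gir ~ temperature_c`.
#' @param data A data frame holding one soil's curve (all rates positive).
#' @param variant `"varying_cp"` (default) or `"constant_cp"`.
#' @param T0 Reference temperature (K), default 300.
#' @param eval_range Temperature range (C) over which the fitted curve is
#'   summarised for Topt/Tinf; default 4-50 C. Wider than the 42 C fitting
#'   cutoff on purpose: community optima can sit at or just above the
#'   warmest fitted temperatures, and capping the summary grid at the cutoff
#'   would censor them.
#' @param grid_spacing Summary grid spacing (C), default 0.01.
#' @param control See [mmrt_control()].
#' @return An object of class `mmrt_fit` with components `params`
#'   ([mmrt_params()]), `variant`, `rss` (in log-rate space), `n`, `k`
#'   (parameter count including the residual variance), `aicc`, `converged`,
#'   `summary` ([summarize_curve()] result, only when converged), `data`,
#'   `starts_tried`. Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`, `simulate`, `logLik`.
#' @export
#' @examples
#' p <- solve_mmrt_params(35, 24, amplitude = 8)
#' tc <- seq(4, 40, by = 2)
#' d <- data.frame(temperature_c = tc,
#'                 gir = mmrt_rate(celsius_to_kelvin(tc), p))
#' f <- mmrt_fit(gir ~ temperature_c, d)
#' summary(f)
mmrt_fit <- function(formula, data, variant = c("varying_cp", "constant_cp"),
                     T0 = 300, eval_range = c(4, 50), grid_spacing = 0.01,
                     control = mmrt_control()) {
  variant <- match.arg(variant)
  mf <- stats::model.frame(formula, data)
  rate <- mf[[1]]
  temp_c <- mf[[2]]
  if (any(rate <= 0)) {
    stop("all rates must be positive (the model is fitted in log space)",
         call. = FALSE)
  }
  n <- length(rate)
  k <- if (variant == "varying_cp") 5L else 4L  # curve params + residual var
  if (n < k + 2) {
    stop("fit refused: ", n, " points is too few for the ", variant,
         " variant (need >= ", k + 2, ")", call. = FALSE)
  }
  temp_k <- celsius_to_kelvin(temp_c)
  lnr <- log(rate)
  dH0 <- starting_dH(temp_k, lnr)

  A_starts <- if (variant == "varying_cp") control$A_starts else 0
  starts <- expand.grid(B = control$B_starts, A = A_starts)
  best <- NULL
  tried <- 0L
  df_fit <- data.frame(lnr = lnr, temp_k = temp_k)
  for (j in seq_len(nrow(starts))) {
    tried <- tried + 1L
    st <- list(dH = dH0,
               dS = starting_dS(temp_k, lnr, dH0, starts$A[j], starts$B[j], T0),
               B = starts$B[j])
    if (variant == "varying_cp") st$A <- starts$A[j]
    fml <- if (variant == "varying_cp") {
      lnr ~ mmrt_lnr_raw(temp_k, dH, dS, A, B, T0)
    } else {
      lnr ~ mmrt_lnr_raw(temp_k, dH, dS, 0, B, T0)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = cbind(df_fit, T0 = T0), start = st,
                        control = minpack.lm::nls.lm.control(
                          maxiter = control$maxiter, ftol = control$ftol,
                          maxfev = control$maxfev)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }

  if (is.null(best)) {
    out <- structure(
      list(params = NULL, variant = variant, rss = NA_real_, n = n, k = k,
           aicc = NA_real_, converged = FALSE, summary = NULL,
           data = data.frame(temperature_c = temp_c, rate = rate),
           starts_tried = tried, call = match.call()),
      class = "mmrt_fit")
    return(out)
  }

  cf <- stats::coef(best$fit)
  params <- mmrt_params(dH = cf[["dH"]], dS = cf[["dS"]],
                        A = if (variant == "varying_cp") cf[["A"]] else 0,
                        B = cf[["B"]], T0 = T0)
  rss <- best$rss
  summ <- withCallingHandlers(
    summarize_curve(params, eval_range = eval_range,
                    grid_spacing = grid_spacing),
    warning = function(w) invokeRestart("muffleWarning")
  )
  structure(
    list(params = params, variant = variant, rss = rss, n = n, k = k,
         aicc = aicc(rss, n, k), converged = TRUE, summary = summ,
         data = data.frame(temperature_c = temp_c, rate = rate),
         starts_tried = tried, call = match.call()),
    class = "mmrt_fit")
}

#' Corrected Akaike information criterion for a least-squares fit
#'
#' Gaussian log-likelihood up to a constant: AIC = n log(rss/n) + 2k, with
#' the finite-sample correction AICc = AIC + 2k(k+1)/(n - k - 1). `k` counts
#' all estimated parameters including the residual variance.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param k Number of estimated parameters (including residual variance).
#' @return AICc value.
#' @export
#' @examples
#' aicc(rss = 20, n = 20, k = 5)
aicc <- function(rss, n, k) {
  stopifnot(rss > 0, n > 0, k > 0)
  if (n <= k + 1) {
    stop("AICc undefined: need n > k + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Choose between the varying- and constant-heat-capacity fits by AICc
#'
#' The fit with the lower AICc is chosen; fits within 2 AICc units are
#' declared equivalent, and ties/equivalence resolve to the
#' varying-heat-capacity variant (the model used for all headline analyses).
#' If one variant failed to converge the other is selected with a caveat.
#'
#' @param fit_varying,fit_constant `mmrt_fit` objects for the two variants.
#' @return A list: `fit` (the chosen `mmrt_fit`), `chosen`, `equivalent`,
#'   `delta_aicc` (constant minus varying), `caveat`.
#' @export
select_variant <- function(fit_varying, fit_constant) {
  okv <- isTRUE(fit_varying$converged)
  okc <- isTRUE(fit_constant$converged)
  if (!okv && !okc) {
    return(list(fit = fit_varying, chosen = "none", equivalent = FALSE,
                delta_aicc = NA_real_, caveat = "neither variant converged"))
  }
  if (!okv || !okc) {
    fit <- if (okv) fit_varying else fit_constant
    return(list(fit = fit, chosen = fit$variant, equivalent = FALSE,
                delta_aicc = NA_real_,
                caveat = paste("only the", fit$variant, "variant converged")))
  }
  delta <- fit_constant$aicc - fit_varying$aicc  # >0 favours varying
  equivalent <- abs(delta) <= 2
  if (equivalent || delta >= 0) {
    list(fit = fit_varying, chosen = "varying_cp", equivalent = equivalent,
         delta_aicc = delta, caveat = NULL)
  } else {
    list(fit = fit_constant, chosen = "constant_cp", equivalent = FALSE,
         delta_aicc = delta, caveat = NULL)
  }
}

#' Fit a cohort of respiration curves and join site metadata
#'
#' Fits both MMRT variants to every soil's curve, selects per soil by AICc
#' (see [select_variant()]), and returns one row per soil with thermodynamic
#' parameters, fit diagnostics and Topt/Tinf. Soils whose curves cannot be
#' fitted (too few points, or no start converges) get `converged = FALSE`
#' rows; downstream analyses should filter on `converged`.
#'
#' @param curves Curve table from [glucose_induced_curves()] (columns
#'   `soil_id`, `temperature_c`, `gir`).
#' @param sites Optional site table with `soil_id` plus metadata columns
#'   (`met`, `ph`, `lat`, `lon`, `cohort`, ...) to join on.
#' @param variant Fixed variant, or `"select"` (default) for per-soil AICc
#'   selection.
#' @param min_points Usability threshold: soils with fewer retained curve
#'   points are refused (a `converged = FALSE` row) rather than fitted,
#'   matching the study design's minimum of 11 usable temperatures per
#'   curve. Set lower to force fitting of sparse curves.
#' @param ... Passed to [mmrt_fit()].
#' @return A data frame, one row per soil: `soil_id`, `variant`, `dH`, `dS`,
#'   `A`, `B`, `T0`, `rss`, `n`, `aicc`, `topt_c`, `tinf_c`, `converged`,
#'   `equivalent`, joined site columns. The `mmrt_fit` objects are attached
#'   as attribute `fits`; unmatched soil ids as attribute `unmatched`.
#' @export
fit_cohort <- function(curves, sites = NULL,
                       variant = c("select", "varying_cp", "constant_cp"),
                       min_points = 11, ...) {
  variant <- match.arg(variant)
  soils <- unique(curves$soil_id)
  if (length(soils) == 0) {
    out <- empty_fit_table()
    attr(out, "fits") <- list()
    return(out)
  }
  rows <- vector("list", length(soils))
  fits <- vector("list", length(soils))
  names(fits) <- as.character(soils)
  for (i in seq_along(soils)) {
    d <- curves[curves$soil_id == soils[i], , drop = FALSE]
    if (nrow(d) < min_points) {
      message("soil '", soils[i], "' refused: ", nrow(d),
              " usable points (< ", min_points, ")")
      rows[[i]] <- cbind(soil_id = soils[i], failed_row("varying_cp"))
      next
    }
    res <- fit_one_soil(d, variant, ...)
    fits[[i]] <- res$fit
    rows[[i]] <- cbind(soil_id = soils[i], res$row)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  unmatched <- character(0)
  if (!is.null(sites)) {
    unmatched <- setdiff(out$soil_id, sites$soil_id)
    if (length(unmatched)) {
      message("no site metadata for: ", paste(unmatched, collapse = ", "))
    }
    out <- merge(out, sites, by = "soil_id", all.x = TRUE, sort = FALSE)
  }
  attr(out, "fits") <- fits
  attr(out, "unmatched") <- unmatched
  out
}

fit_one_soil <- function(d, variant, ...) {
  safe_fit <- function(v) {
    tryCatch(
      withCallingHandlers(
        mmrt_fit(gir ~ temperature_c, d, variant = v, ...),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
  }
  if (variant == "select") {
    fv <- safe_fit("varying_cp")
    fc <- safe_fit("constant_cp")
    if (is.null(fv) && is.null(fc)) {
      return(list(fit = NULL, row = failed_row("varying_cp")))
    }
    if (is.null(fv)) fv <- fc
    if (is.null(fc)) fc <- fv
    sel <- select_variant(fv, fc)
    fit <- sel$fit
    eq <- sel$equivalent
    # adequacy guard: an AICc-preferred variant whose optimum runs off the
    # evaluation grid (typically a runaway heat-capacity slope) yields no
    # usable optimum; fall back to the other variant if its optimum is
    # interior
    other <- if (identical(fit$variant, "varying_cp")) fc else fv
    if (isTRUE(fit$converged) && isTRUE(fit$summary$boundary_censored) &&
        isTRUE(other$converged) && !isTRUE(other$summary$boundary_censored)) {
      fit <- other
      eq <- NA
    }
  } else {
    fit <- safe_fit(variant)
    if (is.null(fit)) return(list(fit = NULL, row = failed_row(variant)))
    eq <- NA
  }
  if (!isTRUE(fit$converged)) {
    return(list(fit = fit, row = failed_row(fit$variant)))
  }
  p <- fit$params
  row <- data.frame(variant = fit$variant, dH = p$dH, dS = p$dS, A = p$A,
                    B = p$B, T0 = p$T0, rss = fit$rss, n = fit$n,
                    aicc = fit$aicc, topt_c = fit$summary$topt_c,
                    tinf_c = fit$summary$tinf_c, converged = TRUE,
                    equivalent = eq)
  list(fit = fit, row = row)
}

failed_row <- function(variant) {
  data.frame(variant = variant, dH = NA_real_, dS = NA_real_, A = NA_real_,
             B = NA_real_, T0 = NA_real_, rss = NA_real_, n = NA_integer_,
             aicc = NA_real_, topt_c = NA_real_, tinf_c = NA_real_,
             converged = FALSE, equivalent = NA)
}

empty_fit_table <- function() {
  cbind(data.frame(soil_id = character(0)), failed_row("varying_cp")[0, ])
}

# ---- S3 methods for mmrt_fit ------------------------------------------------

#' @export
print.mmrt_fit <- function(x, ...) {
  cat("Modified MMRT fit (", x$variant, "), n = ", x$n, "\n", sep = "")
  if (!x$converged) {
    cat("  DID NOT CONVERGE after", x$starts_tried, "starts\n")
    return(invisible(x))
  }
  cat(sprintf("  Topt = %.2f C, Tinf = %.2f C\n",
              x$summary$topt_c, x$summary$tinf_c))
  cat(sprintf("  rss(log) = %.4g, AICc = %.2f\n", x$rss, x$aicc))
  invisible(x)
}

#' @export
summary.mmrt_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mmrt_fit")
}

#' @export
print.summary.mmrt_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (f$converged) {
    print(f$params)
    s <- f$summary
    if (s$boundary_censored) cat("  note: summary is boundary-censored\n")
    if (s$multimodal) cat("  note: curve multimodal on evaluation range\n")
    cat(sprintf("  residual SD (log rate): %.4f\n", sqrt(f$rss / f$n)))
  }
  invisible(x)
}

#' @export
coef.mmrt_fit <- function(object, ...) {
  if (!object$converged) return(c(dH = NA, dS = NA, A = NA, B = NA, T0 = NA))
  p <- object$params
  c(dH = p$dH, dS = p$dS, A = p$A, B = p$B, T0 = p$T0)
}

#' Predict respiration rates from a fitted MMRT curve
#'
#' @param object An `mmrt_fit`.
#' @param newdata Optional data frame with a `temperature_c` column; defaults
#'   to the fitting data.
#' @param type `"rate"` (default), `"log"` (ln rate) or `"derivative"`
#'   (d rate / dT).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mmrt_fit <- function(object, newdata = NULL,
                             type = c("rate", "log", "derivative"), ...) {
  type <- match.arg(type)
  if (!object$converged) stop("cannot predict from a non-converged fit",
                              call. = FALSE)
  tc <- if (is.null(newdata)) object$data$temperature_c else newdata$temperature_c
  tk <- celsius_to_kelvin(tc)
  switch(type,
         rate = mmrt_rate(tk, object$params),
         log = mmrt_log_rate(tk, object$params),
         derivative = mmrt_rate_deriv(tk, object$params))
}

#' @export
fitted.mmrt_fit <- function(object, ...) predict(object)

#' @export
residuals.mmrt_fit <- function(object, type = c("log", "rate"), ...) {
  type <- match.arg(type)
  if (type == "log") {
    log(object$data$rate) - predict(object, type = "log")
  } else {
    object$data$rate - predict(object)
  }
}

#' @export
logLik.mmrt_fit <- function(object, ...) {
  n <- object$n
  val <- -n / 2 * (log(2 * pi) + 1 + log(object$rss / n))
  structure(val, df = object$k, nobs = n, class = "logLik")
}

#' Plot a fitted MMRT temperature response curve
#'
#' Observed points, the fitted curve, its first derivative (dashed, scaled to
#' the plot), and vertical markers at Topt and Tinf.
#'
#' @param x An `mmrt_fit`.
#' @param ... Passed to `plot()`.
#' @export
plot.mmrt_fit <- function(x, ...) {
  if (!x$converged) stop("nothing to plot: fit did not converge", call. = FALSE)
  rng <- range(x$data$temperature_c)
  tc <- seq(rng[1], rng[2], length.out = 300)
  r <- predict(x, data.frame(temperature_c = tc))
  dr <- predict(x, data.frame(temperature_c = tc), type = "derivative")
  plot(x$data$temperature_c, x$data$rate, xlab = "Temperature (°C)",
       ylab = expression(paste("Glucose-induced respiration (", mu,
                               "g CO"[2], "-C g"^-1, " h"^-1, ")")),
       ylim = range(0, x$data$rate, r), ...)
  lines(tc, r, lwd = 2)
  lines(tc, dr / max(abs(dr)) * max(r) * 0.5, lty = 2)
  abline(v = c(x$summary$topt_c, x$summary$tinf_c), col = 2)
  invisible(x)
}

#' Simulate curves from a fitted MMRT model
#'
#' Draws multiplicative lognormal noise around the fitted curve, with the log
#' scale SD taken from the residual sum of squares.
#'
#' @param object An `mmrt_fit`.
#' @param nsim Number of simulated curves.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated rates at the fitted
#'   temperatures.
#' @export
simulate.mmrt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, type = "log")
  sdlog <- sqrt(object$rss / object$n)
  out <- as.data.frame(replicate(nsim, exp(mu + stats::rnorm(length(mu), 0, sdlog))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
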