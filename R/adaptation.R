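# Thermal-adaptation inference: spatial weights, Moran's I, OLS and the
# simultaneous autoregressive (SAR) error model for Topt/Tinf against mean
# environmental temperature (MET).

#' Build row-standardised spatial weights
#'
#' Constructs a neighbourhood matrix from site coordinates, either k-nearest
#' neighbours (symmetrised: i~j if either is among the other's k nearest) or
#' a fixed distance band. Distances are great-circle metres from lat/lon;
#' metre-scale transect offsets embedded in the coordinates are handled by
#' the same metric. Weights are row-standardised; sites with no neighbours
#' (islands) keep zero rows and are reported.
#'
#' @param sites Data frame with `soil_id`, `lat`, `lon` (decimal degrees).
#' @param method `"knn"` (default) or `"distance_band"`.
#' @param k Number of neighbours for `"knn"`, default 8.
#' @param radius Band radius in metres for `"distance_band"`.
#' @return An object of class `spatial_weights`: `ids`, `W` (row-standardised
#'   matrix), `neighbors` (list of index vectors), `method`, `param`,
#'   `islands`.
#' @export
build_weights <- function(sites, method = c("knn", "distance_band"), k = 8,
                          radius = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("soil_id", "lat", "lon") %in% names(sites)),
            nrow(sites) >= 2)
  n <- nrow(sites)
  D <- geosphere::distm(as.matrix(sites[, c("lon", "lat")]),
                        fun = geosphere::distHaversine)
  if (max(D) <= 0) {
    stop("degenerate geometry: all sites coincide", call. = FALSE)
  }
  adj <- matrix(FALSE, n, n)
  if (method == "knn") {
    k <- min(k, n - 1)
    for (i in seq_len(n)) {
      nn <- order(D[i, ])[-1][seq_len(k)]  # drop self
      adj[i, nn] <- TRUE
    }
    adj <- adj | t(adj)  # symmetrise
    param <- k
  } else {
    if (is.null(radius)) stop("distance_band needs a radius (m)", call. = FALSE)
    adj <- D > 0 & D <= radius
    param <- radius
  }
  diag(adj) <- FALSE
  rs <- rowSums(adj)
  islands <- which(rs == 0)
  W <- matrix(0, n, n)
  nz <- rs > 0
  W[nz, ] <- adj[nz, , drop = FALSE] / rs[nz]
  if (length(islands)) {
    warning(length(islands), " island site(s): ",
            paste(sites$soil_id[islands], collapse = ", "), call. = FALSE)
  }
  structure(list(ids = sites$soil_id, W = W,
                 neighbors = apply(adj, 1, which, simplify = FALSE),
                 method = method, param = param, islands = islands),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("Spatial weights:", length(x$ids), "sites,", x$method,
      "(", x$param, "), row-standardised\n")
  if (length(x$islands)) cat("  islands:", length(x$islands), "\n")
  invisible(x)
}

#' Moran's I with permutation and normal-approximation inference
#'
#' Global spatial autocorrelation statistic
#' I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2
#' with null expectation -1/(n-1). The permutation p-value randomly
#' reassigns values to sites; the analytic normal approximation is delegated
#' to `ape::Moran.I` as an independent cross-check.
#'
#' @param values Numeric vector, one value per site (non-zero variance).
#' @param weights A [build_weights()] object (or a bare weight matrix).
#' @param nperm Number of permutations, default 9999.
#' @param alternative `"greater"` (default; positive autocorrelation),
#'   `"less"`, or `"two.sided"`.
#' @param seed Optional RNG seed for the permutations.
#' @return A list of class `morans_test`: `I`, `expected`, `p_perm`,
#'   `p_normal`, `nperm`, `alternative`.
#' @export
morans_i <- function(values, weights, nperm = 9999,
                     alternative = c("greater", "less", "two.sided"),
                     seed = NULL) {
  alternative <- match.arg(alternative)
  W <- if (inherits(weights, "spatial_weights")) weights$W else weights
  n <- length(values)
  stopifnot(nrow(W) == n)
  if (stats::var(values) == 0) {
    stop("Moran's I undefined: values have zero variance", call. = FALSE)
  }
  S0 <- sum(W)
  stat <- function(x) {
    z <- x - mean(x)
    (n / S0) * drop(z %*% W %*% z) / sum(z^2)
  }
  I_obs <- stat(values)
  if (!is.null(seed)) set.seed(seed)
  I_perm <- replicate(nperm, stat(sample(values)))
  p_greater <- (1 + sum(I_perm >= I_obs)) / (nperm + 1)
  p_less <- (1 + sum(I_perm <= I_obs)) / (nperm + 1)
  p_perm <- switch(alternative,
                   greater = p_greater, less = p_less,
                   two.sided = min(1, 2 * min(p_greater, p_less)))
  ap <- ape::Moran.I(values, W, alternative = alternative)
  structure(list(I = I_obs, expected = -1 / (n - 1), p_perm = p_perm,
                 p_normal = ap$p.value, sd_normal = ap$sd, nperm = nperm,
                 alternative = alternative),
            class = "morans_test")
}

#' @export
print.morans_test <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f)\n", x$I, x$expected))
  cat(sprintf("  permutation p = %.4g (%d perms, %s); normal approx p = %.4g\n",
              x$p_perm, x$nperm, x$alternative, x$p_normal))
  invisible(x)
}

#' Ordinary least-squares adaptation fit
#'
#' Thin wrapper over `stats::lm` that returns the slope record used across
#' the adaptation analyses (one row per metric/model).
#'
#' @param formula Model formula, e.g. `topt_c ~ met`.
#' @param data Fit table joined with site metadata.
#' @return A one-row data frame: `model`, `beta0`, `beta_met` (coefficient on
#'   the first predictor), `se_beta`, `lambda` (NA for OLS), `loglik`, `aic`,
#'   `n`, plus the `lm` object as attribute `fit`.
#' @export
fit_ols <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit)))) {
    stop("collinear (rank-deficient) design in OLS fit", call. = FALSE)
  }
  sm <- summary(fit)
  out <- data.frame(model = "ols",
                    beta0 = stats::coef(fit)[1],
                    beta_met = stats::coef(fit)[2],
                    se_beta = sm$coefficients[2, 2],
                    lambda = NA_real_,
                    loglik = as.numeric(stats::logLik(fit)),
                    aic = stats::AIC(fit),
                    n = stats::nobs(fit))
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' Fit a spatial simultaneous autoregressive (SAR) error model
#'
#' Maximum-likelihood fit of y = X beta + u, u = lambda W u + eps, with W a
#' row-standardised neighbourhood matrix. The likelihood is concentrated in
#' lambda: for a trial lambda the data are spatially filtered by
#' (I - lambda W) and beta, sigma^2 come from least squares on the filtered
#' system; the Jacobian log-determinant is computed from the eigenvalues of
#' W. lambda is constrained to (1/min(eig), 1/max(eig)) and maximised by
#' bounded scalar optimisation.
#'
#' @param formula Model formula, e.g. `topt_c ~ met`.
#' @param data Data frame of responses and predictors.
#' @param weights A [build_weights()] object (site order must match `data`).
#' @param lambda Optional fixed value for the autoregressive coefficient;
#'   `NULL` (default) estimates it by maximum likelihood. `lambda = 0`
#'   reduces the model to OLS.
#' @param tol Optimiser tolerance on lambda, default 1e-8.
#' @return An object of class `sar_error`: `coefficients`, `se`, `lambda`,
#'   `lambda_se`, `loglik`, `aic`, `n`, `fitted.values` (trend X beta),
#'   `residuals` (y - X beta), `sigma2`, `call`. Methods: `print`, `summary`,
#'   `coef`, `residuals`, `fitted`, `logLik`, `predict`.
#' @export
sar_error <- function(formula, data, weights, lambda = NULL, tol = 1e-8) {
  W <- if (inherits(weights, "spatial_weights")) weights$W else weights
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  stopifnot(nrow(W) == n, n >= 5)

  ev <- eigen(W, only.values = TRUE)$values
  if (max(abs(Im(ev))) > 1e-8) {
    ev <- Re(ev)[abs(Im(ev)) < 1e-8]  # complex pairs cannot bound lambda
  } else {
    ev <- Re(ev)
  }
  lam_lo <- if (min(ev) < 0) 1 / min(ev) + 1e-6 else -0.9999
  lam_hi <- 1 / max(ev) - 1e-6

  prof <- function(lambda) {
    A <- diag(n) - lambda * W
    ys <- A %*% y
    Xs <- A %*% X
    fit <- stats::lm.fit(Xs, ys)
    rss <- sum(fit$residuals^2)
    logdet <- sum(log(1 - lambda * ev))
    -n / 2 * (log(2 * pi) + 1 + log(rss / n)) + logdet
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(prof, c(lam_lo, lam_hi), maximum = TRUE, tol = tol)
    lambda <- opt$maximum
    ll <- opt$objective
  } else {
    stopifnot(is.finite(lambda), lambda > lam_lo - 1e-6, lambda < lam_hi + 1e-6)
    ll <- prof(lambda)
  }

  A <- diag(n) - lambda * W
  ys <- A %*% y
  Xs <- A %*% X
  fit <- stats::lm.fit(Xs, ys)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  XtX_inv <- chol2inv(chol(crossprod(Xs)))
  se <- sqrt(diag(sigma2 * XtX_inv))
  names(se) <- names(beta)
  # profile-likelihood curvature -> approximate SE for lambda
  h <- 1e-4 * max(1, abs(lambda))
  d2 <- (prof(min(lambda + h, lam_hi)) - 2 * prof(lambda) +
           prof(max(lambda - h, lam_lo))) / h^2
  lambda_se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  p <- length(beta)
  structure(
    list(coefficients = beta, se = se, lambda = lambda,
         lambda_se = lambda_se, loglik = ll,
         aic = -2 * ll + 2 * (p + 2),  # beta + lambda + sigma2
         n = n, fitted.values = drop(X %*% beta),
         residuals = drop(y - X %*% beta), sigma2 = sigma2,
         formula = formula, call = match.call()),
    class = "sar_error")
}

#' @export
print.sar_error <- function(x, ...) {
  cat("SAR error model (ML), n =", x$n, "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  lambda = %.4f, logLik = %.2f, AIC = %.2f\n",
              x$lambda, x$loglik, x$aic))
  invisible(x)
}

#' @export
summary.sar_error <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(object = object, coefficients = tab),
            class = "summary.sar_error")
}

#' @export
print.summary.sar_error <- function(x, ...) {
  cat("SAR error model (maximum likelihood)\n\n")
  stats::printCoefmat(x$coefficients)
  o <- x$object
  cat(sprintf("\nlambda = %.4f (SE %.4f), sigma2 = %.4f\n",
              o$lambda, o$lambda_se, o$sigma2))
  cat(sprintf("logLik = %.3f, AIC = %.3f, n = %d\n", o$loglik, o$aic, o$n))
  invisible(x)
}

#' @export
coef.sar_error <- function(object, ...) object$coefficients

#' @export
residuals.sar_error <- function(object, ...) object$residuals

#' @export
fitted.sar_error <- function(object, ...) object$fitted.values

#' @export
logLik.sar_error <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 2,
            nobs = object$n, class = "logLik")
}

#' @export
predict.sar_error <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  X <- stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                           newdata)
  drop(X %*% object$coefficients)
}

#' Adaptation slopes for Topt and Tinf by OLS and SAR
#'
#' Convenience driver: for each metric fits the OLS and SAR-error regressions
#' against MET and stacks the slope records into the adaptation results
#' table.
#'
#' @param fit_table Converged rows of a [fit_cohort()] table joined with site
#'   metadata (needs `topt_c`, `tinf_c`, `met`).
#' @param weights [build_weights()] built on the same (converged) site rows.
#' @param metrics Metric columns to analyse.
#' @return Data frame with columns `metric`, `model`, `beta0`, `beta_met`,
#'   `se_beta`, `lambda`, `loglik`, `aic`, `n`.
#' @export
adaptation_slopes <- function(fit_table, weights,
                              metrics = c("topt_c", "tinf_c")) {
  rows <- list()
  for (m in metrics) {
    fml <- stats::as.formula(paste(m, "~ met"))
    o <- fit_ols(fml, fit_table)
    s <- sar_error(fml, fit_table, weights)
    rows[[length(rows) + 1]] <- cbind(metric = m, o)
    rows[[length(rows) + 1]] <- data.frame(
      metric = m, model = "sar_error", beta0 = unname(coef(s)[1]),
      beta_met = unname(coef(s)[2]), se_beta = unname(s$se[2]),
      lambda = s$lambda, loglik = s$loglik, aic = s$aic, n = s$n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare MET and pH as predictors of a thermal metric
#'
#' Fits the three OLS models {MET}, {pH}, {MET + pH} and ranks them by AIC.
#' A near-perfect MET-pH correlation flags the joint model as collinear.
#'
#' @param fit_table Fit table with `met` and `ph` columns and the metric.
#' @param metric Metric column name, e.g. `"topt_c"`.
#' @return Data frame ranked by AIC with `model`, `aic`, `delta_aic`, `rank`
#'   and a `collinear` attribute.
#' @export
compare_predictors <- function(fit_table, metric = "topt_c") {
  if (!"ph" %in% names(fit_table) || all(is.na(fit_table$ph))) {
    warning("pH unavailable; returning MET-only model", call. = FALSE)
    o <- fit_ols(stats::as.formula(paste(metric, "~ met")), fit_table)
    return(data.frame(model = "met", aic = o$aic, delta_aic = 0, rank = 1L))
  }
  r <- stats::cor(fit_table$met, fit_table$ph)
  collinear <- abs(r) > 0.999
  models <- c(met = paste(metric, "~ met"),
              ph = paste(metric, "~ ph"),
              `met+ph` = paste(metric, "~ met + ph"))
  aics <- vapply(models, function(f) {
    if (collinear && f == models[["met+ph"]]) return(NA_real_)
    stats::AIC(stats::lm(stats::as.formula(f), data = fit_table))
  }, numeric(1))
  out <- data.frame(model = names(models), aic = aics)
  out <- out[order(out$aic), ]
  out$delta_aic <- out$aic - min(out$aic, na.rm = TRUE)
  out$rank <- rank(out$aic, na.last = "keep")
  rownames(out) <- NULL
  attr(out, "collinear") <- collinear
  attr(out, "cor_met_ph") <- r
  if (collinear) warning("met and ph are (near-)perfectly collinear; ",
                         "joint model skipped", call. = FALSE)
  out
}

#' Methodological QC checks on the fitted metrics
#'
#' Two labelled quality-control analyses (not headline inference): (1) the
#' MET regression slope compared with the slope using the 30-day pre-sampling
#' temperature `t30`, with a z-test on the slope difference; (2) two-sample
#' t-tests of Topt and Tinf between the two incubation temperature blocks.
#' Checks with absent metadata are skipped with a notice.
#'
#' @param fit_table Fit table with the metrics and optional `t30`,
#'   `block_id` columns.
#' @param alpha QC significance level, default 0.05.
#' @return A list of class `qc_report` with elements `t30` and `blocks`
#'   (NULL when skipped).
#' @export
qc_checks <- function(fit_table, alpha = 0.05) {
  out <- list(t30 = NULL, blocks = NULL, alpha = alpha)
  if ("t30" %in% names(fit_table) && !all(is.na(fit_table$t30))) {
    rows <- list()
    for (m in intersect(c("topt_c", "tinf_c"), names(fit_table))) {
      a <- fit_ols(stats::as.formula(paste(m, "~ met")), fit_table)
      b <- fit_ols(stats::as.formula(paste(m, "~ t30")), fit_table)
      z <- (a$beta_met - b$beta_met) / sqrt(a$se_beta^2 + b$se_beta^2)
      rows[[m]] <- data.frame(metric = m, slope_met = a$beta_met,
                              slope_t30 = b$beta_met,
                              diff = a$beta_met - b$beta_met,
                              p = 2 * stats::pnorm(-abs(z)),
                              flag = 2 * stats::pnorm(-abs(z)) < alpha)
    }
    out$t30 <- do.call(rbind, rows)
    rownames(out$t30) <- NULL
  } else {
    message("QC: t30 not available; 30-day-temperature check skipped")
  }
  if ("block_id" %in% names(fit_table) &&
      length(unique(stats::na.omit(fit_table$block_id))) == 2) {
    rows <- list()
    for (m in intersect(c("topt_c", "tinf_c"), names(fit_table))) {
      tt <- stats::t.test(stats::as.formula(paste(m, "~ block_id")),
                          data = fit_table)
      rows[[m]] <- data.frame(metric = m, t = unname(tt$statistic),
                              p = tt$p.value, flag = tt$p.value < alpha)
    }
    out$blocks <- do.call(rbind, rows)
    rownames(out$blocks) <- NULL
  } else {
    message("QC: block_id not available (or not two blocks); ",
            "block check skipped")
  }
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (alpha =", x$alpha, ") - quality control, not inference\n")
  if (!is.null(x$t30)) { cat("MET vs 30-day temperature slopes:\n"); print(x$t30) }
  if (!is.null(x$blocks)) { cat("Temperature-block t-tests:\n"); print(x$blocks) }
  invisible(x)
}
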