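# Non-linear least squares MMRT fitting, AICc selection, cohort fitting.

noiseless_curve <- function(p, temps = seq(4, 40, 2)) {
  data.frame(temperature_c = temps,
             gir = mmrt_rate(celsius_to_kelvin(temps), p))
}

test_that("AICc: hand value, penalty monotonicity, vanishing correction", {
  expect_equal(aicc(rss = 20, n = 20, k = 5), 14.285714285714286)
  expect_lt(aicc(10, 20, 4), aicc(10, 20, 5))
  # correction term vanishes as n grows with rss/n and k fixed
  aic_part <- function(n, k) n * log(1) + 2 * k
  expect_lt(aicc(1e6, 1e6, 5) - aic_part(1e6, 5), 1e-4)
  expect_gt(aicc(20, 20, 5) - aic_part(20, 5), 4)
  expect_error(aicc(10, 6, 5), "undefined")
})

test_that("noiseless curves recover the generating parameters", {
  p <- solve_mmrt_params(35, 24, A = -5, amplitude = 8)
  f <- mmrt_fit(gir ~ temperature_c, noiseless_curve(p))
  expect_true(f$converged)
  cf <- coef(f)
  expect_equal(cf[["dH"]], p$dH, tolerance = 0.01)
  expect_equal(cf[["dS"]], p$dS, tolerance = 0.01)
  expect_equal(cf[["B"]], p$B, tolerance = 0.01)
  expect_equal(cf[["A"]], p$A, tolerance = 0.1)   # weakly identified
  expect_lt(f$rss, 1e-10)
})

test_that("fit is invariant to duplicating every observation", {
  p <- solve_mmrt_params(33, 22, amplitude = 5)
  set.seed(5)
  d <- noiseless_curve(p)
  d$gir <- d$gir * exp(rnorm(nrow(d), 0, 0.05))
  f1 <- mmrt_fit(gir ~ temperature_c, d)
  f2 <- mmrt_fit(gir ~ temperature_c, rbind(d, d))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
  expect_equal(f2$rss, 2 * f1$rss, tolerance = 1e-5)
})

test_that("refitting data generated from a fit reproduces the same optimum", {
  p <- solve_mmrt_params(36, 25)
  set.seed(6)
  d <- noiseless_curve(p)
  d$gir <- d$gir * exp(rnorm(nrow(d), 0, 0.05))
  f1 <- mmrt_fit(gir ~ temperature_c, d)
  d2 <- data.frame(temperature_c = d$temperature_c, gir = fitted(f1))
  f2 <- mmrt_fit(gir ~ temperature_c, d2)
  expect_within(f2$summary$topt_c, f1$summary$topt_c, 0.011)
  expect_equal(coef(f2)[c("dH", "dS", "B")], coef(f1)[c("dH", "dS", "B")],
               tolerance = 1e-3)
})

test_that("variant selection: tie rule, equivalence band, caveats", {
  f <- list(variant = "varying_cp", converged = TRUE, aicc = -50)
  g <- list(variant = "constant_cp", converged = TRUE, aicc = -50)
  class(f) <- class(g) <- "mmrt_fit"
  sel <- select_variant(f, g)
  expect_identical(sel$chosen, "varying_cp")
  expect_true(sel$equivalent)

  g$aicc <- -60  # constant clearly better
  expect_identical(select_variant(f, g)$chosen, "constant_cp")
  g$aicc <- -51.5  # within the 2-unit band -> varying
  expect_identical(select_variant(f, g)$chosen, "varying_cp")

  g$converged <- FALSE
  sel <- select_variant(f, g)
  expect_identical(sel$chosen, "varying_cp")
  expect_match(sel$caveat, "only the varying_cp")
})

test_that("a strongly temperature-dependent heat capacity is detected by AICc", {
  set.seed(7)
  prefer <- vapply(1:30, function(i) {
    topt <- runif(1, 32, 38)
    p <- solve_mmrt_params(topt, topt - runif(1, 10, 12), A = -20,
                           amplitude = 8)
    d <- noiseless_curve(p, temps = seq(4, 40, 1))
    d$gir <- d$gir * exp(rnorm(nrow(d), 0, 0.02))
    fv <- mmrt_fit(gir ~ temperature_c, d)
    fc <- mmrt_fit(gir ~ temperature_c, d, variant = "constant_cp")
    select_variant(fv, fc)$chosen == "varying_cp"
  }, logical(1))
  expect_gt(mean(prefer), 0.5)
})

test_that("parameter recovery under realistic noise: optima within field tolerance", {
  set.seed(8)
  errs <- t(vapply(1:200, function(i) {
    topt <- runif(1, 31, 41)
    tinf <- topt - runif(1, 9, 12)
    p <- solve_mmrt_params(topt, tinf, A = -5, amplitude = 8)
    d <- noiseless_curve(p, temps = seq(4, 40, 2))
    d$gir <- d$gir * exp(rnorm(nrow(d), 0, 0.05))  # CV 5 %
    f <- mmrt_fit(gir ~ temperature_c, d)
    if (!f$converged) return(c(NA_real_, NA_real_))
    c(abs(f$summary$topt_c - topt), abs(f$summary$tinf_c - tinf))
  }, numeric(2)))
  expect_gt(mean(!is.na(errs[, 1])), 0.99)
  expect_lte(median(errs[, 1], na.rm = TRUE), 0.5)
  expect_lte(median(errs[, 2], na.rm = TRUE), 1.0)
})

test_that("fits refuse impossible inputs and report failure states", {
  p <- solve_mmrt_params(35, 24)
  d <- noiseless_curve(p)[1:5, ]
  expect_error(mmrt_fit(gir ~ temperature_c, d), "refused")
  d2 <- noiseless_curve(p)
  d2$gir[3] <- -1
  expect_error(mmrt_fit(gir ~ temperature_c, d2), "positive")
})

test_that("cohort fitting joins sites, refuses sparse curves, survives empty input", {
  empty <- data.frame(soil_id = character(0), temperature_c = numeric(0),
                      gir = numeric(0))
  out <- fit_cohort(empty)
  expect_identical(nrow(out), 0L)

  p1 <- solve_mmrt_params(33, 22, amplitude = 4)
  p2 <- solve_mmrt_params(37, 26, amplitude = 9)
  curves <- rbind(cbind(soil_id = "a", noiseless_curve(p1)),
                  cbind(soil_id = "b", noiseless_curve(p2)),
                  cbind(soil_id = "sparse", noiseless_curve(p1)[1:8, ]))
  names(curves)[3] <- "gir"
  sites <- data.frame(soil_id = c("a", "b"), met = c(12, 30),
                      lat = c(-40, -38), lon = c(170, 176))
  expect_message(tab <- fit_cohort(curves, sites), "refused")
  expect_identical(tab$converged, c(TRUE, TRUE, FALSE))
  expect_lt(max(abs(tab$topt_c[1:2] - c(33, 37))), 0.012)
  expect_equal(tab$met[1:2], c(12, 30))
  expect_true(is.na(tab$topt_c[3]))
  # unmatched site ids are reported
  expect_identical(attr(tab, "unmatched"), "sparse")
})

test_that("mmrt_fit methods: predict, residuals, logLik, simulate are coherent", {
  p <- solve_mmrt_params(34, 23, amplitude = 6)
  set.seed(9)
  d <- noiseless_curve(p)
  d$gir <- d$gir * exp(rnorm(nrow(d), 0, 0.05))
  f <- mmrt_fit(gir ~ temperature_c, d)
  expect_equal(residuals(f), log(d$gir) - log(fitted(f)), tolerance = 1e-10)
  expect_equal(sum(residuals(f)^2), f$rss)
  expect_equal(unname(predict(f, data.frame(temperature_c = 20), type = "log")),
               mmrt_log_rate(celsius_to_kelvin(20), f$params))
  expect_s3_class(logLik(f), "logLik")
  expect_identical(attr(logLik(f), "df"), f$k)
  sim <- simulate(f, nsim = 3, seed = 1)
  expect_identical(dim(sim), c(nrow(d), 3L))
  expect_true(all(sim > 0))
})
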