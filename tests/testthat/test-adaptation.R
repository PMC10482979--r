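# Spatial weights, Moran's I, and the adaptation regressions (OLS + SAR).

test_that("knn weights: equidistant symmetry and brute-force adjacency", {
  # three (nearly) equidistant sites, k = 2: every weight is 1/2
  tri <- data.frame(soil_id = c("a", "b", "c"),
                    lat = c(-40, -40, -40 + 0.01 * sqrt(3) / 2),
                    lon = c(172, 172.01, 172.005))
  w <- build_weights(tri, k = 2)
  expect_equal(sort(unique(as.vector(w$W))), c(0, 0.5))
  expect_equal(rowSums(w$W), rep(1, 3))

  # mixed dense-transect + scattered layout: knn adjacency re-derived from
  # the brute-force distance matrix
  set.seed(3)
  sites <- rbind(
    data.frame(soil_id = sprintf("t%d", 1:6), lat = -38 + (1:6) * 1e-5,
               lon = 176),
    data.frame(soil_id = sprintf("n%d", 1:6), lat = runif(6, -45, -36),
               lon = runif(6, 168, 178)))
  w <- build_weights(sites, k = 3)
  D <- geosphere::distm(as.matrix(sites[, c("lon", "lat")]))
  adj <- matrix(FALSE, 12, 12)
  for (i in 1:12) adj[i, order(D[i, ])[2:4]] <- TRUE
  adj <- adj | t(adj)
  expect_identical(w$W > 0, adj)
  # transect sites neighbour transect sites
  expect_true(all(which(w$W[1, ] > 0) <= 6))
})

test_that("distance-band weights form a chain on a regular transect", {
  tr <- data.frame(soil_id = paste0("s", 1:5),
                   lat = -38 + (0:4) * 1 / 111319.4908, lon = 176)
  w <- build_weights(tr, method = "distance_band", radius = 1.5)
  nb <- lapply(seq_len(5), function(i) which(w$W[i, ] > 0))
  expect_identical(nb, list(2L, c(1L, 3L), c(2L, 4L), c(3L, 5L), 4L))
  expect_error(build_weights(tr[c(1, 1), ], k = 1), "coincide")
})

test_that("Moran's I: null mean, checkerboard brute force, ape cross-check", {
  lat <- lattice_sites(4, 4)
  w <- build_weights(lat, method = "distance_band", radius = 1200)  # rook
  checker <- rep(c(1, 0, 1, 0, 0, 1, 0, 1), 2)
  m <- morans_i(checker, w, nperm = 199, seed = 1, alternative = "less")
  expect_equal(m$expected, -1 / 15)

  # brute-force double sum of the definition
  z <- checker - mean(checker)
  W <- w$W
  num <- 0
  for (i in 1:16) for (j in 1:16) num <- num + W[i, j] * z[i] * z[j]
  I_brute <- 16 / sum(W) * num / sum(z^2)
  expect_equal(m$I, I_brute, tolerance = 1e-12)
  expect_lt(m$I, -0.5)          # strong negative autocorrelation
  expect_lt(m$p_perm, 0.05)

  # independent implementation: ape's normal-approximation machinery
  ap <- ape::Moran.I(checker, W, alternative = "less")
  expect_equal(m$I, ap$observed, tolerance = 1e-12)
  expect_equal(m$p_normal, ap$p.value)

  # smooth gradient over a transect: positive I, small permutation p
  tr <- data.frame(soil_id = paste0("s", 1:15),
                   lat = -38 + (1:15) * 1e-5, lon = 176)
  wt <- build_weights(tr, k = 2)
  g <- morans_i(seq(5, 35, length.out = 15), wt, nperm = 999, seed = 2)
  expect_gt(g$I, 0.5)
  expect_lt(g$p_perm, 0.01)

  expect_error(morans_i(rep(1, 15), wt), "variance")
})

test_that("OLS: exact line, collinearity guard, calibrated uncertainty", {
  d <- data.frame(met = seq(5, 35, length.out = 20))
  d$topt_c <- 0.3 * d$met + 25
  o <- suppressWarnings(fit_ols(topt_c ~ met, d))  # perfect-fit warning
  expect_equal(o$beta_met, 0.3, tolerance = 1e-12)
  expect_lt(o$se_beta, 1e-12)

  d$met2 <- d$met
  expect_error(fit_ols(topt_c ~ met + met2, d), "collinear")

  # slope CI calibration: ~95 % of replicates cover the true slope
  set.seed(123)
  cover <- vapply(1:200, function(i) {
    dd <- data.frame(met = runif(47, 11, 35))
    dd$y <- 25 + 0.29 * dd$met + rnorm(47, 0, 1.8)
    o <- fit_ols(y ~ met, dd)
    abs(o$beta_met - 0.29) <= 2 * o$se_beta
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("SAR with lambda = 0 equals OLS to numerical identity", {
  set.seed(14)
  sites <- lattice_sites()
  sites$met <- runif(36, 11, 35)
  sites$topt_c <- 30 + 0.29 * sites$met + rnorm(36, 0, 1.5)
  w <- build_weights(sites, k = 4)
  s0 <- sar_error(topt_c ~ met, sites, w, lambda = 0)
  o <- lm(topt_c ~ met, sites)
  expect_lt(max(abs(coef(s0) - coef(o))), 1e-8)
  expect_equal(unname(fitted(s0)), unname(fitted(o)), tolerance = 1e-8)

  # iid data: the estimated lambda stays small and slopes agree closely
  s <- sar_error(topt_c ~ met, sites, w)
  expect_lt(abs(coef(s)[["met"]] - coef(o)[["met"]]), 0.05)
})

test_that("SAR coefficients match a brute-force GLS oracle at fixed lambda", {
  set.seed(15)
  sites <- lattice_sites()
  sites$met <- runif(36, 11, 35)
  sites$y <- 28 + 0.3 * sites$met + rnorm(36)
  w <- build_weights(sites, k = 4)
  lam <- 0.4
  s <- sar_error(y ~ met, sites, w, lambda = lam)
  A <- diag(36) - lam * w$W
  Sigma_inv <- t(A) %*% A
  X <- cbind(1, sites$met)
  beta_gls <- solve(t(X) %*% Sigma_inv %*% X, t(X) %*% Sigma_inv %*% sites$y)
  expect_equal(unname(coef(s)), drop(beta_gls), tolerance = 1e-10)
})

test_that("SAR recovers a known spatial error process", {
  sites <- lattice_sites()
  w <- build_weights(sites, k = 4)
  n <- 36
  Ainv <- solve(diag(n) - 0.6 * w$W)
  set.seed(16)
  est <- t(vapply(1:60, function(i) {
    met <- runif(n, 11, 35)
    u <- drop(Ainv %*% rnorm(n, 0, 1.2))
    d <- data.frame(met = met, y = 30 + 0.3 * met + u)
    s <- sar_error(y ~ met, d, w)
    c(lambda = s$lambda, beta = unname(coef(s)[2]))
  }, numeric(2)))
  expect_within(mean(est[, "beta"]), 0.3, 0.05)
  expect_gt(mean(est[, "lambda"]), 0.35)
  expect_lt(mean(est[, "lambda"]), 0.8)
})

test_that("slope is equivariant under a constant MET shift", {
  set.seed(17)
  sites <- lattice_sites()
  sites$met <- runif(36, 11, 35)
  sites$y <- 30 + 0.29 * sites$met + rnorm(36, 0, 1)
  w <- build_weights(sites, k = 4)
  s1 <- sar_error(y ~ met, sites, w)
  sites2 <- sites
  sites2$met <- sites$met + 10
  s2 <- sar_error(y ~ met, sites2, w)
  expect_equal(coef(s2)[["met"]], coef(s1)[["met"]], tolerance = 1e-6)
  expect_equal(coef(s2)[["(Intercept)"]],
               coef(s1)[["(Intercept)"]] - 10 * coef(s1)[["met"]],
               tolerance = 1e-5)
})

test_that("predictor comparison prefers the true driver and flags collinearity", {
  set.seed(18)
  d <- data.frame(met = runif(40, 11, 35))
  d$ph <- rnorm(40, 6, 0.5)                  # pure noise
  d$topt_c <- 30 + 0.3 * d$met + rnorm(40, 0, 1)
  cmp <- compare_predictors(d, "topt_c")
  expect_identical(cmp$model[1], "met")

  d$ph <- 10 - 0.2 * d$met                   # r = -1 exactly
  expect_warning(cmp2 <- compare_predictors(d, "topt_c"), "collinear")
  expect_true(attr(cmp2, "collinear"))
  expect_true(is.na(cmp2$aic[cmp2$model == "met+ph"]))

  d$ph <- NULL
  expect_warning(cmp3 <- compare_predictors(d, "topt_c"), "unavailable")
  expect_identical(cmp3$model, "met")
})

test_that("QC checks: identical predictors, block type-I rate, block power", {
  set.seed(19)
  d <- data.frame(met = runif(40, 11, 35), block_id = rep(c("A", "B"), 20))
  d$topt_c <- 30 + 0.29 * d$met + rnorm(40, 0, 1.5)
  d$tinf_c <- d$topt_c - 10.5
  d$t30 <- d$met
  qc <- qc_checks(d)
  expect_equal(qc$t30$diff, c(0, 0), tolerance = 1e-12)

  # random blocks: the block t-test rejects at ~alpha
  set.seed(20)
  rej <- vapply(1:200, function(i) {
    dd <- d
    dd$block_id <- sample(dd$block_id)
    suppressMessages(qc_checks(dd))$blocks$flag[1]
  }, logical(1))
  expect_lt(mean(rej), 0.12)
  expect_gt(mean(rej), 0.005)

  # a +2 C block offset on Topt is detectable at n = 40 (soils assigned to
  # blocks at random, so the block contrast is free of the MET trend)
  set.seed(21)
  hit <- vapply(1:50, function(i) {
    dd <- data.frame(block_id = rep(c("A", "B"), 20))
    dd$topt_c <- 33 + rnorm(40, 0, 1.5) + ifelse(dd$block_id == "A", 2, 0)
    dd$tinf_c <- dd$topt_c - 10.5
    suppressMessages(qc_checks(dd))$blocks$flag[1]
  }, logical(1))
  expect_gt(mean(hit), 0.9)
})
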