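# The thermodynamic core: heat-capacity model, log-rate, derivatives and
# curve summaries.

test_that("heat-capacity model: reference identity, constant variant, hand arithmetic", {
  p <- mmrt_params(dH = 5e4, dS = -50, A = -3, B = -1500)
  expect_equal(mmrt_delta_cp(p$T0, p), -1500)              # B at T0, any A
  p0 <- mmrt_params(dH = 5e4, dS = -50, A = 0, B = -1500)
  expect_equal(mmrt_delta_cp(c(250, 300, 350), p0), rep(-1500, 3))
  ph <- mmrt_params(dH = 0, dS = 0, A = -10, B = -1000)
  expect_equal(mmrt_delta_cp(305, ph), -10 * 5 - 1000)     # linear form by hand
  expect_error(mmrt_delta_cp(NaN, p), "finite")
  expect_error(mmrt_params(dH = Inf, dS = 0, A = 0, B = -1), "finite")
})

test_that("log rate matches independent term-by-term evaluation and limiting cases", {
  # dH = dS = 0 at T0: both heat-capacity factors vanish, only the
  # pre-exponential term survives
  p <- mmrt_params(dH = 0, dS = 0, A = -7, B = -3000, T0 = 300)
  expect_equal(mmrt_log_rate(300, p), 29.46376028516042, tolerance = 1e-12)

  # value frozen from an independent high-precision symbolic evaluation
  p2 <- mmrt_params(dH = 5e4, dS = -50, A = 0, B = -2000, T0 = 300)
  expect_equal(mmrt_log_rate(310, p2), 3.956253765241606, tolerance = 1e-12)

  # A = 0 degenerates to the constant-heat-capacity model, written out
  # independently here
  const_cp_lnr <- function(tk, dH, dS, B, T0) {
    kB <- 1.380649e-23; h <- 6.62607015e-34; R <- 8.314462618
    log(kB * tk / h) - dH / (R * tk) - B * (tk - T0) / (R * tk) + dS / R +
      B * (log(tk) - log(T0)) / R
  }
  tk <- seq(270, 330, by = 0.5)
  expect_equal(mmrt_log_rate(tk, p2), const_cp_lnr(tk, 5e4, -50, -2000, 300),
               tolerance = 1e-14)
  expect_error(mmrt_log_rate(-5, p2), "positive")
})

test_that("rate is positive, unimodal on sensible parameters, and guards overflow", {
  p <- solve_mmrt_params(35, 24)
  tk <- celsius_to_kelvin(seq(0, 50, by = 0.01))
  r <- mmrt_rate(tk, p)
  expect_true(all(r > 0))
  expect_equal(r, exp(mmrt_log_rate(tk, p)))
  expect_identical(sum(diff(sign(diff(r))) < 0), 1L)  # exactly one peak
  bad <- mmrt_params(dH = -1e7, dS = 1e5, A = 0, B = 0)
  expect_error(mmrt_rate(310, bad), "overflow")
})

test_that("analytic rate derivative agrees with central differences", {
  h <- 1e-3
  for (p in random_mmrt_params(25, seed = 11)) {
    tk <- celsius_to_kelvin(c(10, 20, 28, 36))
    num <- (mmrt_rate(tk + h, p) - mmrt_rate(tk - h, p)) / (2 * h)
    expect_equal(mmrt_rate_deriv(tk, p), num, tolerance = 1e-6)
  }
})

test_that("derivative is zero at Topt and maximal at Tinf", {
  p <- solve_mmrt_params(33, 23)
  s <- summarize_curve(p, grid_spacing = 0.005)
  d_opt <- mmrt_rate_deriv(celsius_to_kelvin(s$topt_c), p)
  scale <- max(abs(mmrt_rate_deriv(celsius_to_kelvin(seq(4, 42, 0.5)), p)))
  expect_lt(abs(d_opt) / scale, 1e-2)
  # the derivative peaks at Tinf: no higher value nearby
  near <- seq(s$tinf_c - 2, s$tinf_c + 2, by = 0.05)
  expect_within(near[which.max(mmrt_rate_deriv(celsius_to_kelvin(near), p))],
                s$tinf_c, 0.06)
})

test_that("curve summary matches the closed-form optimum for constant heat capacity", {
  # for A = 0 the log-rate derivative root is (B T0 - dH)/(R + B)
  p <- mmrt_params(dH = 5e4, dS = -50, A = 0, B = -2000, T0 = 300)
  s <- summarize_curve(p, eval_range = c(4, 70), grid_spacing = 0.01)
  expect_within(s$topt_c, 53.20674045934076, 0.011)

  R <- mmrt_constants()$R
  for (p in random_mmrt_params(100, seed = 21, A_range = c(0, 0))) {
    closed <- (p$B * p$T0 - p$dH) / (R + p$B) - 273.15
    s <- summarize_curve(p, eval_range = c(0, 60), grid_spacing = 0.02)
    expect_within(s$topt_c, closed, 0.021)
  }
})

test_that("summary argmax agrees with a root-finder on the analytic derivative", {
  for (p in random_mmrt_params(40, seed = 31)) {
    s <- summarize_curve(p, eval_range = c(0, 55), grid_spacing = 0.02)
    root <- uniroot(function(tc) mmrt_dlog_rate_dT(celsius_to_kelvin(tc), p),
                    c(s$topt_c - 1, s$topt_c + 1))$root
    expect_within(s$topt_c, root, 0.021)
  }
})

test_that("Tinf sits below Topt and grid refinement is consistent", {
  for (p in random_mmrt_params(30, seed = 41)) {
    s1 <- summarize_curve(p, eval_range = c(0, 55), grid_spacing = 0.04)
    s2 <- summarize_curve(p, eval_range = c(0, 55), grid_spacing = 0.02)
    expect_lt(s1$tinf_c, s1$topt_c)
    expect_lt(abs(s1$topt_c - s2$topt_c), 0.04 + 1e-9)
    expect_lt(abs(s1$tinf_c - s2$tinf_c), 0.04 + 1e-9)
  }
})

test_that("summaries flag boundary censoring and reject coarse grids", {
  p <- solve_mmrt_params(35, 24)
  s <- summarize_curve(p, eval_range = c(4, 30))  # optimum beyond the range
  expect_true(s$boundary_censored)
  expect_false(summarize_curve(p)$boundary_censored)
  expect_error(summarize_curve(p, grid_spacing = 0.1), "grid_spacing")
})

test_that("temperature conversion round-trips and is the single pathway", {
  tc <- c(-10, 0, 4, 25, 42.42)
  expect_equal(kelvin_to_celsius(celsius_to_kelvin(tc)), tc)
  expect_equal(celsius_to_kelvin(0), 273.15)
})

test_that("prescribed-optimum construction hits its targets", {
  for (tt in list(c(32.9, 22.4), c(40, 28), c(31, 24.5))) {
    p <- solve_mmrt_params(tt[1], tt[2], A = -5, amplitude = 3)
    s <- summarize_curve(p, eval_range = c(0, 55), grid_spacing = 0.01)
    expect_within(s$topt_c, tt[1], 0.011)
    expect_within(s$tinf_c, tt[2], 0.011)
    r <- mmrt_rate(celsius_to_kelvin(seq(0, 55, 0.01)), p)
    expect_equal(max(r), 3, tolerance = 1e-3)  # amplitude lands at the peak
  }
})
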