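# Macromolecular rate theory (MMRT) with a temperature-dependent activation
# heat capacity: the thermodynamic model underlying every temperature response
# curve in this package.

#' Physical constants used by the MMRT model
#'
#' CODATA values of Boltzmann's constant, Planck's constant and the universal
#' gas constant. Returned as a locked list; all model functions take these as
#' an argument so the constants appear in exactly one place.
#'
#' @return A list with elements `kB` (J K^-1), `h` (J s) and `R`
#'   (J mol^-1 K^-1).
#' @export
#' @examples
#' mmrt_constants()$R
mmrt_constants <- function() {
  list(kB = 1.380649e-23, h = 6.62607015e-34, R = 8.314462618)
}

#' Celsius/Kelvin conversion helpers
#'
#' All user-facing temperatures in this package are degrees Celsius; model
#' internals work in Kelvin. These two helpers are the only conversion
#' pathway (offset 273.15).
#'
#' @param temp_c,temp_k Temperatures in degrees Celsius / Kelvin.
#' @return Numeric vector of converted temperatures.
#' @export
celsius_to_kelvin <- function(temp_c) {
  stopifnot(is.numeric(temp_c))
  temp_c + 273.15
}

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(temp_k) {
  stopifnot(is.numeric(temp_k))
  temp_k - 273.15
}

#' MMRT parameter set
#'
#' Bundles the thermodynamic parameters of the modified MMRT model: the
#' activation enthalpy and entropy at the reference temperature, and a linear
#' model for the activation heat capacity, dCp(T) = A (T - T0) + B. Setting
#' `A = 0` recovers the constant-heat-capacity MMRT variant exactly.
#'
#' @param dH Activation enthalpy at `T0` (J mol^-1).
#' @param dS Activation entropy at `T0` (J mol^-1 K^-1).
#' @param A Slope of the activation heat capacity with temperature
#'   (J mol^-1 K^-2).
#' @param B Activation heat capacity at `T0` (J mol^-1 K^-1).
#' @param T0 Reference temperature (K), default 300.
#' @return An object of class `mmrt_params`.
#' @export
#' @examples
#' p <- mmrt_params(dH = 5e4, dS = -50, A = 0, B = -2000)
#' mmrt_delta_cp(300, p)   # == B at the reference temperature
mmrt_params <- function(dH, dS, A = 0, B, T0 = 300) {
  vals <- c(dH = dH, dS = dS, A = A, B = B, T0 = T0)
  if (!all(is.finite(vals))) {
    stop("all MMRT parameters must be finite", call. = FALSE)
  }
  if (T0 <= 0) stop("reference temperature T0 must be positive", call. = FALSE)
  structure(as.list(vals), class = "mmrt_params")
}

#' @export
print.mmrt_params <- function(x, ...) {
  cat("MMRT parameters (T0 =", format(x$T0), "K)\n")
  cat(sprintf("  dH  %12.1f J/mol\n", x$dH))
  cat(sprintf("  dS  %12.3f J/mol/K\n", x$dS))
  cat(sprintf("  A   %12.3f J/mol/K^2\n", x$A))
  cat(sprintf("  B   %12.1f J/mol/K\n", x$B))
  invisible(x)
}

check_temp_k <- function(temp_k) {
  if (!is.numeric(temp_k) || !all(is.finite(temp_k))) {
    stop("temperature must be finite and numeric", call. = FALSE)
  }
  if (any(temp_k <= 0)) {
    stop("absolute temperature must be positive (K)", call. = FALSE)
  }
  invisible(temp_k)
}

#' Activation heat capacity at a given temperature
#'
#' Evaluates the linear heat-capacity model dCp(T) = A (T - T0) + B.
#'
#' @param temp_k Absolute temperature (K).
#' @param params An [mmrt_params()] object.
#' @return Activation heat capacity (J mol^-1 K^-1).
#' @export
mmrt_delta_cp <- function(temp_k, params) {
  check_temp_k(temp_k)
  params$A * (temp_k - params$T0) + params$B
}

#' Natural-log respiration rate under modified MMRT
#'
#' The model for ln(Rs):
#' ln(kB T / h) - dH/(R T) - dCp(T) (T - T0)/(R T) + dS/R
#' + dCp(T) (ln T - ln T0)/R, with dCp(T) substituted pointwise from the
#' linear heat-capacity model. Continuous and twice differentiable for T > 0.
#'
#' @inheritParams mmrt_delta_cp
#' @param consts Physical constants, see [mmrt_constants()].
#' @return ln rate (log of rate units).
#' @export
mmrt_log_rate <- function(temp_k, params, consts = mmrt_constants()) {
  check_temp_k(temp_k)
  T0 <- params$T0
  R <- consts$R
  dcp <- params$A * (temp_k - T0) + params$B
  log(consts$kB * temp_k / consts$h) -
    params$dH / (R * temp_k) -
    dcp * (temp_k - T0) / (R * temp_k) +
    params$dS / R +
    dcp * (log(temp_k) - log(T0)) / R
}

#' Respiration rate under modified MMRT
#'
#' Exponential of [mmrt_log_rate()]; strictly positive. Overflow to infinity
#' (pathological parameters) is raised as an error rather than returned
#' silently.
#'
#' @inheritParams mmrt_log_rate
#' @return Respiration rate (rate units).
#' @export
mmrt_rate <- function(temp_k, params, consts = mmrt_constants()) {
  out <- exp(mmrt_log_rate(temp_k, params, consts))
  if (any(!is.finite(out))) {
    stop("MMRT rate overflowed for the given parameters (non-finite value)",
         call. = FALSE)
  }
  out
}

# d/dT of mmrt_log_rate, analytic. The rate derivative is rate * this.
mmrt_dlog_rate_dT <- function(temp_k, params, consts = mmrt_constants()) {
  check_temp_k(temp_k)
  T0 <- params$T0
  R <- consts$R
  A <- params$A
  B <- params$B
  dcp <- A * (temp_k - T0) + B
  # f = dcp*(T-T0)/T ; f' = [ (2A(T-T0)+B)*T - A(T-T0)^2 - B(T-T0) ] / T^2
  fprime <- ((2 * A * (temp_k - T0) + B) * temp_k -
               A * (temp_k - T0)^2 - B * (temp_k - T0)) / temp_k^2
  1 / temp_k +
    params$dH / (R * temp_k^2) -
    fprime / R +
    (A * (log(temp_k) - log(T0)) + dcp / temp_k) / R
}

#' First derivative of the MMRT respiration rate
#'
#' d(rate)/dT in rate units per K, computed analytically as
#' rate(T) * d(ln rate)/dT. The peak of this derivative is the inflection
#' temperature Tinf; its zero crossing at the curve peak is Topt.
#'
#' @inheritParams mmrt_log_rate
#' @return Derivative of the rate with respect to temperature.
#' @export
mmrt_rate_deriv <- function(temp_k, params, consts = mmrt_constants()) {
  mmrt_rate(temp_k, params, consts) * mmrt_dlog_rate_dT(temp_k, params, consts)
}

#' Summarise an MMRT curve: temperature optimum and inflection point
#'
#' Evaluates the fitted curve on a regular temperature grid and reports the
#' temperature of the largest predicted rate (Topt) and of the largest rise
#' between successive grid values, i.e. the peak of the first derivative
#' (Tinf). Tinf is defined on the rate (not log-rate) derivative. If either
#' argmax falls on a grid endpoint the summary is flagged boundary-censored;
#' more than one interior rate peak is flagged multimodal (the largest peak
#' is reported).
#'
#' @param params An [mmrt_params()] object.
#' @param eval_range Numeric length-2, evaluation bounds in degrees Celsius.
#'   Default 4-42 C, the support over which curves are fitted.
#' @param grid_spacing Grid resolution in degrees Celsius (must be <= 0.05).
#' @param consts Physical constants.
#' @return A list of class `mmrt_summary`: `topt_c`, `tinf_c`,
#'   `grid_spacing`, `eval_range`, `boundary_censored`, `multimodal`.
#' @export
#' @examples
#' p <- mmrt_params(dH = 3e4, dS = -40, A = 0, B = -4000)
#' summarize_curve(p)
summarize_curve <- function(params, eval_range = c(4, 42), grid_spacing = 0.01,
                            consts = mmrt_constants()) {
  stopifnot(length(eval_range) == 2, eval_range[1] < eval_range[2])
  if (grid_spacing > 0.05) {
    stop("grid_spacing must be <= 0.05 C for reliable summaries", call. = FALSE)
  }
  grid_c <- seq(eval_range[1], eval_range[2], by = grid_spacing)
  rate <- mmrt_rate(celsius_to_kelvin(grid_c), params, consts)

  i_opt <- which.max(rate)
  dr <- diff(rate)               # successive differences ~ first derivative
  i_inf <- which.max(dr)         # left edge of the steepest rise
  tinf_c <- (grid_c[i_inf] + grid_c[i_inf + 1]) / 2

  sign_changes <- sum(diff(sign(dr)) < 0)  # + -> - transitions = interior peaks
  multimodal <- sign_changes > 1
  if (multimodal) {
    warning("rate curve is not unimodal on the evaluation range; ",
            "reporting the largest peak", call. = FALSE)
  }
  boundary <- i_opt %in% c(1L, length(grid_c)) ||
    i_inf %in% c(1L, length(dr))

  structure(
    list(topt_c = grid_c[i_opt], tinf_c = tinf_c,
         grid_spacing = grid_spacing, eval_range = eval_range,
         boundary_censored = boundary, multimodal = multimodal),
    class = "mmrt_summary"
  )
}

#' @export
print.mmrt_summary <- function(x, ...) {
  cat(sprintf("Topt = %.2f C, Tinf = %.2f C (grid %.3g C on [%g, %g] C)\n",
              x$topt_c, x$tinf_c, x$grid_spacing,
              x$eval_range[1], x$eval_range[2]))
  if (x$boundary_censored) cat("  [boundary-censored]\n")
  if (x$multimodal) cat("  [multimodal]\n")
  invisible(x)
}

# Solve for (dH, B) so the curve's Topt and Tinf hit given targets, with A and
# T0 fixed; dS then sets the peak height. d(ln rate)/dT is linear in both dH
# and B, so B has a closed form given dH and the target Topt; dH is found by a
# 1-D root search on the achieved Tinf. Used by the synthetic-study generator
# and for constructing reference curves with known optima.

solve_B_for_topt <- function(topt_k, dH, A, T0, consts = mmrt_constants()) {
  # d(ln rate)/dT = c0 + c1 * B at fixed T; solve c0 + c1 B = 0
  p0 <- mmrt_params(dH = dH, dS = 0, A = A, B = 0, T0 = T0)
  c0 <- mmrt_dlog_rate_dT(topt_k, p0, consts)
  c1 <- (topt_k - T0) / (consts$R * topt_k^2)
  if (abs(c1) < 1e-14) {
    stop("target Topt coincides with T0; B cannot be identified", call. = FALSE)
  }
  -c0 / c1
}

tinf_continuous <- function(params, lower_c, upper_c, consts = mmrt_constants()) {
  opt <- stats::optimize(
    function(tc) mmrt_rate_deriv(celsius_to_kelvin(tc), params, consts),
    lower = lower_c, upper = upper_c, maximum = TRUE, tol = 1e-7
  )
  opt$maximum
}

#' Construct MMRT parameters with a prescribed Topt and Tinf
#'
#' Solves for the activation enthalpy `dH` and heat capacity `B` (with the
#' heat-capacity slope `A` and reference temperature fixed) such that the
#' curve's temperature optimum and inflection point equal the targets, then
#' sets the entropy `dS` so that the peak rate equals `amplitude`.
#'
#' @param topt_c,tinf_c Target optimum and inflection temperatures (C);
#'   `tinf_c < topt_c` required.
#' @param A Heat-capacity slope (J mol^-1 K^-2), fixed.
#' @param T0 Reference temperature (K).
#' @param amplitude Peak rate at Topt (rate units).
#' @param dH_bounds Search interval for the enthalpy (J mol^-1).
#' @param consts Physical constants.
#' @return An [mmrt_params()] object whose [summarize_curve()] optimum and
#'   inflection match the targets.
#' @export
#' @examples
#' p <- solve_mmrt_params(topt_c = 32.9, tinf_c = 22.4)
#' summarize_curve(p, grid_spacing = 0.01)
solve_mmrt_params <- function(topt_c, tinf_c, A = -5, T0 = 300, amplitude = 8,
                              dH_bounds = c(2e3, 4e5),
                              consts = mmrt_constants()) {
  stopifnot(tinf_c < topt_c, amplitude > 0)
  topt_k <- celsius_to_kelvin(topt_c)
  lo_c <- tinf_c - 30

  tinf_given_dH <- function(dH) {
    B <- solve_B_for_topt(topt_k, dH, A, T0, consts)
    p <- mmrt_params(dH = dH, dS = 0, A = A, B = B, T0 = T0)
    tinf_continuous(p, lo_c, topt_c - 1e-3, consts)
  }
  g <- function(dH) tinf_given_dH(dH) - tinf_c
  # expand the search interval if the target gap is extreme for this A
  lo <- dH_bounds[1]; hi <- dH_bounds[2]
  for (try in 1:6) {
    glo <- tryCatch(g(lo), error = function(e) NA_real_)
    ghi <- tryCatch(g(hi), error = function(e) NA_real_)
    if (is.finite(glo) && is.finite(ghi) && sign(glo) != sign(ghi)) break
    lo <- max(lo / 2, 100)
    hi <- hi * 2
    if (try == 6) stop("no MMRT parameters reach Topt = ", topt_c,
                       ", Tinf = ", tinf_c, " with A = ", A, call. = FALSE)
  }
  root <- stats::uniroot(g, interval = c(lo, hi), tol = 1e-6)
  dH <- root$root
  B <- solve_B_for_topt(topt_k, dH, A, T0, consts)
  p0 <- mmrt_params(dH = dH, dS = 0, A = A, B = B, T0 = T0)
  dS <- consts$R * (log(amplitude) - mmrt_log_rate(topt_k, p0, consts))
  mmrt_params(dH = dH, dS = dS, A = A, B = B, T0 = T0)
}
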