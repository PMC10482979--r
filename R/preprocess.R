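# Tube-level preprocessing: blank correction, headspace CO2 -> mass flux, and
# control subtraction to glucose-induced respiration curves.

REQUIRED_INCUBATION_COLS <- c("soil_id", "tube_id", "temperature_c",
                              "treatment", "co2_ppm")
TREATMENT_LEVELS <- c("control", "glucose", "blank")

#' Blank-correct headspace CO2 concentrations
#'
#' Subtracts, per soil batch, the mean CO2 concentration of the blank tubes
#' from every non-blank tube. Corrected concentrations that would be negative
#' are floored at zero with a warning. Blank rows are consumed (dropped from
#' the output). With `enabled = FALSE` the input is returned unchanged.
#'
#' @param records Incubation data frame with at least columns `soil_id`,
#'   `tube_id`, `temperature_c`, `treatment` (control/glucose/blank) and
#'   `co2_ppm`.
#' @param enabled Set `FALSE` to disable blank correction (pass-through).
#' @return The records with `co2_ppm` corrected and blanks removed. The mean
#'   blank per soil is attached as attribute `blank_means`.
#' @export
blank_correct <- function(records, enabled = TRUE) {
  stopifnot(all(REQUIRED_INCUBATION_COLS %in% names(records)))
  if (!enabled) return(records)
  out <- vector("list", length(unique(records$soil_id)))
  blank_means <- numeric(0)
  for (i in seq_along(out)) {
    sid <- unique(records$soil_id)[i]
    batch <- records[records$soil_id == sid, , drop = FALSE]
    blanks <- batch$co2_ppm[batch$treatment == "blank"]
    if (length(blanks) == 0) {
      stop("no blank tubes for soil '", sid,
           "'; supply blanks or disable blank correction", call. = FALSE)
    }
    keep <- batch[batch$treatment != "blank", , drop = FALSE]
    keep$co2_ppm <- keep$co2_ppm - mean(blanks)
    if (any(keep$co2_ppm < 0)) {
      warning("blank correction produced ", sum(keep$co2_ppm < 0),
              " negative concentration(s) for soil '", sid,
              "'; floored at 0", call. = FALSE)
      keep$co2_ppm[keep$co2_ppm < 0] <- 0
    }
    blank_means[as.character(sid)] <- mean(blanks)
    out[[i]] <- keep
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "blank_means") <- blank_means
  res
}

#' Convert a headspace CO2 concentration to a soil mass-specific C flux
#'
#' Ideal-gas conversion of a (blank-corrected) CO2 mole fraction in a sealed
#' tube headspace to micrograms of CO2-C per gram of soil per hour:
#' n = P V / (R T) moles of gas in the headspace at the incubation
#' temperature and 1 atm, of which `ppm * 1e-6` is CO2; times 12.011 g C per
#' mole; divided by soil mass and incubation time.
#'
#' @param co2_ppm CO2 concentration (ppm by volume), blank-corrected.
#' @param temperature_c Incubation temperature (C).
#' @param headspace_ml Headspace volume (mL), default 22.
#' @param incubation_hours Incubation duration (h), default 5.
#' @param soil_mass_g Soil fresh mass (g), default 2.
#' @param pressure_atm Headspace pressure (atm), default 1.
#' @return Respiration rate, ug CO2-C g^-1 soil h^-1. Vectorised.
#' @export
#' @examples
#' ppm_to_mass_rate(500, temperature_c = 25)
ppm_to_mass_rate <- function(co2_ppm, temperature_c, headspace_ml = 22,
                             incubation_hours = 5, soil_mass_g = 2,
                             pressure_atm = 1) {
  stopifnot(headspace_ml > 0, incubation_hours > 0, soil_mass_g > 0,
            pressure_atm > 0)
  if (any(co2_ppm < 0, na.rm = TRUE)) {
    stop("co2_ppm must be non-negative (blank-correct first)", call. = FALSE)
  }
  R_Latm <- 0.0820573661  # L atm mol^-1 K^-1
  n_total <- pressure_atm * (headspace_ml / 1000) /
    (R_Latm * celsius_to_kelvin(temperature_c))
  ug_C <- co2_ppm * 1e-6 * n_total * 12.011 * 1e6
  ug_C / (soil_mass_g * incubation_hours)
}

# inverse of ppm_to_mass_rate, used by the synthetic generator
mass_rate_to_ppm <- function(rate, temperature_c, headspace_ml = 22,
                             incubation_hours = 5, soil_mass_g = 2,
                             pressure_atm = 1) {
  R_Latm <- 0.0820573661
  n_total <- pressure_atm * (headspace_ml / 1000) /
    (R_Latm * celsius_to_kelvin(temperature_c))
  rate * soil_mass_g * incubation_hours / (n_total * 12.011 * 1e6) * 1e6
}

rate_from_record <- function(records) {
  hs <- if ("headspace_ml" %in% names(records)) records$headspace_ml else 22
  hrs <- if ("incubation_hours" %in% names(records)) records$incubation_hours else 5
  sm <- if ("soil_mass_g" %in% names(records)) records$soil_mass_g else 2
  ppm_to_mass_rate(records$co2_ppm, records$temperature_c,
                   headspace_ml = hs, incubation_hours = hrs, soil_mass_g = sm)
}

#' Build glucose-induced respiration curves from paired tubes
#'
#' Pairs control and glucose tubes at matched incubation temperatures
#' (within `pair_tol` C), converts each tube's blank-corrected concentration
#' to a mass-specific flux at its own temperature, and subtracts control from
#' treatment. Non-positive differences and temperatures at or above `cutoff`
#' are excluded (the model is fitted in log space below the cutoff) and
#' counted per soil.
#'
#' @param records Blank-corrected incubation records (no blank rows), see
#'   [blank_correct()].
#' @param cutoff Upper fitting temperature (C), default 42; points at or
#'   above it are dropped.
#' @param pair_tol Temperature tolerance (C) for matching control and
#'   glucose tubes in the same block slot, default 0.25.
#' @param min_points Minimum retained points per curve before the curve is
#'   flagged insufficient, default 11.
#' @return A data frame (`soil_id`, `temperature_c`, `gir`) of glucose-induced
#'   respiration rates (ug CO2-C g^-1 h^-1), with attribute `quality`: a per-
#'   soil data frame of input pairs, retained and excluded counts, exclusion
#'   reasons, and an `insufficient` flag.
#' @export
glucose_induced_curves <- function(records, cutoff = 42, pair_tol = 0.25,
                                   min_points = 11) {
  stopifnot(all(REQUIRED_INCUBATION_COLS %in% names(records)))
  if (any(records$treatment == "blank")) {
    stop("blank rows present; run blank_correct() first", call. = FALSE)
  }
  soils <- unique(records$soil_id)
  curves <- vector("list", length(soils))
  quality <- vector("list", length(soils))
  for (i in seq_along(soils)) {
    sid <- soils[i]
    batch <- records[records$soil_id == sid, , drop = FALSE]
    ctl <- batch[batch$treatment == "control", , drop = FALSE]
    glc <- batch[batch$treatment == "glucose", , drop = FALSE]
    ctl <- ctl[order(ctl$temperature_c), , drop = FALSE]
    glc <- glc[order(glc$temperature_c), , drop = FALSE]
    if (nrow(ctl) != nrow(glc) ||
        any(abs(ctl$temperature_c - glc$temperature_c) > pair_tol)) {
      orphans <- pairing_orphans(ctl$temperature_c, glc$temperature_c, pair_tol)
      stop("control/glucose tubes do not pair one-to-one for soil '", sid,
           "'; unmatched temperatures: ",
           paste(format(orphans), collapse = ", "), call. = FALSE)
    }
    gir <- rate_from_record(glc) - rate_from_record(ctl)
    temp <- (ctl$temperature_c + glc$temperature_c) / 2
    nonpos <- gir <= 0
    hot <- temp >= cutoff
    keep <- !nonpos & !hot
    curves[[i]] <- data.frame(soil_id = rep(sid, sum(keep)),
                              temperature_c = temp[keep],
                              gir = gir[keep])
    quality[[i]] <- data.frame(
      soil_id = sid, n_pairs = length(gir), n_retained = sum(keep),
      n_excluded = sum(!keep), n_nonpositive = sum(nonpos),
      n_above_cutoff = sum(hot & !nonpos),
      insufficient = sum(keep) < min_points
    )
    if (sum(keep) < min_points) {
      warning("soil '", sid, "': only ", sum(keep), " usable points (< ",
              min_points, "); curve flagged insufficient", call. = FALSE)
    }
  }
  out <- do.call(rbind, curves)
  rownames(out) <- NULL
  attr(out, "quality") <- do.call(rbind, quality)
  out
}

pairing_orphans <- function(t_ctl, t_glc, tol) {
  orphans <- c()
  for (t in t_ctl) if (!any(abs(t_glc - t) <= tol)) orphans <- c(orphans, t)
  for (t in t_glc) if (!any(abs(t_ctl - t) <= tol)) orphans <- c(orphans, t)
  sort(unique(orphans))
}
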