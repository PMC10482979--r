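# File exchange (CSV/JSON) and the end-to-end pipeline driver. All tabular
# temperatures in files are degrees Celsius; Kelvin exists only inside the
# model functions.

#' Read and validate an incubation CSV
#'
#' Expects one row per tube with columns `soil_id`, `tube_id`,
#' `temperature_c`, `treatment` (control/glucose/blank), `co2_ppm`, and
#' optionally `incubation_hours`, `soil_mass_g`, `headspace_ml`. Rows with
#' unknown treatment labels, non-numeric/out-of-range temperatures or
#' negative concentrations are rejected; their line numbers are collected in
#' a validation report.
#'
#' @param path CSV file path.
#' @param strict If `TRUE` (default) any rejected row is an error; otherwise
#'   valid rows are returned and the report is attached.
#' @return Validated records with attribute `validation` (data frame of
#'   rejected line numbers and reasons; empty when clean).
#' @export
read_incubation_csv <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    stop("incubation file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(REQUIRED_INCUBATION_COLS, names(raw))
  if (length(missing)) {
    stop("incubation CSV is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  temp <- suppressWarnings(as.numeric(raw$temperature_c))
  ppm <- suppressWarnings(as.numeric(raw$co2_ppm))
  problems <- list()
  flag <- function(bad, reason) {
    if (any(bad, na.rm = TRUE)) {
      problems[[length(problems) + 1]] <<- data.frame(
        line = which(bad) + 1L, reason = reason)  # +1 for the header line
    }
  }
  flag(!raw$treatment %in% TREATMENT_LEVELS, "unknown treatment label")
  flag(is.na(temp), "non-numeric temperature")
  flag(!is.na(temp) & (temp < 0 | temp > 55), "temperature outside 0-55 C")
  flag(is.na(ppm), "non-numeric co2_ppm")
  flag(!is.na(ppm) & ppm < 0, "negative co2_ppm")
  report <- if (length(problems)) do.call(rbind, problems) else
    data.frame(line = integer(0), reason = character(0))
  if (nrow(report)) {
    report <- report[order(report$line), , drop = FALSE]
    rownames(report) <- NULL
    if (strict) {
      stop("incubation CSV failed validation (", nrow(report), " problem(s), ",
           "first at line ", report$line[1], ": ", report$reason[1], ")",
           call. = FALSE)
    }
    warning(nrow(report), " row(s) rejected by validation", call. = FALSE)
  }
  keep <- !(seq_len(nrow(raw)) + 1L) %in% report$line
  out <- raw[keep, , drop = FALSE]
  out$temperature_c <- temp[keep]
  out$co2_ppm <- ppm[keep]
  rownames(out) <- NULL
  attr(out, "validation") <- report
  out
}

#' Read a site metadata CSV
#'
#' Columns: `soil_id`, `lat`, `lon`, `met`, and optionally `ph`, `cohort`,
#' `t30`, `block_id`.
#'
#' @param path CSV file path.
#' @return Validated site records.
#' @export
read_sites_csv <- function(path) {
  if (!file.exists(path)) stop("sites file not found: ", path, call. = FALSE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("soil_id", "lat", "lon", "met"), names(out))
  if (length(missing)) {
    stop("sites CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(out$met < 0 | out$met > 70, na.rm = TRUE)) {
    stop("MET outside the plausible 0-70 C range", call. = FALSE)
  }
  out
}

#' Run the full analysis pipeline and write its artifact bundle
#'
#' preprocess -> fit -> adaptation -> surface -> scenarios, writing each
#' stage's table as CSV plus a JSON provenance record (package version, seed,
#' effective configuration) into `out_dir`. Inputs are either file paths
#' (`incubation`, `sites`) or in-memory data frames, e.g. from
#' [simulate_study()].
#'
#' @param incubation Incubation records (data frame or CSV path).
#' @param sites Site records (data frame or CSV path).
#' @param out_dir Output directory, created if needed. `NULL` skips writing.
#' @param cutoff Upper fitting temperature (C), default 42.
#' @param weights_k k for the k-nearest-neighbour spatial weights.
#' @param spline_df Spline degrees of freedom for the surface.
#' @param scenarios List of `c(met0, delta)` pairs to evaluate.
#' @param seed Seed recorded in the provenance and applied before any
#'   stochastic step (Moran permutations).
#' @return A list of class `thermadapt_run`: `curves`, `quality`,
#'   `fit_table`, `adaptation`, `moran`, `surface`, `scenarios`,
#'   `provenance`.
#' @export
run_pipeline <- function(incubation, sites, out_dir = NULL, cutoff = 42,
                         weights_k = 8, spline_df = 3,
                         scenarios = list(c(20, 4.5)), seed = 1) {
  if (is.character(incubation)) incubation <- read_incubation_csv(incubation)
  if (is.character(sites)) sites <- read_sites_csv(sites)
  set.seed(seed)

  corrected <- blank_correct(incubation)
  curves <- suppressWarnings(glucose_induced_curves(corrected, cutoff = cutoff))
  quality <- attr(curves, "quality")

  fit_table <- fit_cohort(curves, sites)
  conv <- fit_table[fit_table$converged %in% TRUE, , drop = FALSE]
  if (nrow(conv) < 5) stop("fewer than 5 converged fits; cannot continue",
                           call. = FALSE)

  w <- suppressWarnings(
    build_weights(conv[, c("soil_id", "lat", "lon")], k = weights_k))
  adaptation <- adaptation_slopes(conv, w)
  moran <- list(
    topt = morans_i(conv$topt_c, w, nperm = 999, seed = seed),
    tinf = morans_i(conv$tinf_c, w, nperm = 999, seed = seed + 1))

  surf <- build_surface(conv, df = spline_df)
  scen <- lapply(scenarios, function(sc) scenario(surf, sc[1], sc[2]))

  provenance <- list(
    package = "thermadapt",
    version = as.character(utils::packageVersion("thermadapt")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config = list(cutoff = cutoff, weights_k = weights_k,
                  spline_df = spline_df,
                  scenarios = lapply(scenarios, as.numeric)),
    n_soils_in = length(unique(incubation$soil_id)),
    n_converged = nrow(conv))

  run <- structure(
    list(curves = curves, quality = quality, fit_table = fit_table,
         adaptation = adaptation, moran = moran, surface = surf,
         scenarios = scen, provenance = provenance),
    class = "thermadapt_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(run$curves, "curves.csv")
  wcsv(run$quality, "quality.csv")
  drop_nonatomic <- vapply(run$fit_table, is.atomic, logical(1))
  wcsv(run$fit_table[, drop_nonatomic, drop = FALSE], "fits.csv")
  wcsv(run$adaptation, "adaptation.csv")
  wcsv(as.data.frame(run$surface), "surface.csv")
  for (i in seq_along(run$scenarios)) {
    s <- run$scenarios[[i]]
    wcsv(data.frame(temp_c = s$temp_grid, nonadapted = s$nonadapted,
                    adapted = s$adapted, pct_diff = s$pct_diff,
                    pct_change_nonadapted = s$pct_change_nonadapted,
                    pct_change_adapted = s$pct_change_adapted),
         sprintf("scenario_met%s_plus%s.csv", s$met0, s$delta))
  }
  moran_rep <- lapply(run$moran, function(m) {
    m[c("I", "expected", "p_perm", "p_normal", "nperm", "alternative")]
  })
  jsonlite::write_json(moran_rep, file.path(out_dir, "moran.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.thermadapt_run <- function(x, ...) {
  cat("thermadapt pipeline run\n")
  cat("  soils in:", x$provenance$n_soils_in,
      "| converged fits:", x$provenance$n_converged, "\n")
  sar <- x$adaptation[x$adaptation$model == "sar_error", ]
  for (i in seq_len(nrow(sar))) {
    cat(sprintf("  %s ~ MET (SAR): slope %.3f (SE %.3f)\n",
                sar$metric[i], sar$beta_met[i], sar$se_beta[i]))
  }
  invisible(x)
}
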