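# Memoised synthetic cohorts shared across test files: each is a full
# 48-soil study (one unusable soil, so 47 analysed) fitted end to end, with
# SAR-error adaptation slopes. Building these once keeps the suite fast.

.cohort_cache <- new.env(parent = emptyenv())

fitted_cohort <- function(i) {
  key <- paste0("c", i)
  if (is.null(.cohort_cache[[key]])) {
    cfg <- sim_config(seed = 5000 + i, bad_soil = TRUE)
    study <- simulate_study(cfg)
    corrected <- blank_correct(study$incubation)
    curves <- suppressWarnings(glucose_induced_curves(corrected))
    fit_table <- suppressMessages(fit_cohort(curves, study$sites))
    conv <- fit_table[fit_table$converged %in% TRUE, , drop = FALSE]
    w <- suppressWarnings(
      build_weights(conv[, c("soil_id", "lat", "lon")], k = 8))
    slopes <- adaptation_slopes(conv, w)
    .cohort_cache[[key]] <- list(
      study = study, fit_table = fit_table, conv = conv, weights = w,
      slopes = slopes,
      sar_topt = slopes$beta_met[slopes$metric == "topt_c" &
                                   slopes$model == "sar_error"],
      sar_tinf = slopes$beta_met[slopes$metric == "tinf_c" &
                                   slopes$model == "sar_error"])
  }
  .cohort_cache[[key]]
}

cohort_sar_slopes <- function(n) {
  t(vapply(seq_len(n), function(i) {
    co <- fitted_cohort(i)
    c(topt = co$sar_topt, tinf = co$sar_tinf)
  }, numeric(2)))
}
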