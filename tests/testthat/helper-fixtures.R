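# Shared fixtures, built in code.

# absolute-band comparison (expect_equal's tolerance is relative)
expect_within <- function(x, target, band) {
  testthat::expect_lt(abs(x - target), band + 1e-12)
}

# Random, physically sensible MMRT parameter sets (unimodal on 4-42 C):
# constructed through the Topt/Tinf solver so every draw has an interior
# optimum and inflection on the evaluation range.
random_mmrt_params <- function(n, seed = 1, A_range = c(-15, 10)) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    topt <- runif(1, 28, 40)
    tinf <- topt - runif(1, 7, 14)
    solve_mmrt_params(topt, tinf, A = runif(1, A_range[1], A_range[2]),
                      amplitude = exp(runif(1, 0, 3)))
  })
}

# Small tube-level table for one soil with an exactly known glucose-induced
# curve (no noise): control is a mild Arrhenius baseline, glucose adds the
# MMRT rate, everything is converted to headspace ppm and back.
tube_table_for <- function(params, soil_id = "s1", temps = seq(2, 50, 2),
                           ambient = 420) {
  ctl <- 0.5 * exp(65e3 / 8.314462618 *
                     (1 / 298.15 - 1 / celsius_to_kelvin(temps)))
  gir <- mmrt_rate(celsius_to_kelvin(temps), params)
  mk <- function(tr, rate) {
    data.frame(soil_id = soil_id,
               tube_id = paste(soil_id, tr, seq_along(temps), sep = "_"),
               temperature_c = temps, treatment = tr,
               co2_ppm = ambient + thermadapt:::mass_rate_to_ppm(rate, temps),
               incubation_hours = 5, soil_mass_g = 2, headspace_ml = 22)
  }
  blanks <- data.frame(soil_id = soil_id,
                       tube_id = paste(soil_id, "blank", 1:4, sep = "_"),
                       temperature_c = 22, treatment = "blank",
                       co2_ppm = ambient, incubation_hours = 5,
                       soil_mass_g = 2, headspace_ml = 22)
  rbind(mk("control", ctl), mk("glucose", ctl + gir), blanks)
}

# A 6x6 regular lattice of sites (~1 km spacing) for spatial tests.
lattice_sites <- function(nx = 6, ny = 6) {
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  data.frame(soil_id = sprintf("g%02d", seq_len(nrow(g))),
             lat = -40 + g$iy * 0.01, lon = 172 + g$ix * 0.01)
}
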