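# Fixture builders shared across the suite. Everything is generated in code.

# A small hand-written perfusion table with varied covariates.
tiny_table <- function(deposition = c(130.68, 12.5, 800, 3.2, 55, 210)) {
  perfusion_table(
    subject_id = c("CP89", "CP89", "CP90", "CP90", "CP92", "CP98"),
    shear_rate = c(1690, 212, 1390, 212, 1690, 212),
    time_min = c(10, 3, 20, 5, 30, 10),
    hematocrit = c(0.26, 0.24, 0.30, 0.22, 0.28, 0.31),
    platelet_conc = c(341, 300, 420, 182, 250, 449),
    blood = c("native", "heparinized", "native", "native",
              "heparinized", "native"),
    tissue = c("PT", "SE", "TM", "PT", "SE", "TM"),
    stenosis = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    deposition = deposition
  )
}

# One non-stenosed record for MBL forward simulations.
one_record <- function(shear_rate = 1690, time_min = 10, hematocrit = 0.2646,
                       platelet_conc = 341, tissue = "PT") {
  perfusion_table(
    subject_id = "S01", shear_rate = shear_rate, time_min = time_min,
    hematocrit = hematocrit, platelet_conc = platelet_conc,
    blood = "native", tissue = tissue, stenosis = FALSE,
    deposition = NA_real_
  )
}

# The six-point noiseless pig-tendon design used for kinetic recovery:
# times 3/5/10 min at shear 212 and 1690 1/s, population-mean hematology.
pt_recovery_data <- function(params = reference_mbl_params(),
                             geometry = chamber_geometry()) {
  g <- expand.grid(t = c(3, 5, 10), gam = c(212, 1690))
  d <- perfusion_table(
    subject_id = "S01", shear_rate = g$gam, time_min = g$t,
    hematocrit = 0.2646, platelet_conc = 341, blood = "native",
    tissue = "PT", stenosis = FALSE, deposition = NA_real_
  )
  attach_mbl_response(d, params, geometry, noise_sd_log10 = 0, seed = 1)
}

# Independent fixed-step explicit Euler integration of the two-layer system.
# Deliberately naive: the oracle for the adaptive ODE path.
euler_deposition <- function(record, params, geometry = chamber_geometry(),
                             t_end_min, dt_min = 1e-3) {
  D <- platelet_diffusivity(record$hematocrit, record$shear_rate,
                            params$diffusivity)
  h <- mass_transfer_coefficient(D, record$shear_rate,
                                 geometry$substrate_length)
  c0 <- to_si_concentration(record$platelet_conc)
  a1 <- effective_flux(params$k1, h, c0) * geometry$area
  a2 <- effective_flux(params$k2, h, c0) * geometry$area
  p1_max <- monolayer_capacity(geometry, params$d_p)
  dt <- dt_min * 60
  n <- round(t_end_min / dt_min)
  p1 <- 0
  p2 <- 0
  for (i in seq_len(n)) {
    cover <- p1 / p1_max
    p1 <- p1 + dt * a1 * (1 - cover)
    p2 <- p2 + dt * a2 * cover
  }
  (p1 + p2) / geometry$area / 1e10
}

# PM-generated multi-subject dataset for evaluation tests.
pm_dataset <- function(noise = 0.1, seed = 7, records_per_subject = 25) {
  cfg <- generator_config(records_per_subject = records_per_subject,
                          noise_sd_log10 = noise, seed = seed)
  d <- sample_covariates(cfg)
  attach_pm_response(d, reference_pm_params(), noise, seed = seed + 1L)
}

small_rf <- function(seed = 1L) rf_config(ntree = 60, n_repeats = 3, seed = seed)
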