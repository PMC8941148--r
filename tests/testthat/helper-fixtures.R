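# Small configurations shared across test files.

noise_free_config <- function(seed = 2, ...) {
  sim_config(date_sd = 0, residual_sd = 0, date_cv = 0, residual_cv = 0,
             titration_noise_sd = 0, gran_ph_noise_sd = 0, alkalinity_sd = 0,
             dpm_counting = FALSE, seed = seed, ...)
}

small_config <- function(seed = 1, ...) {
  sim_config(n_dates = 6, seed = seed, ...)
}

# bottle-level respiration rates for one simulated study
respiration_table <- function(study) {
  o2 <- winkler_o2_table(study$titration_table, study$standardization_table)
  r <- bottle_rates(o2)
  d <- r[r$analyte == "respiration", ]
  d$treatment <- factor(d$treatment, levels = c("dark", "IR"))
  d
}
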