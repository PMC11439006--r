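# shared fixtures, all built in code

# crop whose absorption, quantum yield and carbon use efficiency are
# identically 1, isolating the unit-conversion chain
unit_crop <- function(w_C = 0.5, t_M = 100, f_E = 1, t_E = 0) {
  m <- matrix(0, 5, 5)
  m[2, 2] <- 1
  mec_crop_parameters("unit", t_A = 1, t_Q = t_M, t_E = t_E, t_M = t_M,
                      f_E = f_E, w_C = w_C, cue_max = 1, a_max = 1,
                      a_exponent = 0, cqy_coeffs = m,
                      ppf_range = c(1e-6, 5000), co2_range = c(1e-6, 5000))
}

# small hand-built harvest table
toy_series <- function() {
  measurement_series(data.frame(
    t = c(10, 15, 20),
    n_plants = 5,
    fresh_weight = c(20, 60, 120),
    fw_sd = c(2, 6, 12),
    dry_biomass = c(1, 3, 6),
    biomass_sd = c(0.1, 0.3, 0.6),
    n_fraction_fw = c(0.005, 0.004, 0.003),
    n_fraction_sd = c(5e-4, 4e-4, 3e-4)),
    condition = "normal")
}

lettuce_truth <- function() default_np_parameters("normal")

# bounds centered on the truth with relative half-width `frac`
truth_bounds <- function(params, frac = 0.5,
                         which = c("r", "K", "m_N0", "b_eta", "m_eta",
                                   "b_mu", "m_mu")) {
  v <- unlist(unclass(params))[which]
  lapply(v, function(x) sort(c(x * (1 - frac), x * (1 + frac))))
}
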