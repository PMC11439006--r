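#' Default lettuce hydroponic scenario
#'
#' The reference controlled-environment lettuce study conditions: PPF 225
#' umol m^-2 s^-1, CO2 525 ppm, 16 h photoperiod, planting density 19.2
#' plants m^-2, fresh-weight water fraction 0.95, destructive harvests at
#' 11, 20, 25, 30, 35 and 40 d after emergence (a 43 d harvest existed but
#' is excluded: plants were bolting and their vegetative-growth data are
#' not usable).
#'
#' @return list with elements `env` ([environment_state()]), `layout`
#'   ([cultivation_layout()]) and `harvest_times`.
#' @examples
#' default_lettuce_scenario()$harvest_times
#' @export
default_lettuce_scenario <- function() {
  list(env = environment_state(ppf = 225, co2 = 525, photoperiod = 16),
       layout = cultivation_layout(sigma_N = 19.2, water_fraction = 0.95),
       harvest_times = c(11, 20, 25, 30, 35, 40))
}

#' Default true NP parameter sets per nitrogen condition
#'
#' Ground-truth parameter sets used by the synthetic-experiment generator,
#' chosen once to emulate the qualitative regime of the reference lettuce
#' study: the nitrogen-accumulation rate `r` is highest under deficiency
#' (plants scavenge the little nitrogen available quickly) while the
#' nitrogen ceiling `K` is lowest there; the excess condition accumulates
#' nitrogen to a similar ceiling but converts it to biomass less
#' effectively (ammonium stress), giving the lowest biomass at harvest;
#' nitrogen use efficiency and the relative accumulation rate decline
#' linearly over the measured window in all conditions.  `alpha = 1`
#' throughout (see [np_parameters()] on the scaling symmetry).
#'
#' @param condition `"normal"`, `"deficient"` or `"excess"`.
#' @return an [np_parameters()] object.
#' @export
default_np_parameters <- function(condition = c("normal", "deficient",
                                                "excess")) {
  condition <- match.arg(condition)
  switch(condition,
    normal = np_parameters(r = 0.30, K = 0.45, alpha = 1, m_N0 = 0.002,
                           b_eta = 12, m_eta = -0.20,
                           b_mu = 0.30, m_mu = -0.005),
    deficient = np_parameters(r = 0.38, K = 0.28, alpha = 1, m_N0 = 0.002,
                              b_eta = 12.5, m_eta = -0.22,
                              b_mu = 0.30, m_mu = -0.005),
    excess = np_parameters(r = 0.26, K = 0.42, alpha = 1, m_N0 = 0.002,
                           b_eta = 13, m_eta = -0.30,
                           b_mu = 0.30, m_mu = -0.006))
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0 || mean == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic hydroponic harvest experiment
#'
#' Simulates per-plant dry biomass (NP forward model) and plant nitrogen
#' (logistic closed form) at each harvest time for each condition, draws
#' `n_per_harvest` per-plant values with multiplicative lognormal noise at
#' the stated coefficients of variation (masses are positive, and noise
#' scales with growth), derives fresh weight through the layout's water
#' fraction, and emits per-harvest means and standard deviations as
#' [measurement_series()] - the same table shape that
#' [load_measurements()] reads, so generated datasets round-trip through
#' the CSV interface.
#'
#' @param true_params named list of [np_parameters()] per condition (names
#'   become condition labels), or a single [np_parameters()] object.
#' @param layout a [cultivation_layout()].
#' @param harvest_times increasing harvest schedule \[d_AE\].
#' @param n_per_harvest plants destructively harvested per time point.
#' @param noise list with `biomass_cv` and `nfrac_cv`: per-plant
#'   coefficients of variation of dry biomass and of the fresh-weight
#'   nitrogen fraction (0 = noiseless).
#' @param seed integer seed; identical seeds give identical datasets.
#' @param dt forward-simulation grid step \[d\].
#' @return named list of [measurement_series()], one per condition.
#' @examples
#' scen <- default_lettuce_scenario()
#' dat <- generate_experiment(
#'   list(normal = default_np_parameters("normal")),
#'   scen$layout, scen$harvest_times, n_per_harvest = 8,
#'   noise = list(biomass_cv = 0.1, nfrac_cv = 0.1), seed = 7)
#' dat$normal$dry_biomass
#' @export
generate_experiment <- function(true_params,
                                layout = default_lettuce_scenario()$layout,
                                harvest_times = c(11, 20, 25, 30, 35, 40),
                                n_per_harvest = 8,
                                noise = list(biomass_cv = 0.1,
                                             nfrac_cv = 0.1),
                                seed = 1, dt = 0.1) {
  if (inherits(true_params, "np_parameters"))
    true_params <- list(other = true_params)
  if (any(diff(harvest_times) <= 0))
    stop("harvest_times must be strictly increasing")
  if (noise$biomass_cv < 0 || noise$nfrac_cv < 0)
    stop("coefficients of variation must be >= 0")
  set.seed(seed)
  grid <- sort(unique(c(seq(0, max(harvest_times), by = dt), harvest_times)))
  out <- lapply(names(true_params), function(cond) {
    p <- true_params[[cond]]
    curve <- simulate_np(p, grid, warn = FALSE)
    mb_true <- approx(curve$t_dae, curve$biomass_total,
                      xout = harvest_times)$y
    mn_true <- nitrogen_mass(harvest_times, p)
    fw_true <- fresh_weight(mb_true, layout$water_fraction)
    nfrac_true <- ifelse(fw_true > 0, mn_true / fw_true, 0)
    recs <- lapply(seq_along(harvest_times), function(i) {
      dry_i <- rlnorm_mean_cv(n_per_harvest, mb_true[i], noise$biomass_cv)
      frac_i <- rlnorm_mean_cv(n_per_harvest, nfrac_true[i], noise$nfrac_cv)
      fw_i <- fresh_weight(dry_i, layout$water_fraction)
      sd0 <- function(x) if (length(x) > 1L) sd(x) else 0
      data.frame(t = harvest_times[i], n_plants = n_per_harvest,
                 fresh_weight = mean(fw_i), fw_sd = sd0(fw_i),
                 dry_biomass = mean(dry_i), biomass_sd = sd0(dry_i),
                 n_fraction_fw = mean(frac_i), n_fraction_sd = sd0(frac_i))
    })
    measurement_series(do.call(rbind, recs),
                       condition = if (cond %in% c("deficient", "normal",
                                                   "excess")) cond
                                   else "other")
  })
  names(out) <- names(true_params)
  out
}
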