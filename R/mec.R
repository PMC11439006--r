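#' Canopy light absorption fraction
#'
#' Power-law canopy closure: `A(t) = a_max * (t / t_A)^a_exponent` before
#' canopy closure at `t_A`, and `A = a_max` afterwards.
#'
#' @param t time \[d_AE\], >= 0 (vectorized).
#' @param crop an [mec_crop()] parameter set.
#' @return absorbed fraction of incident photosynthetic photon flux,
#'   in \[0, a_max\].
#' @examples
#' lettuce <- mec_crop("lettuce")
#' canopy_absorption(c(0, lettuce$t_A / 2, lettuce$t_A), lettuce)
#' @export
canopy_absorption <- function(t, crop) {
  if (any(t < 0)) stop("t must be >= 0")
  ifelse(t < crop$t_A,
         crop$a_max * (t / crop$t_A)^crop$a_exponent,
         crop$a_max)
}

# raw response-surface evaluation (no senescence ramp); vectorized in nothing
cqy_surface <- function(ppf, co2, crop) {
  warn <- FALSE
  if (ppf < crop$ppf_range[1] || ppf > crop$ppf_range[2]) {
    ppf <- min(max(ppf, crop$ppf_range[1]), crop$ppf_range[2]); warn <- TRUE
  }
  if (co2 < crop$co2_range[1] || co2 > crop$co2_range[2]) {
    co2 <- min(max(co2, crop$co2_range[1]), crop$co2_range[2]); warn <- TRUE
  }
  if (warn)
    warning(sprintf(
      "(PPF, CO2) outside the response surface's validity box [%g, %g] x [%g, %g]; evaluating at the clamped point",
      crop$ppf_range[1], crop$ppf_range[2],
      crop$co2_range[1], crop$co2_range[2]))
  xb <- c(1 / ppf, 1, ppf, ppf^2, ppf^3)
  yb <- c(1 / co2, 1, co2, co2^2, co2^3)
  max(0, drop(xb %*% crop$cqy_coeffs %*% yb))
}

#' Canopy quantum yield
#'
#' Evaluates the crop's bundled canopy quantum yield response surface at the
#' environment's (PPF, CO2).  For crops with a post-senescence decline
#' (`cqy_min` present) the surface value is multiplied by a linear ramp from
#' 1 at `t_Q` to `cqy_min` at `t_M`.  Values are clamped at 0, and
#' evaluation outside the surface's documented validity box warns and clamps
#' to the box edge.
#'
#' @param env an [environment_state()]; requires `ppf > 0` and `co2 > 0`.
#' @param t time \[d_AE\] (vectorized).
#' @param crop an [mec_crop()] parameter set.
#' @return canopy quantum yield \[mol_C fixed per mol photons absorbed\].
#' @export
canopy_quantum_yield <- function(env, t, crop) {
  if (env$ppf <= 0 || env$co2 <= 0)
    stop("canopy_quantum_yield requires ppf > 0 and co2 > 0")
  base <- cqy_surface(env$ppf, env$co2, crop)
  if (is.null(crop$cqy_min)) return(rep(base, length(t)))
  frac <- ifelse(t <= crop$t_Q, 1,
                 pmax(crop$cqy_min,
                      1 + (crop$cqy_min - 1) *
                        pmin(1, (t - crop$t_Q) / (crop$t_M - crop$t_Q))))
  base * frac
}

#' 24-hour carbon use efficiency
#'
#' Constant at `cue_max` through `t_Q`; crops with a senescence decline
#' (`cue_min` present) ramp linearly to `cue_min` at `t_M` and hold it
#' thereafter.
#'
#' @inheritParams canopy_absorption
#' @return carbon use efficiency \[mol_C biomass per mol_C fixed\].
#' @export
carbon_use_efficiency <- function(t, crop) {
  if (any(t < 0)) stop("t must be >= 0")
  if (is.null(crop$cue_min)) return(rep(crop$cue_max, length(t)))
  ifelse(t <= crop$t_Q, crop$cue_max,
         crop$cue_max + (crop$cue_min - crop$cue_max) *
           pmin(1, (t - crop$t_Q) / (crop$t_M - crop$t_Q)))
}

#' Daily carbon gain and areal biomass growth rate
#'
#' The energy cascade: daily areal carbon gain is
#' `0.0036 * H * eta_C * A * PPF * Y_Q` \[mol_C d^-1 m^-2\] (the factor
#' 0.0036 converts umol s^-1 over H hours to mol d^-1), and the biomass
#' growth rate is `(m_molar_C / w_C)` times the carbon gain
#' \[g_DW d^-1 m^-2\].
#'
#' @param t time \[d_AE\] (vectorized).
#' @param env an [environment_state()].
#' @param crop an [mec_crop()] parameter set.
#' @return `daily_carbon_gain()`: \[mol_C d^-1 m^-2\];
#'   `areal_growth_rate()`: \[g_DW d^-1 m^-2\].
#' @examples
#' # unit anchor: H = 24 h with eta_C = A = Y_Q = PPF = 1 gives 0.0864
#' unit_crop <- mec_crop_parameters("unit", t_A = 1, t_Q = 100, t_E = 0,
#'   t_M = 100, f_E = 1, w_C = 0.5, cue_max = 1, a_max = 1, a_exponent = 0,
#'   cqy_coeffs = {m <- matrix(0, 5, 5); m[2, 2] <- 1; m},
#'   ppf_range = c(0.5, 2000), co2_range = c(1, 2000))
#' daily_carbon_gain(1, environment_state(1, 400, 24), unit_crop)
#' @export
daily_carbon_gain <- function(t, env, crop) {
  if (env$ppf == 0) return(rep(0, length(t)))   # dark: no quantum yield
  0.0036 * env$photoperiod * carbon_use_efficiency(t, crop) *
    canopy_absorption(t, crop) * env$ppf *
    canopy_quantum_yield(env, t, crop)
}

#' @rdname daily_carbon_gain
#' @export
areal_growth_rate <- function(t, env, crop) {
  (crop$m_molar_C / crop$w_C) * daily_carbon_gain(t, env, crop)
}

# edible-overlap trapezoid: integrates f_E * rate over [t_E, t] with linear
# interpolation of the rate at t_E when it falls inside a grid interval
edible_cumint <- function(times, rate, t_E, f_E) {
  n <- length(times)
  inc <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    a <- times[i]; b <- times[i + 1L]
    if (b <= t_E) next
    if (a >= t_E) {
      inc[i] <- (rate[i] + rate[i + 1L]) / 2 * (b - a)
    } else {
      rE <- rate[i] + (rate[i + 1L] - rate[i]) * (t_E - a) / (b - a)
      inc[i] <- (rE + rate[i + 1L]) / 2 * (b - t_E)
    }
  }
  f_E * c(0, cumsum(inc))
}

#' Simulate the MEC biomass model
#'
#' Integrates the areal growth rate over the grid by the trapezoid rule
#' (the rate depends only on time, so quadrature suffices).  Total biomass
#' accumulates from 0; edible biomass accumulates the fraction `f_E` of
#' growth after organ-formation onset `t_E`.  Grid points beyond crop
#' maturity `t_M` are truncated with a warning.
#'
#' @param env an [environment_state()].
#' @param crop an [mec_crop()] parameter set.
#' @param t_grid increasing time grid \[d_AE\] starting at 0; default
#'   0 to `t_M` in steps of `dt`.
#' @param dt default grid step \[d\] when `t_grid` is not given.
#' @return an areal-basis [growth_curve()].
#' @examples
#' curve <- simulate_mec(environment_state(225, 525), mec_crop("lettuce"))
#' tail(curve, 1)
#' @export
simulate_mec <- function(env, crop, t_grid = NULL, dt = 0.1) {
  if (is.null(t_grid)) t_grid <- seq(0, crop$t_M, by = dt)
  if (t_grid[1] != 0) stop("t_grid must start at 0")
  if (any(t_grid > crop$t_M)) {
    warning("t_grid extends beyond crop maturity t_M; truncating")
    t_grid <- t_grid[t_grid <= crop$t_M]
  }
  rate <- areal_growth_rate(t_grid, env, crop)
  gain <- daily_carbon_gain(t_grid, env, crop)
  total <- cumtrapz(t_grid, rate)
  edible <- edible_cumint(t_grid, rate, crop$t_E, crop$f_E)
  growth_curve(t_grid, total, pmin(edible, total), rate, gain,
               basis = "areal")
}
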