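#' Hybrid MEC-NP limiting-factor simulation
#'
#' Runs the light/CO2-driven MEC model and the nitrogen-driven NP model on a
#' shared time grid (NP output converted to the areal basis through the
#' cultivation layout) and takes, at every grid point, the smaller of the
#' two instantaneous growth rates as the realized rate; a single biomass
#' state accumulates the realized increments by the trapezoid rule.  Each
#' step is labelled with the limiting model (`"np"`, `"mec"`, or `"both"`
#' within relative tolerance 1e-9), so label switches trace rate crossovers
#' - e.g. growth limited first by nitrogen, later by photon flux.
#'
#' Rates are compared at calendar time `t` for both models (no
#' developmental-stage re-mapping), and the comparison is rate-level, not
#' curve-level.  Edible biomass follows the MEC allocation rule: the
#' fraction `f_E` of realized growth after organ-formation onset `t_E`.
#'
#' @param env an [environment_state()].
#' @param crop an [mec_crop()] parameter set.
#' @param np_params an [np_parameters()] object (per-plant basis).
#' @param layout a [cultivation_layout()] converting NP output to areal.
#' @param t_grid increasing grid \[d_AE\] from 0; defaults to
#'   `seq(0, crop$t_M, by = dt)`.
#' @param dt default grid step \[d\].
#' @param f_E edible allocation fraction; defaults to the crop's MEC value
#'   (the edible share may differ under nitrogen limitation, so it is
#'   overridable).
#' @param clamp_negative clamp negative NP growth rates at zero (see
#'   [simulate_np()]).
#' @return an areal-basis [growth_curve()] with a `limiting_model` column;
#'   steps where the labels say `"np"` contribute NP increments, etc.
#' @examples
#' hy <- hybrid_simulate(environment_state(225, 525), mec_crop("lettuce"),
#'   np_parameters(r = 0.3, K = 0.45, m_N0 = 0.002, b_eta = 12,
#'                 m_eta = -0.2, b_mu = 0.3, m_mu = -0.005),
#'   cultivation_layout())
#' table(hy$limiting_model)
#' @export
hybrid_simulate <- function(env, crop, np_params, layout, t_grid = NULL,
                            dt = 0.1, f_E = crop$f_E,
                            clamp_negative = TRUE) {
  if (is.null(t_grid)) t_grid <- seq(0, crop$t_M, by = dt)
  if (t_grid[1] != 0) stop("t_grid must start at 0")
  rate_mec <- areal_growth_rate(t_grid, env, crop)
  rate_np <- nitrogen_productivity(t_grid, np_params) *
    nitrogen_mass(t_grid, np_params) * layout$sigma_N
  if (clamp_negative) rate_np <- pmax(rate_np, 0)
  rate <- pmin(rate_mec, rate_np)

  n <- length(t_grid)
  inc_mec <- diff(t_grid) * (rate_mec[-n] + rate_mec[-1]) / 2
  inc_np <- diff(t_grid) * (rate_np[-n] + rate_np[-1]) / 2
  tol <- 1e-9 * pmax(abs(inc_mec), abs(inc_np), 1e-300)
  step_label <- ifelse(abs(inc_mec - inc_np) <= tol, "both",
                       ifelse(inc_np < inc_mec, "np", "mec"))
  total <- cumtrapz(t_grid, rate)
  edible <- edible_cumint(t_grid, rate, crop$t_E, f_E)
  growth_curve(t_grid, total, pmin(edible, total), rate, NA_real_,
               basis = "areal", limiting_model = c(step_label[1], step_label))
}
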