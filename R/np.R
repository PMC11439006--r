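#' Nitrogen-productivity model parameters
#'
#' Parameter set of the nitrogen-productivity (NP) growth model: logistic
#' plant-nitrogen accumulation (rate `r`, limit `K`, scaling `alpha`,
#' initial mass `m_N0`) and the productivity decomposition
#' `Ydot_N(t) = eta_N(t) * mu_N(t) * eta_u` with nitrogen use efficiency
#' and relative nitrogen accumulation rate approximated as linear in time:
#' `eta_N(t) = b_eta + m_eta * t`, `mu_N(t) = b_mu + m_mu * t`.
#'
#' `alpha` rescales the whole nitrogen trajectory (including the initial
#' condition `m_N(0) = alpha * m_N0`); note the exact scaling symmetry
#' `(alpha, K, m_N0) -> (c*alpha, K/c, m_N0/c)` which leaves every model
#' observable unchanged - see the package vignette and [fit_np()].
#'
#' @param r governing nitrogen-accumulation rate \[d^-1\], > 0.
#' @param K limiting value of plant nitrogen mass \[g_N\], > 0.
#' @param alpha dimensionless scaling factor, > 0.
#' @param m_N0 initial plant nitrogen mass \[g_N\], in (0, K\].
#' @param b_eta,m_eta intercept \[g_DW g_N^-1\] and slope
#'   \[g_DW g_N^-1 d^-1\] of the linear nitrogen use efficiency.
#' @param b_mu,m_mu intercept \[d^-1\] and slope \[d^-2\] of the linear
#'   relative nitrogen accumulation rate.
#' @param eta_u uptake efficiency, dimensionless in \[0, 1\] (default 1:
#'   uptake at its maximum).
#' @return an object of class `np_parameters`.
#' @examples
#' np_parameters(r = 0.3, K = 0.45, m_N0 = 0.002, b_eta = 12,
#'               m_eta = -0.2, b_mu = 0.3, m_mu = -0.005)
#' @export
np_parameters <- function(r, K, alpha = 1, m_N0, b_eta, m_eta = 0,
                          b_mu, m_mu = 0, eta_u = 1) {
  if (r <= 0) stop("r must be > 0")
  if (K <= 0) stop("K must be > 0")
  if (alpha <= 0) stop("alpha must be > 0")
  if (m_N0 <= 0 || m_N0 > K) stop("m_N0 must lie in (0, K]")
  if (eta_u < 0 || eta_u > 1) stop("eta_u must lie in [0, 1]")
  structure(list(r = r, K = K, alpha = alpha, m_N0 = m_N0,
                 b_eta = b_eta, m_eta = m_eta, b_mu = b_mu, m_mu = m_mu,
                 eta_u = eta_u),
            class = "np_parameters")
}

#' @export
print.np_parameters <- function(x, ...) {
  cat("<np_parameters>\n")
  cat(sprintf("  logistic N:  r = %g d^-1, K = %g g_N, alpha = %g, m_N0 = %g g_N\n",
              x$r, x$K, x$alpha, x$m_N0))
  cat(sprintf("  eta_N(t) = %g %+g t  [g_DW g_N^-1]\n", x$b_eta, x$m_eta))
  cat(sprintf("  mu_N(t)  = %g %+g t  [d^-1],  eta_u = %g\n",
              x$b_mu, x$m_mu, x$eta_u))
  invisible(x)
}

#' Serialize NP parameters
#'
#' Flat JSON mapping of the nine parameter fields; the same schema is
#' consumed by the fitting and sensitivity modules and the CLI.
#'
#' @param params an [np_parameters()] object.
#' @param path file path.
#' @return `read_np_parameters()` returns an [np_parameters()] object.
#' @export
write_np_parameters <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_np_parameters
#' @export
read_np_parameters <- function(path) {
  x <- jsonlite::fromJSON(path)
  do.call(np_parameters, x[intersect(names(x), names(formals(np_parameters)))])
}

#' Plant nitrogen mass over time
#'
#' Three-parameter logistic nitrogen accumulation,
#' `m_N(t) = alpha * m_N0 * K * exp(r t) / ((K - m_N0) + m_N0 * exp(r t))`,
#' evaluated in the overflow-safe rearrangement
#' `alpha * K / (1 + ((K - m_N0)/m_N0) * exp(-r t))`.  `K = m_N0` gives the
#' constant `alpha * K` exactly.
#'
#' @param t time \[d\], >= 0 (vectorized).
#' @param params an [np_parameters()] object.
#' @return plant nitrogen mass \[g_N\].
#' @examples
#' p <- np_parameters(r = 0.3, K = 0.45, m_N0 = 0.002, b_eta = 12,
#'                    m_eta = -0.2, b_mu = 0.3, m_mu = -0.005)
#' nitrogen_mass(c(0, 20, 60), p)
#' @export
nitrogen_mass <- function(t, params) {
  if (any(t < 0)) stop("t must be >= 0")
  with(params, alpha * K / (1 + ((K - m_N0) / m_N0) * exp(-r * t)))
}

#' Nitrogen productivity of the NP model
#'
#' `Ydot_N(t) = eta_N(t) * mu_N(t) * eta_u`, with the linear-in-time
#' nitrogen use efficiency and relative nitrogen accumulation rate.  The
#' linear forms can turn negative late in life; callers decide whether to
#' clamp (see [simulate_np()]).
#'
#' @inheritParams nitrogen_mass
#' @return nitrogen productivity \[g_DW d^-1 g_N^-1\].
#' @export
nitrogen_productivity <- function(t, params) {
  with(params, (b_eta + m_eta * t) * (b_mu + m_mu * t) * eta_u)
}

#' Agren-form nitrogen productivity
#'
#' The classical state-dependent form `Ydot_N = a - a' * m_B / m_N`: a
#' species-specific leading term diminished in proportion to the
#' biomass-to-nitrogen ratio.  May return negative values; clamping is the
#' caller's decision.
#'
#' @param m_B plant dry biomass \[g_DW\].
#' @param m_N plant nitrogen mass \[g_N\], > 0.
#' @param params an [agren_parameters()] object.
#' @return nitrogen productivity \[g_DW d^-1 g_N^-1\].
#' @export
agren_productivity <- function(m_B, m_N, params) {
  if (any(m_N <= 0)) stop("m_N must be > 0")
  params$a - params$a_prime * (m_B / m_N)
}

#' @rdname agren_productivity
#' @param a leading term \[g_DW d^-1 g_N^-1\], > 0.
#' @param a_prime correction (photosynthetic-nitrogen degradation) term
#'   \[d^-1\], >= 0.
#' @export
agren_parameters <- function(a, a_prime) {
  if (a <= 0) stop("a must be > 0")
  if (a_prime < 0) stop("a_prime must be >= 0")
  structure(list(a = a, a_prime = a_prime), class = "agren_parameters")
}

#' Simulate the NP biomass model (per-plant basis)
#'
#' Integrates `dm_B/dt = eta_N(t) * mu_N(t) * eta_u * m_N(t)` with the
#' closed-form logistic `m_N`, by the trapezoid rule on the grid.  By
#' default a negative instantaneous rate (possible late in life under the
#' linear productivity forms) is clamped at 0 with a warning; set
#' `clamp_negative = FALSE` to allow biomass loss.
#'
#' @param params an [np_parameters()] object.
#' @param t_grid increasing time grid \[d\] starting at 0.
#' @param m_B0 initial biomass \[g_DW\], >= 0 (default 0 at emergence).
#' @param clamp_negative clamp negative growth rates at zero?
#' @param warn warn when clamping occurs?
#' @return a per-plant-basis [growth_curve()] whose `growth_rate` column
#'   holds the (possibly clamped) integrand; `biomass_edible` equals
#'   `biomass_total` (the NP model does not partition organs).
#' @examples
#' p <- np_parameters(r = 0.3, K = 0.45, m_N0 = 0.002, b_eta = 12,
#'                    m_eta = -0.2, b_mu = 0.3, m_mu = -0.005)
#' curve <- simulate_np(p, seq(0, 40, by = 0.1))
#' tail(curve, 1)
#' @export
simulate_np <- function(params, t_grid = seq(0, 40, by = 0.1), m_B0 = 0,
                        clamp_negative = TRUE, warn = TRUE) {
  if (t_grid[1] != 0) stop("t_grid must start at 0")
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  if (m_B0 < 0) stop("m_B0 must be >= 0")
  rate <- nitrogen_productivity(t_grid, params) * nitrogen_mass(t_grid, params)
  if (clamp_negative && any(rate < 0)) {
    if (warn)
      warning("negative growth rate clamped at 0 (productivity turned negative on the grid)")
    rate <- pmax(rate, 0)
  }
  total <- m_B0 + cumtrapz(t_grid, rate)
  growth_curve(t_grid, total, total, rate, NA_real_, basis = "per-plant")
}

#' Convert a per-plant growth curve to an areal basis
#'
#' Multiplies the biomass and rate channels by the planting density
#' `sigma_N`.  Fresh-weight conversion is available separately through
#' [fresh_weight()].
#'
#' @param curve a per-plant-basis [growth_curve()].
#' @param layout a [cultivation_layout()].
#' @return an areal-basis [growth_curve()].
#' @examples
#' p <- np_parameters(r = 0.3, K = 0.45, m_N0 = 0.002, b_eta = 12,
#'                    m_eta = -0.2, b_mu = 0.3, m_mu = -0.005)
#' to_areal(simulate_np(p, seq(0, 30, 0.5)), cultivation_layout())
#' @export
to_areal <- function(curve, layout) {
  if (attr(curve, "basis") != "per-plant")
    stop("to_areal expects a per-plant-basis curve")
  s <- layout$sigma_N
  growth_curve(curve$t_dae, curve$biomass_total * s,
               curve$biomass_edible * s, curve$growth_rate * s,
               curve$carbon_gain * s, basis = "areal",
               limiting_model = curve$limiting_model)
}
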