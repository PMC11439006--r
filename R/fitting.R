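# ---- seeded differential evolution (rand/1/bin) ----------------------------

de_optim <- function(fn, lower, upper, seed = 1,
                     pop_size = NULL, maxiter = 1000, F = c(0.5, 1),
                     CR = 0.7, tol = 1e-8) {
  d <- length(lower)
  stopifnot(length(upper) == d)
  if (any(lower > upper)) stop("infeasible bounds: lower > upper")
  free <- which(upper > lower)
  if (!length(free)) {
    x <- lower
    return(list(par = x, value = fn(x), n_evals = 1L, converged = TRUE,
                iterations = 0L))
  }
  set.seed(seed)
  np <- pop_size %||% max(15L * length(free), 20L)
  pop <- matrix(rep(lower, each = np), np, d)
  for (j in free) {
    # Latin-hypercube start: one draw per equal-probability stratum
    strata <- (sample.int(np) - runif(np)) / np
    pop[, j] <- lower[j] + strata * (upper[j] - lower[j])
  }
  fit <- apply(pop, 1L, fn)
  n_evals <- np
  converged <- FALSE
  iter <- 0L
  rows <- seq_len(np)
  for (iter in seq_len(maxiter)) {
    Fg <- if (length(F) == 2L) runif(1, F[1], F[2]) else F  # dither
    # rand/1/bin donors r1 != r2 != r3 != i, drawn per row; collisions redrawn
    r <- vapply(1:3, function(k) {
      x <- sample.int(np, np, replace = TRUE)
      while (any(bad <- x == rows)) x[bad] <- sample.int(np, sum(bad),
                                                         replace = TRUE)
      x
    }, integer(np))
    mutant <- pop[r[, 1], , drop = FALSE] +
      Fg * (pop[r[, 2], , drop = FALSE] - pop[r[, 3], , drop = FALSE])
    cross <- matrix(FALSE, np, d)
    cross[, free] <- matrix(runif(np * length(free)) < CR, np)
    cross[cbind(rows, free[sample.int(length(free), np, replace = TRUE)])] <- TRUE
    trial <- pop
    trial[cross] <- mutant[cross]
    trial <- pmin(pmax(trial, matrix(lower, np, d, byrow = TRUE)),
                  matrix(upper, np, d, byrow = TRUE))
    ftrial <- apply(trial, 1L, fn)
    n_evals <- n_evals + np
    sel <- ftrial <= fit
    pop[sel, ] <- trial[sel, , drop = FALSE]
    fit[sel] <- ftrial[sel]
    if (max(fit) - min(fit) <= tol * (abs(mean(fit)) + 1)) {
      converged <- TRUE
      break
    }
  }
  best <- which.min(fit)
  list(par = pop[best, ], value = fit[best], n_evals = n_evals,
       converged = converged, iterations = iter)
}

# ---- observation assembly ---------------------------------------------------

#' Assemble fitting observations from a harvest series
#'
#' Turns a [measurement_series()] into the channel list consumed by
#' [np_objective()]: per-harvest dry biomass, per-harvest plant nitrogen
#' mass, and the measurement-derived nitrogen-productivity interval series
#' reported at interval midpoints (the default constraint set).  Optional
#' `"nue"` and `"rnar"` channels expose the empirical nitrogen use
#' efficiency and relative nitrogen accumulation rate series; they are
#' compared against the eta_N / mu_N lines directly and are the only
#' channels that identify the eta_N / mu_N split (the productivity product
#' cannot), at the cost of an intrinsic estimator-model mismatch - see the
#' package vignette.
#'
#' @param series a [measurement_series()].
#' @param channels subset of
#'   `c("biomass", "nitrogen", "productivity", "nue", "rnar")`.
#' @return named list of data frames with columns `t` and `value`.
#' @export
as_np_observations <- function(series,
                               channels = c("biomass", "nitrogen",
                                            "productivity")) {
  channels <- match.arg(channels,
                        c("biomass", "nitrogen", "productivity",
                          "nue", "rnar"), several.ok = TRUE)
  obs <- list()
  if ("biomass" %in% channels)
    obs$biomass <- data.frame(t = series$t, value = series$dry_biomass)
  if ("nitrogen" %in% channels)
    obs$nitrogen <- data.frame(t = series$t, value = series$m_N)
  t <- series$t
  t1 <- t[-length(t)]; t2 <- t[-1]; t_mid <- (t1 + t2) / 2
  if ("productivity" %in% channels) {
    p <- empirical_productivity(series)
    obs$productivity <- data.frame(t = p$t_mid, value = p$productivity,
                                   t1 = t1, t2 = t2)
  }
  if ("nue" %in% channels)
    obs$nue <- data.frame(t = t_mid,
                          value = empirical_nue_series(series)$value)
  if ("rnar" %in% channels)
    obs$rnar <- data.frame(t = t_mid,
                           value = empirical_rnar_series(series)$value)
  obs
}

# biomass trajectory at requested times without growth_curve overhead
np_biomass_at <- function(params, t, m_B0, dt, clamp_negative = TRUE) {
  grid <- sort(unique(c(seq(0, max(t), by = dt), t)))
  rate <- nitrogen_productivity(grid, params) * nitrogen_mass(grid, params)
  if (clamp_negative) rate <- pmax(rate, 0)
  total <- m_B0 + cumtrapz(grid, rate)
  approx(grid, total, xout = t)$y
}

# the biomass/nitrogen/productivity channels are predicted by applying the
# same interval estimator used on the data to the model trajectory (so a
# perfect parameter set gives zero residuals there); the nue/rnar channels
# are predicted by the eta_N / mu_N lines themselves, mirroring how those
# lines are calibrated against the empirical series - that is what
# identifies the eta_N / mu_N split
np_predict_channel <- function(channel, df, params, layout, m_B0, dt) {
  scale <- if (is.null(layout)) 1 else layout$sigma_N
  interval <- !is.null(df$t1)
  switch(channel,
    biomass = np_biomass_at(params, df$t, m_B0, dt) * scale,
    nitrogen = nitrogen_mass(df$t, params),
    productivity = if (interval) {
      mb <- np_biomass_at(params, c(df$t1, df$t2), m_B0, dt)
      n <- nrow(df)
      mn1 <- nitrogen_mass(df$t1, params)
      mn2 <- nitrogen_mass(df$t2, params)
      (mb[(n + 1):(2 * n)] - mb[1:n]) / (df$t2 - df$t1) / ((mn1 + mn2) / 2)
    } else nitrogen_productivity(df$t, params),
    nue = params$b_eta + params$m_eta * df$t,
    rnar = params$b_mu + params$m_mu * df$t,
    stop("unknown observation channel: ", channel))
}

#' Least-squares objective for NP parameter estimation
#'
#' Sum over observation channels and time points of weighted squared
#' residuals between model predictions and observations (the squared
#' Euclidean norm of the weighted residual vector).  Because the channels
#' carry different units, the default weight for each channel is the
#' reciprocal of the sample standard deviation of its observed values
#' (1 when that is zero), so no channel dominates by unit choice alone.
#'
#' @param params an [np_parameters()] object.
#' @param observations a [measurement_series()] (converted through
#'   [as_np_observations()] with its default channels) or a named channel
#'   list as returned by [as_np_observations()].
#' @param weights optional named per-channel weights overriding the
#'   default.
#' @param layout optional [cultivation_layout()]; when supplied, biomass
#'   predictions are converted to the areal basis before comparison.
#' @param m_B0 initial biomass passed to [simulate_np()].
#' @param dt simulation grid step \[d\].
#' @return scalar objective; attribute `per_target` holds the per-channel
#'   weighted residual sums.
#' @export
np_objective <- function(params, observations, weights = NULL,
                         layout = NULL, m_B0 = 0, dt = 0.1) {
  fn <- make_np_objective(observations, weights, layout, m_B0, dt)
  fn(unclass(params), detail = TRUE)
}

# precompiled objective closure: the simulation grid, observation indices
# and channel weights are resolved once, so differential evolution pays
# only for the trajectory evaluation itself
make_np_objective <- function(observations, weights = NULL, layout = NULL,
                              m_B0 = 0, dt = 0.1) {
  if (inherits(observations, "measurement_series"))
    observations <- as_np_observations(observations)
  if (!length(observations)) stop("no observations supplied")
  all_t <- unlist(lapply(observations, function(df)
    c(df$t, df$t1, df$t2)))
  grid <- sort(unique(c(seq(0, max(all_t), by = dt), all_t)))
  scale <- if (is.null(layout)) 1 else layout$sigma_N
  chan <- lapply(names(observations), function(ch) {
    df <- observations[[ch]]
    w <- weights[[ch]] %||% {
      s <- sd(df$value)
      if (is.na(s) || s == 0) 1 else 1 / s
    }
    list(name = ch, value = df$value, w = w,
         i = match(df$t, grid),
         i1 = if (!is.null(df$t1)) match(df$t1, grid),
         i2 = if (!is.null(df$t2)) match(df$t2, grid),
         t = df$t, dt_int = if (!is.null(df$t1)) df$t2 - df$t1)
  })
  names(chan) <- names(observations)
  dgrid <- diff(grid)

  function(p, detail = FALSE) {
    bad <- with(p, r <= 0 || K <= 0 || alpha <= 0 || m_N0 <= 0 ||
                  m_N0 > K || eta_u < 0 || eta_u > 1)
    if (bad) return(if (detail) structure(1e12, per_target = NULL) else 1e12)
    mN <- p$alpha * p$K / (1 + ((p$K - p$m_N0) / p$m_N0) * exp(-p$r * grid))
    rate <- pmax((p$b_eta + p$m_eta * grid) * (p$b_mu + p$m_mu * grid) *
                   p$eta_u * mN, 0)
    n <- length(grid)
    total <- m_B0 + c(0, cumsum(dgrid * (rate[-n] + rate[-1]) / 2))
    per <- vapply(chan, function(ch) {
      pred <- switch(ch$name,
        biomass = total[ch$i] * scale,
        nitrogen = mN[ch$i],
        productivity = if (!is.null(ch$i1))
          (total[ch$i2] - total[ch$i1]) / ch$dt_int /
            ((mN[ch$i1] + mN[ch$i2]) / 2)
        else (p$b_eta + p$m_eta * ch$t) * (p$b_mu + p$m_mu * ch$t) * p$eta_u,
        nue = p$b_eta + p$m_eta * ch$t,
        rnar = p$b_mu + p$m_mu * ch$t,
        stop("unknown observation channel: ", ch$name))
      sum((ch$w * (pred - ch$value))^2)
    }, numeric(1))
    if (detail) structure(sum(per), per_target = per) else sum(per)
  }
}

# ---- fitting ----------------------------------------------------------------

#' Default parameter bounds for NP fitting
#'
#' Wide, unit-aware boxes for the free parameters.  The initial nitrogen
#' mass `m_N0` defaults to \[0.1 mg, 10 mg\], encoding the prior that a
#' seedling holds on the order of a milligram of nitrogen.
#'
#' @return named list of `c(lower, upper)` vectors.
#' @export
default_np_bounds <- function() {
  list(r = c(0.02, 1.2), K = c(0.01, 10), m_N0 = c(1e-4, 1e-2),
       b_eta = c(0, 100), m_eta = c(-5, 5),
       b_mu = c(0, 1.5), m_mu = c(-0.1, 0.1))
}

build_np_params <- function(x, free_names, fixed) {
  vals <- as.list(fixed)
  vals[free_names] <- as.list(x)
  vals$alpha <- vals$alpha %||% 1
  vals$eta_u <- vals$eta_u %||% 1
  tryCatch(do.call(np_parameters, vals), error = function(e) NULL)
}

#' Fit NP model parameters by differential evolution with L-BFGS polishing
#'
#' Minimizes [np_objective()] over a bounded parameter box with a seeded
#' rand/1/bin differential-evolution search, then polishes the best member
#' with bounded quasi-Newton (L-BFGS-B) steps, returning the better of the
#' two iterates.  `alpha` and `eta_u` are held fixed by default: `eta_u`
#' because uptake is assumed maximal, `alpha` because of the exact scaling
#' symmetry `(alpha, K, m_N0) -> (c*alpha, K/c, m_N0/c)` that makes the
#' triple jointly non-identifiable (the model is over-parameterized).
#' Either can be freed by adding bounds for it.
#'
#' @param observations a [measurement_series()] or channel list (see
#'   [np_objective()]).
#' @param bounds named list of `c(lower, upper)` boxes; the names define
#'   the free parameter set.  Collapsed boxes (`lower == upper`) pin a
#'   parameter at that value.
#' @param seed integer seed for the stochastic search.
#' @param fixed named values for parameters not in `bounds`.
#' @param weights,layout,m_B0,dt passed to [np_objective()].
#' @param control list overriding differential-evolution settings
#'   `pop_size` (default 15 x number of free parameters), `maxiter`
#'   (1000), mutation factor `F` (a length-2 vector requests per-generation
#'   dither, default U(0.5, 1)), crossover rate `CR` (0.7), `tol` (1e-8),
#'   `polish` (TRUE), and `log10` (names of free parameters searched on a
#'   log10 scale when their lower bound is positive; default
#'   `c("r", "K", "m_N0")`, the scale parameters spanning orders of
#'   magnitude).  The search uses rand/1/bin mutation from a
#'   Latin-hypercube start.
#' @return an object of class `np_fit` with elements `params`
#'   ([np_parameters()]), `objective`, `bounds`, `n_evals`, `converged`,
#'   `per_target_residuals` and `seed`.
#' @examples
#' \donttest{
#' scen <- default_lettuce_scenario()
#' dat <- generate_experiment(list(normal = default_np_parameters("normal")),
#'   scen$layout, scen$harvest_times, n_per_harvest = 8,
#'   noise = list(biomass_cv = 0, nfrac_cv = 0), seed = 1)
#' fit <- fit_np(dat$normal, bounds = default_np_bounds(), seed = 1,
#'               control = list(maxiter = 150))
#' fit$params$r
#' }
#' @export
fit_np <- function(observations, bounds = default_np_bounds(), seed = 1,
                   fixed = c(alpha = 1, eta_u = 1), weights = NULL,
                   layout = NULL, m_B0 = 0, dt = 0.1, control = list()) {
  if (inherits(observations, "measurement_series"))
    observations <- as_np_observations(observations)
  if (!length(observations)) stop("no observations supplied")
  free_names <- names(bounds)
  lower <- vapply(bounds, `[`, numeric(1), 1L)
  upper <- vapply(bounds, `[`, numeric(1), 2L)
  if (any(lower > upper)) stop("infeasible bounds: lower > upper")
  all_fields <- c("r", "K", "alpha", "m_N0", "b_eta", "m_eta", "b_mu",
                  "m_mu", "eta_u")
  missing_fields <- setdiff(all_fields, c(free_names, names(fixed),
                                          c("alpha", "eta_u")))
  if (length(missing_fields))
    stop("parameters neither bounded nor fixed: ",
         paste(missing_fields, collapse = ", "))

  obj <- make_np_objective(observations, weights = weights, layout = layout,
                           m_B0 = m_B0, dt = dt)
  base_vals <- list(r = NA_real_, K = NA_real_, alpha = 1, m_N0 = NA_real_,
                    b_eta = NA_real_, m_eta = 0, b_mu = NA_real_, m_mu = 0,
                    eta_u = 1)
  base_vals[names(fixed)] <- as.list(fixed)
  ctrl <- list(pop_size = NULL, maxiter = 1000, F = c(0.5, 1), CR = 0.7,
               tol = 1e-8, polish = TRUE, log10 = c("r", "K", "m_N0"))
  ctrl[names(control)] <- control
  # scale parameters spanning orders of magnitude are searched on a log
  # scale (only where the lower bound is positive)
  logged <- which(free_names %in% ctrl$log10 & lower > 0)
  lower[logged] <- log10(lower[logged])
  upper[logged] <- log10(upper[logged])
  fn <- function(x) {
    x[logged] <- 10^x[logged]
    vals <- base_vals
    vals[free_names] <- x
    obj(vals)
  }
  de <- de_optim(fn, lower, upper, seed = seed, pop_size = ctrl$pop_size,
                 maxiter = ctrl$maxiter, F = ctrl$F, CR = ctrl$CR,
                 tol = ctrl$tol)
  best <- de
  if (isTRUE(ctrl$polish) && any(upper > lower)) {
    pol <- tryCatch(
      optim(de$par, fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value <= de$value)
      best <- list(par = pol$par, value = pol$value,
                   n_evals = de$n_evals + as.integer(pol$counts[1]),
                   converged = de$converged, iterations = de$iterations)
    else best$n_evals <- de$n_evals
  }
  par_nat <- best$par
  par_nat[logged] <- 10^par_nat[logged]
  params <- build_np_params(par_nat, free_names, fixed)
  obj <- np_objective(params, observations, weights = weights,
                      layout = layout, m_B0 = m_B0, dt = dt)
  structure(list(params = params, objective = as.numeric(obj),
                 bounds = bounds, n_evals = best$n_evals,
                 converged = best$converged,
                 per_target_residuals = attr(obj, "per_target"),
                 free = setNames(par_nat, free_names), seed = seed),
            class = "np_fit")
}

#' @export
print.np_fit <- function(x, ...) {
  cat(sprintf("<np_fit> objective = %.6g (%s, %d evaluations, seed %d)\n",
              x$objective,
              if (x$converged) "converged" else "not converged",
              x$n_evals, x$seed))
  print(x$params)
  invisible(x)
}

#' Fit the NP model to an MEC baseline growth curve
#'
#' Calibrates NP parameters against the biomass trajectory predicted by the
#' light/CO2-driven MEC model - no nitrogen or productivity observations
#' constrain the fit, so the nitrogen state is purely a latent driver
#' shaped to reproduce the MEC curve.  The NP per-plant output is converted
#' to the areal basis through the layout before comparison.
#'
#' Because only a biomass trajectory constrains these fits, the nitrogen
#' use efficiency / accumulation-rate split is unidentifiable (only the
#' product `eta_N * mu_N` matters), so the NUE intercept `b_eta` is pinned
#' at a representative 10 g_DW g_N^-1 by default and the remaining
#' parameters absorb the scale; supply `bounds` containing `b_eta` to free
#' it.
#'
#' @param mec_curve an areal-basis [growth_curve()] from [simulate_mec()].
#' @param layout a [cultivation_layout()].
#' @param bounds,seed,control as in [fit_np()].
#' @param fixed named values for parameters not in `bounds`.
#' @param n_obs number of (evenly subsampled) curve points used as
#'   observations.
#' @return an `np_fit` (see [fit_np()]) with an extra element `rel_rmse`:
#'   root-mean-square biomass error on the observation points divided by
#'   the final MEC biomass.
#' @export
fit_np_to_mec <- function(mec_curve, layout,
                          bounds = default_np_bounds()[
                            c("r", "K", "m_N0", "m_eta", "b_mu", "m_mu")],
                          seed = 1, control = list(),
                          fixed = c(alpha = 1, eta_u = 1, b_eta = 10),
                          n_obs = 60) {
  if (attr(mec_curve, "basis") != "areal")
    stop("mec_curve must be on the areal basis")
  idx <- unique(round(seq(1, nrow(mec_curve), length.out = n_obs)))
  obs <- list(biomass = data.frame(t = mec_curve$t_dae[idx],
                                   value = mec_curve$biomass_total[idx]))
  fit <- fit_np(obs, bounds = bounds, seed = seed, layout = layout,
                fixed = fixed, control = control)
  pred <- np_predict_channel("biomass", obs$biomass, fit$params, layout,
                             0, 0.1)
  final <- obs$biomass$value[length(obs$biomass$value)]
  fit$rel_rmse <- sqrt(mean((pred - obs$biomass$value)^2)) / final
  fit
}
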