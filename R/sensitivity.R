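#' Biomass area-under-curve quantity of interest
#'
#' Trapezoidal time integral of total biomass - a scalar summary of the
#' whole growth trajectory used as the quantity of interest (QoI) in the
#' sensitivity analysis.
#'
#' @param curve a [growth_curve()].
#' @return the integral \[g_DW d (m^-2)\]; a single-point curve returns 0
#'   with a warning.
#' @export
qoi_auc <- function(curve) {
  if (nrow(curve) < 2L) {
    warning("single-point curve: area under the curve is 0")
    return(0)
  }
  trapz(curve$t_dae, curve$biomass_total)
}

#' Uniform parameter sampling
#'
#' Independent uniform draws within a per-parameter box, reproducible under
#' a seed.
#'
#' @param bounds named list of `c(lower, upper)` vectors.
#' @param n number of samples.
#' @param seed integer seed.
#' @return an `n x d` matrix with one column per parameter.
#' @export
sample_uniform <- function(bounds, n, seed = 1) {
  lower <- vapply(bounds, `[`, numeric(1), 1L)
  upper <- vapply(bounds, `[`, numeric(1), 2L)
  if (any(lower > upper)) stop("infeasible bounds: lower > upper")
  set.seed(seed)
  m <- vapply(seq_along(bounds),
              function(j) runif(n, lower[j], upper[j]), numeric(n))
  m <- matrix(m, nrow = n)
  colnames(m) <- names(bounds)
  m
}

delta_raw <- function(p, q, n_bins, grid, bw) {
  ord <- order(p)
  n <- length(q)
  f_marg <- density(q, bw = bw, from = grid[1], to = grid[2], n = 512)
  bins <- split(ord, cut(seq_len(n), breaks = n_bins, labels = FALSE))
  acc <- 0
  for (b in bins) {
    if (length(b) < 2L) next
    f_c <- density(q[b], bw = bw, from = grid[1], to = grid[2], n = 512)
    tv <- 0.5 * trapz(f_marg$x, abs(f_c$y - f_marg$y))
    acc <- acc + (length(b) / n) * tv
  }
  acc
}

#' Moment-independent (Borgonovo) sensitivity indices
#'
#' For each parameter, the index is half the expected total-variation
#' distance between the unconditional QoI density and the QoI density
#' conditional on the parameter, estimated by equal-frequency partitioning
#' of the parameter into `n_bins` classes with Gaussian-kernel density
#' estimates sharing the full-sample bandwidth.  The kernel estimator has a
#' positive finite-sample bias, so by default a bootstrap bias reduction is
#' applied (`2 * delta_hat` minus the mean over `n_boot` resampled
#' replicates), and the result is clipped to \[0, 1\].  Rows are
#' canonicalized by QoI order before estimation, so the result is exactly
#' invariant under joint permutation of the sample rows.
#'
#' @param samples `n x d` parameter matrix (rows = model runs).
#' @param qoi_values length-`n` vector of QoI values, finite.
#' @param n_bins number of equal-frequency parameter classes.
#' @param n_boot bootstrap replicates for the bias reduction (0 disables
#'   it).
#' @param seed seed for the bootstrap replicates.
#' @return named vector of indices in \[0, 1\]; a constant QoI returns all
#'   zeros.
#' @examples
#' x <- sample_uniform(list(a = c(0, 1), b = c(0, 1)), 2000, seed = 2)
#' delta <- borgonovo_delta(x, x[, "a"]^2, seed = 2)
#' delta["a"] > delta["b"]
#' @export
borgonovo_delta <- function(samples, qoi_values, n_bins = 20, n_boot = 5,
                            seed = 1) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 200L) stop("need at least 200 samples")
  if (any(!is.finite(qoi_values))) stop("QoI values must be finite")
  d <- ncol(samples)
  nm <- colnames(samples) %||% paste0("p", seq_len(d))
  if (sd(qoi_values) == 0)
    return(setNames(rep(0, d), nm))
  # canonical row order: estimator invariant under joint row permutation
  ord <- do.call(order, c(list(qoi_values), lapply(seq_len(d),
                                                   function(j) samples[, j])))
  samples <- samples[ord, , drop = FALSE]
  qoi_values <- qoi_values[ord]
  bw <- stats::bw.nrd0(qoi_values)
  rng <- range(qoi_values)
  grid <- c(rng[1] - 3 * bw, rng[2] + 3 * bw)
  raw <- vapply(seq_len(d), function(j)
    delta_raw(samples[, j], qoi_values, n_bins, grid, bw), numeric(1))
  est <- raw
  if (n_boot > 0L) {
    set.seed(seed)
    boot <- matrix(0, n_boot, d)
    for (k in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      qb <- qoi_values[idx]
      bwb <- stats::bw.nrd0(qb)
      gridb <- c(min(qb) - 3 * bwb, max(qb) + 3 * bwb)
      boot[k, ] <- vapply(seq_len(d), function(j)
        delta_raw(samples[idx, j], qb, n_bins, gridb, bwb), numeric(1))
    }
    est <- 2 * raw - colMeans(boot)
  }
  setNames(pmin(1, pmax(0, est)), nm)
}

#' Train a physicality classifier
#'
#' Fits a probabilistic binary classifier (single-hidden-layer neural
#' network) predicting whether a parameter combination yields a physically
#' meaningful simulation.  Inputs are min-max standardized to the observed
#' column ranges before training.  If only one class is present, a constant
#' predictor is returned with a warning.
#'
#' @param samples `n x d` parameter matrix, `n >= 20`.
#' @param labels logical (or 0/1) vector: `TRUE` = physical.
#' @param seed integer seed (network initialisation is random).
#' @param size hidden units.
#' @param decay weight decay.
#' @param maxit training iterations.
#' @return an object of class `physicality_classifier`; use
#'   [predict_probability()] on it.
#' @export
train_physicality_classifier <- function(samples, labels, seed = 1,
                                         size = 6, decay = 0.01,
                                         maxit = 500) {
  samples <- as.matrix(samples)
  labels <- as.logical(labels)
  if (nrow(samples) < 20L) stop("need at least 20 labeled samples")
  lo <- apply(samples, 2L, min)
  hi <- apply(samples, 2L, max)
  span <- ifelse(hi > lo, hi - lo, 1)
  if (length(unique(labels)) < 2L) {
    warning("only one class present; returning a constant classifier")
    return(structure(list(constant = mean(labels), lo = lo, span = span),
                     class = "physicality_classifier"))
  }
  x <- sweep(sweep(samples, 2L, lo), 2L, span, "/")
  set.seed(seed)
  net <- nnet::nnet(x, as.numeric(labels), size = size, decay = decay,
                    maxit = maxit, entropy = TRUE, trace = FALSE)
  structure(list(net = net, lo = lo, span = span),
            class = "physicality_classifier")
}

#' Predicted probability that parameters are physical
#'
#' @param classifier a [train_physicality_classifier()] result.
#' @param samples parameter matrix (same column order as training).
#' @return vector of probabilities in \[0, 1\].
#' @export
predict_probability <- function(classifier, samples) {
  samples <- as.matrix(samples)
  if (!is.null(classifier$constant))
    return(rep(classifier$constant, nrow(samples)))
  x <- sweep(sweep(samples, 2L, classifier$lo), 2L, classifier$span, "/")
  as.numeric(predict(classifier$net, x))
}

#' Classifier-screened global sensitivity analysis
#'
#' The five-step accelerated procedure: (1) draw `n0` uniform samples and
#' simulate them, labelling each physical when its QoI (biomass integral)
#' is strictly positive; (2) train a probabilistic classifier on those
#' labels; (3) draw `n_star >> n0` candidate samples and keep those whose
#' predicted probability of physicality reaches `threshold`; (4) simulate
#' only the kept candidates; (5) pool every positive-QoI sample from both
#' stages and compute the Borgonovo indices.  As `threshold -> 0` the
#' screening degrades gracefully to plain unscreened sampling.
#'
#' @param simulator function mapping a named parameter vector to a scalar
#'   QoI.
#' @param bounds named list of `c(lower, upper)` boxes.
#' @param n0 initial simulation budget (order 100).
#' @param n_star candidate pool size, `>= n0`.
#' @param threshold classifier acceptance probability in (0, 1).
#' @param seed integer seed driving every stochastic stage.
#' @param n_bins,n_boot passed to [borgonovo_delta()].
#' @return an object of class `sensitivity_result`: `delta` (named index
#'   vector), sampling diagnostics `n0`, `n0_pos`, `n_star`, `n_star_pos`,
#'   `seed` and `qoi_name`.
#' @export
screened_gsa <- function(simulator, bounds, n0 = 200, n_star = 20000,
                         threshold = 0.5, seed = 1, n_bins = 20,
                         n_boot = 5) {
  if (n_star < n0) stop("require n_star >= n0")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  s0 <- sample_uniform(bounds, n0, seed = seed)
  q0 <- apply(s0, 1L, simulator)
  pos0 <- q0 > 0
  clf <- withCallingHandlers(
    train_physicality_classifier(s0, pos0, seed = seed),
    warning = function(w) invokeRestart("muffleWarning"))
  cand <- sample_uniform(bounds, n_star, seed = seed + 1L)
  keep <- predict_probability(clf, cand) >= threshold
  kept <- cand[keep, , drop = FALSE]
  qk <- if (nrow(kept)) apply(kept, 1L, simulator) else numeric(0)
  posk <- qk > 0
  samples <- rbind(s0[pos0, , drop = FALSE], kept[posk, , drop = FALSE])
  qoi <- c(q0[pos0], qk[posk])
  if (!length(qoi))
    stop("no physical samples after screening; widen the parameter bounds")
  structure(list(
    delta = borgonovo_delta(samples, qoi, n_bins = n_bins,
                            n_boot = n_boot, seed = seed),
    n0 = n0, n0_pos = sum(pos0),
    n_star = n_star, n_star_pos = as.integer(nrow(kept)),
    n_used = length(qoi), seed = seed,
    qoi_name = "biomass_auc"),
    class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> QoI = %s, seed %d\n", x$qoi_name, x$seed))
  cat(sprintf("  N0 = %d (physical %d), N* = %d (accepted %d), pooled %d\n",
              x$n0, x$n0_pos, x$n_star, x$n_star_pos, x$n_used))
  print(round(sort(x$delta, decreasing = TRUE), 4))
  invisible(x)
}

#' Parameter bounds from a collection of fits
#'
#' Elementwise minimum/maximum of the free-parameter vectors across fits
#' (e.g. the per-condition estimates), giving the uniform-prior box for the
#' sensitivity analysis.
#'
#' @param fits list of at least two [fit_np()] results with identical free
#'   parameter sets.
#' @return named list of `c(lower, upper)` vectors.
#' @export
bounds_from_fits <- function(fits) {
  if (length(fits) < 2L) stop("need at least 2 fits")
  nm <- names(fits[[1]]$free)
  for (f in fits)
    if (!identical(names(f$free), nm))
      stop("fits have inconsistent free parameter sets")
  mat <- do.call(rbind, lapply(fits, `[[`, "free"))
  setNames(lapply(nm, function(p) range(mat[, p])), nm)
}

#' Parameter bounds by relative perturbation around a nominal point
#'
#' `[p (1 - fraction), p (1 + fraction)]` per parameter, with the order
#' swapped for negative nominal values so lower <= upper always holds.
#'
#' @param nominal an [np_parameters()] object (or named numeric vector).
#' @param fraction relative half-width, > 0 (0.1 = +/- 10%).
#' @param params which parameters to perturb; defaults to all NP fields
#'   except `eta_u`.
#' @return named list of `c(lower, upper)` vectors.
#' @export
bounds_from_perturbation <- function(nominal, fraction = 0.1,
                                     params = c("r", "K", "alpha", "m_N0",
                                                "b_eta", "m_eta", "b_mu",
                                                "m_mu")) {
  if (fraction < 0) stop("fraction must be >= 0")
  vals <- unlist(unclass(nominal))[params]
  setNames(lapply(vals, function(p) sort(c(p * (1 - fraction),
                                           p * (1 + fraction)))),
           params)
}

#' QoI simulator factory for the NP model
#'
#' Builds the `simulator` closure used by [screened_gsa()]: a named
#' parameter vector overrides fields of `base`, the NP model is simulated
#' over `[0, t_max]` and the biomass area under the curve is returned.
#' Growth rates are deliberately *not* clamped here, so non-physical
#' parameter combinations can yield non-positive integrals and exercise
#' the screening.
#'
#' @param base an [np_parameters()] object supplying unvaried fields.
#' @param t_max simulation horizon \[d\].
#' @param dt grid step \[d\].
#' @return function: named numeric vector -> scalar QoI.
#' @export
np_auc_simulator <- function(base, t_max = 40, dt = 0.1) {
  grid <- seq(0, t_max, by = dt)
  function(p) {
    vals <- unclass(base)
    vals[names(p)] <- as.list(p)
    params <- tryCatch(do.call(np_parameters, vals),
                       error = function(e) NULL)
    if (is.null(params)) return(-Inf)
    rate <- nitrogen_productivity(grid, params) * nitrogen_mass(grid, params)
    trapz(grid, cumtrapz(grid, rate))
  }
}
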