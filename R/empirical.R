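#' Harvest measurement series
#'
#' Destructive-harvest records for one nitrogen condition: per-harvest
#' per-plant means and standard deviations of fresh weight, dry biomass and
#' the total-nitrogen fraction of fresh weight.  Plant nitrogen mass `m_N`
#' is derived as `fresh_weight * n_fraction_fw` when absent, and its
#' standard deviation `m_N_sd` by first-order propagation through that
#' product.
#'
#' @param records data frame with columns `t` \[d_AE, strictly increasing\],
#'   `n_plants`, `fresh_weight` \[g_FW\], `fw_sd`, `dry_biomass` \[g_DW\],
#'   `biomass_sd`, `n_fraction_fw` (dimensionless), `n_fraction_sd`, and
#'   optionally `m_N`, `m_N_sd`.
#' @param condition one of `"deficient"`, `"normal"`, `"excess"`, `"other"`.
#' @return an object of classes `measurement_series` and `data.frame`.
#' @export
measurement_series <- function(records,
                               condition = c("normal", "deficient",
                                             "excess", "other")) {
  condition <- match.arg(condition)
  need <- c("t", "n_plants", "fresh_weight", "fw_sd", "dry_biomass",
            "biomass_sd", "n_fraction_fw", "n_fraction_sd")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("measurement records missing column(s): ",
         paste(miss, collapse = ", "))
  records <- records[order(records$t), , drop = FALSE]
  if (any(diff(records$t) <= 0)) stop("t must be strictly increasing")
  if (any(records$fresh_weight < 0) || any(records$dry_biomass < 0))
    stop("masses must be >= 0")
  if (any(records$n_fraction_fw < 0) || any(records$n_fraction_fw > 1))
    stop("n_fraction_fw must lie in [0, 1]")
  if (is.null(records$m_N))
    records$m_N <- plant_nitrogen_mass(records$fresh_weight,
                                       records$n_fraction_fw)
  if (is.null(records$m_N_sd))
    records$m_N_sd <- sqrt((records$n_fraction_fw * records$fw_sd)^2 +
                             (records$fresh_weight * records$n_fraction_sd)^2)
  rownames(records) <- NULL
  structure(records, condition = condition,
            class = c("measurement_series", "data.frame"))
}

#' @export
print.measurement_series <- function(x, ...) {
  cat(sprintf("<measurement_series> condition = %s, %d harvests (%g-%g d_AE)\n",
              attr(x, "condition"), nrow(x), min(x$t), max(x$t)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Plant nitrogen mass from fresh weight and nitrogen fraction
#'
#' @param fresh_weight per-plant fresh weight \[g_FW\], >= 0.
#' @param n_fraction_fw total-nitrogen fraction of fresh weight
#'   (dimensionless, e.g. 0.0036 for 0.36%), >= 0.
#' @return nitrogen mass \[g_N\]: the product of the two inputs.
#' @examples
#' plant_nitrogen_mass(100, 0.0036)   # 0.36 g_N
#' @export
plant_nitrogen_mass <- function(fresh_weight, n_fraction_fw) {
  if (any(fresh_weight < 0) || any(n_fraction_fw < 0))
    stop("inputs must be >= 0")
  fresh_weight * n_fraction_fw
}

series_at <- function(series, t) {
  i <- match(t, series$t)
  if (is.na(i)) stop(sprintf("no harvest record at t = %g d_AE", t))
  series[i, , drop = FALSE]
}

#' Empirical nitrogen use efficiency over a harvest interval
#'
#' Dry biomass produced between two harvests per mean plant nitrogen mass
#' over the interval (two-point arithmetic mean):
#' `(m_B(t2) - m_B(t1)) / ((m_N(t1) + m_N(t2)) / 2)`.
#'
#' @param series a [measurement_series()].
#' @param t1,t2 harvest times \[d_AE\] present in the series, `t1 < t2`.
#' @return nitrogen use efficiency \[g_DW g_N^-1\].
#' @export
empirical_nue <- function(series, t1, t2) {
  if (t1 >= t2) stop("require t1 < t2")
  r1 <- series_at(series, t1); r2 <- series_at(series, t2)
  mbar <- (r1$m_N + r2$m_N) / 2
  if (mbar <= 0) stop("mean nitrogen mass over the interval is zero")
  (r2$dry_biomass - r1$dry_biomass) / mbar
}

#' Empirical relative nitrogen accumulation rate over a harvest interval
#'
#' Mean relative (logarithmic) rate of plant-nitrogen increase:
#' `(ln m_N(t2) - ln m_N(t1)) / (t2 - t1)`.
#'
#' @inheritParams empirical_nue
#' @return relative nitrogen accumulation rate \[d^-1\].
#' @export
empirical_rnar <- function(series, t1, t2) {
  if (t1 >= t2) stop("require t1 < t2")
  r1 <- series_at(series, t1); r2 <- series_at(series, t2)
  if (r1$m_N <= 0 || r2$m_N <= 0)
    stop("m_N must be > 0 at both harvests")
  (log(r2$m_N) - log(r1$m_N)) / (t2 - t1)
}

#' Interval series of empirical NUE / RNAR
#'
#' Applies [empirical_nue()] / [empirical_rnar()] to every consecutive
#' harvest pair, reporting values at interval midpoints.
#'
#' @param series a [measurement_series()] with at least 2 records.
#' @return data frame with columns `t_mid` and `value`.
#' @export
empirical_nue_series <- function(series) {
  pairwise_series(series, empirical_nue)
}

#' @rdname empirical_nue_series
#' @export
empirical_rnar_series <- function(series) {
  pairwise_series(series, empirical_rnar)
}

pairwise_series <- function(series, fun) {
  if (nrow(series) < 2L) stop("need at least 2 harvest records")
  t <- series$t
  data.frame(
    t_mid = (t[-1] + t[-length(t)]) / 2,
    value = vapply(seq_len(length(t) - 1L),
                   function(i) fun(series, t[i], t[i + 1L]), numeric(1)))
}

#' Empirical nitrogen productivity with propagated error
#'
#' For each consecutive harvest pair, the productivity
#' `Ydot_N = (dm_B/dt) / m_N` is estimated as the forward difference of dry
#' biomass over the interval divided by the interval-mean nitrogen mass,
#' reported at the interval midpoint.  The standard deviation is obtained
#' by first-order propagation of the stored per-plant standard deviations
#' of biomass and nitrogen mass through that expression.
#'
#' @param series a [measurement_series()] with at least 2 records.
#' @return data frame with columns `t_mid` \[d_AE\], `productivity`
#'   \[g_DW d^-1 g_N^-1\] and `propagated_sd`.
#' @export
empirical_productivity <- function(series) {
  if (nrow(series) < 2L) stop("need at least 2 harvest records")
  n <- nrow(series)
  i1 <- seq_len(n - 1L); i2 <- i1 + 1L
  dt <- series$t[i2] - series$t[i1]
  dmb <- series$dry_biomass[i2] - series$dry_biomass[i1]
  mbar <- (series$m_N[i1] + series$m_N[i2]) / 2
  if (any(mbar <= 0)) stop("interval-mean nitrogen mass must be > 0")
  y <- dmb / dt / mbar
  var_b <- (series$biomass_sd[i1]^2 + series$biomass_sd[i2]^2) / (dt * mbar)^2
  var_n <- (y / (2 * mbar))^2 * (series$m_N_sd[i1]^2 + series$m_N_sd[i2]^2)
  data.frame(t_mid = (series$t[i1] + series$t[i2]) / 2,
             productivity = y,
             propagated_sd = sqrt(var_b + var_n))
}

#' Condition-average nitrogen productivity
#'
#' Mean of the interval estimates from [empirical_productivity()] (each
#' interval weighted equally; pooling alternatives are a one-liner on the
#' returned interval table).
#'
#' @param series a [measurement_series()].
#' @return scalar mean productivity \[g_DW d^-1 g_N^-1\].
#' @export
mean_productivity <- function(series) {
  mean(empirical_productivity(series)$productivity)
}

#' Measurement CSV schema
#'
#' Column-name mapping used by [load_measurements()] /
#' [write_measurements()], making the loader tolerant to dataset dialects.
#' `time_basis = "d_AS"` converts sowing-based times to emergence-based by
#' subtracting `emergence_offset` (default 3 d, the lag between sowing and
#' emergence in the reference lettuce study).
#'
#' @param ... canonical = file column name overrides; canonical names are
#'   `condition, t, n_plants, fresh_weight, fw_sd, dry_biomass, biomass_sd,
#'   n_fraction_fw, n_fraction_sd, m_N, m_N_sd`.
#' @param time_basis `"d_AE"` (default) or `"d_AS"`.
#' @param emergence_offset days between sowing and emergence.
#' @return a named schema list.
#' @export
measurement_schema <- function(..., time_basis = c("d_AE", "d_AS"),
                               emergence_offset = 3) {
  cols <- list(condition = "condition", t = "t", n_plants = "n_plants",
               fresh_weight = "fresh_weight", fw_sd = "fw_sd",
               dry_biomass = "dry_biomass", biomass_sd = "biomass_sd",
               n_fraction_fw = "n_fraction_fw",
               n_fraction_sd = "n_fraction_sd",
               m_N = "m_N", m_N_sd = "m_N_sd")
  over <- list(...)
  cols[names(over)] <- over
  list(columns = cols, time_basis = match.arg(time_basis),
       emergence_offset = emergence_offset)
}

#' Load / write harvest measurement tables
#'
#' Reads a comma-separated UTF-8 table (header row) holding one row per
#' condition x harvest, mapped through a [measurement_schema()], and
#' returns one [measurement_series()] per condition.  Any columns not named
#' in the schema (e.g. nutrient-solution chemistry: nitrate/ammonium
#' concentrations, pH) are carried verbatim in an `aux` attribute for
#' plotting, never modelled.  Missing mandatory columns raise an error
#' naming the column.
#'
#' @param path CSV file path.
#' @param schema a [measurement_schema()].
#' @return `load_measurements()`: named list of [measurement_series()];
#'   `write_measurements()`: the path, invisibly.
#' @export
load_measurements <- function(path, schema = measurement_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("schema error: file has no data rows")
  cols <- schema$columns
  mandatory <- setdiff(names(cols), c("m_N", "m_N_sd"))
  for (canon in mandatory) {
    if (!cols[[canon]] %in% names(df))
      stop(sprintf("schema error: missing column '%s' (expected for '%s')",
                   cols[[canon]], canon))
  }
  keep <- intersect(unlist(cols), names(df))
  aux <- df[, setdiff(names(df), keep), drop = FALSE]
  out <- df[, keep, drop = FALSE]
  names(out) <- names(cols)[match(keep, unlist(cols))]
  if (schema$time_basis == "d_AS")
    out$t <- out$t - schema$emergence_offset
  split_idx <- split(seq_len(nrow(out)), out$condition)
  res <- lapply(names(split_idx), function(cond) {
    rows <- split_idx[[cond]]
    s <- measurement_series(out[rows, setdiff(names(out), "condition")],
                            condition = if (cond %in% c("deficient", "normal",
                                                        "excess")) cond
                                        else "other")
    attr(s, "aux") <- aux[rows, , drop = FALSE]
    s
  })
  names(res) <- names(split_idx)
  res
}

#' @rdname load_measurements
#' @param series_list named list of [measurement_series()] (or a single
#'   series).
#' @export
write_measurements <- function(series_list, path) {
  if (inherits(series_list, "measurement_series"))
    series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    cbind(condition = attr(s, "condition"), as.data.frame(s))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
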