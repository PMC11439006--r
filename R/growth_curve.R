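#' Growth-curve container
#'
#' A time-indexed biomass trajectory.  Stored as a data frame with columns
#' `t_dae` (days after emergence, strictly increasing), `biomass_total`,
#' `biomass_edible`, `growth_rate` and `carbon_gain`, plus a `basis`
#' attribute declaring whether the mass channels are areal
#' \[g_DW m^-2\] or per-plant \[g_DW\].  The basis is always explicit, never
#' inferred from magnitudes.
#'
#' @param times strictly increasing time grid \[d_AE\].
#' @param biomass_total cumulative dry biomass.
#' @param biomass_edible cumulative edible dry biomass.
#' @param growth_rate instantaneous biomass growth rate \[g_DW d^-1 (m^-2)\].
#' @param carbon_gain daily carbon gain \[mol_C d^-1 m^-2\] (`NA` for models
#'   that do not resolve carbon).
#' @param basis `"areal"` or `"per-plant"`.
#' @param limiting_model optional per-step limiting-model labels (hybrid
#'   simulations).
#' @return an object of classes `growth_curve` and `data.frame`.
#' @export
growth_curve <- function(times, biomass_total, biomass_edible, growth_rate,
                         carbon_gain = NA_real_,
                         basis = c("areal", "per-plant"),
                         limiting_model = NULL) {
  basis <- match.arg(basis)
  n <- length(times)
  stopifnot(length(biomass_total) == n, length(biomass_edible) == n,
            length(growth_rate) == n)
  if (n > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  tol <- 1e-9 * max(1, abs(biomass_total), na.rm = TRUE)
  if (any(biomass_edible > biomass_total + tol, na.rm = TRUE))
    stop("biomass_edible must not exceed biomass_total")
  df <- data.frame(t_dae = times, biomass_total = biomass_total,
                   biomass_edible = biomass_edible,
                   growth_rate = growth_rate,
                   carbon_gain = rep_len(carbon_gain, n))
  if (!is.null(limiting_model)) df$limiting_model <- limiting_model
  structure(df, basis = basis, class = c("growth_curve", "data.frame"))
}

#' @export
print.growth_curve <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<growth_curve> basis = %s, %d points over [%g, %g] d_AE\n",
              attr(x, "basis"), n, x$t_dae[1], x$t_dae[n]))
  cat(sprintf("  final biomass: total %.4g, edible %.4g %s\n",
              x$biomass_total[n], x$biomass_edible[n],
              if (attr(x, "basis") == "areal") "g_DW m^-2" else "g_DW"))
  invisible(x)
}

#' Curve basis accessor
#' @param curve a [growth_curve()].
#' @return `"areal"` or `"per-plant"`.
#' @export
curve_basis <- function(curve) attr(curve, "basis")

#' Write / read a growth curve as CSV
#'
#' Columns `t_dae, biomass_total, biomass_edible, growth_rate, carbon_gain`
#' (plus `limiting_model` for hybrid curves); the basis is stored in a
#' leading `#` comment line.
#'
#' @param curve a [growth_curve()].
#' @param path file path.
#' @return `write_growth_curve()` returns `path` invisibly;
#'   `read_growth_curve()` returns a [growth_curve()].
#' @export
write_growth_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# basis: %s", attr(curve, "basis")), con)
  write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_growth_curve
#' @export
read_growth_curve <- function(path) {
  first <- readLines(path, n = 1L)
  basis <- if (grepl("per-plant", first)) "per-plant" else "areal"
  df <- read.csv(path, comment.char = "#")
  growth_curve(df$t_dae, df$biomass_total, df$biomass_edible,
               df$growth_rate, df$carbon_gain %||% NA_real_, basis = basis,
               limiting_model = df$limiting_model)
}
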