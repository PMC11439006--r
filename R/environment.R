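#' Growth-environment settings
#'
#' Bundles the environmental drivers of the MEC model: incident
#' photosynthetic photon flux (PPF), atmospheric CO2 concentration and the
#' photoperiod, plus the set-point temperatures and relative humidity which
#' are carried for record-keeping (the biomass model assumes they are not
#' growth limiting).
#'
#' @param ppf photosynthetic photon flux at the canopy
#'   \[umol photons m^-2 s^-1\], >= 0.
#' @param co2 atmospheric CO2 concentration \[umol mol^-1, i.e. ppm\], >= 0.
#' @param photoperiod light hours per day \[h d^-1\], in \[0, 24\].
#' @param temp_light,temp_dark light/dark cycle air temperatures \[deg C\].
#' @param rel_humidity relative humidity, dimensionless in \[0, 1\].
#' @return an object of class `environment_state`.
#' @examples
#' environment_state(ppf = 225, co2 = 525, photoperiod = 16)
#' @export
environment_state <- function(ppf, co2, photoperiod = 16,
                              temp_light = 22, temp_dark = 22,
                              rel_humidity = 0.5) {
  stopifnot(is.numeric(ppf), length(ppf) == 1L,
            is.numeric(co2), length(co2) == 1L)
  if (ppf < 0) stop("ppf must be >= 0")
  if (co2 < 0) stop("co2 must be >= 0")
  if (photoperiod < 0 || photoperiod > 24)
    stop("photoperiod must lie in [0, 24] h d^-1")
  if (rel_humidity < 0 || rel_humidity > 1)
    stop("rel_humidity must lie in [0, 1]")
  structure(list(ppf = ppf, co2 = co2, photoperiod = photoperiod,
                 temp_light = temp_light, temp_dark = temp_dark,
                 rel_humidity = rel_humidity),
            class = "environment_state")
}

#' @export
print.environment_state <- function(x, ...) {
  cat("<environment_state>\n")
  cat(sprintf("  PPF         %g umol m^-2 s^-1\n", x$ppf))
  cat(sprintf("  CO2         %g ppm\n", x$co2))
  cat(sprintf("  photoperiod %g h d^-1\n", x$photoperiod))
  cat(sprintf("  T light/dark %g/%g degC, RH %g\n",
              x$temp_light, x$temp_dark, x$rel_humidity))
  invisible(x)
}

#' Cultivation layout
#'
#' Areal numeric planting density and the fresh-weight water fraction used to
#' convert per-plant dry-weight model output to areal and fresh-weight bases.
#'
#' @param sigma_N areal numeric planting density \[plants m^-2\], > 0.
#' @param water_fraction fresh-weight water fraction, in \[0, 1).
#' @return an object of class `cultivation_layout`.
#' @examples
#' cultivation_layout()          # lettuce reference: 19.2 m^-2, 0.95
#' @export
cultivation_layout <- function(sigma_N = 19.2, water_fraction = 0.95) {
  if (!is.numeric(sigma_N) || sigma_N <= 0) stop("sigma_N must be > 0")
  if (water_fraction < 0 || water_fraction >= 1)
    stop("water_fraction must lie in [0, 1)")
  structure(list(sigma_N = sigma_N, water_fraction = water_fraction),
            class = "cultivation_layout")
}

#' @export
print.cultivation_layout <- function(x, ...) {
  cat(sprintf("<cultivation_layout> sigma_N = %g m^-2, water fraction = %g\n",
              x$sigma_N, x$water_fraction))
  invisible(x)
}

#' Fresh weight from dry weight
#'
#' @param m_dw dry mass \[g_DW\].
#' @param water_fraction fresh-weight water fraction in \[0, 1).
#' @return fresh mass \[g_FW\]: `m_dw / (1 - water_fraction)`.
#' @examples
#' fresh_weight(1, 0.95)   # 20 g
#' @export
fresh_weight <- function(m_dw, water_fraction) {
  if (any(water_fraction >= 1) || any(water_fraction < 0))
    stop("water_fraction must lie in [0, 1)")
  m_dw / (1 - water_fraction)
}
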