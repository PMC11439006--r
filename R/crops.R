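#' Crop parameter sets for the MEC model
#'
#' Nine reference crops are bundled with the package (dry bean, lettuce,
#' rice, soybean, tomato, wheat, peanut, sweet potato, white potato).  Each
#' crop file stores the developmental time points (canopy closure `t_A`,
#' senescence onset `t_Q`, organ-formation onset `t_E`, maturity `t_M`, all
#' in days after emergence), the edible carbon allocation fraction `f_E`,
#' the biomass carbon fraction `w_C`, the 24-h carbon use efficiency
#' (`cue_max`, with an optional terminal `cue_min` for crops whose carbon
#' use efficiency declines after `t_Q`), the canopy absorption parameters
#' (`a_max`, growth exponent `a_exponent`), and the canopy quantum yield
#' response surface as a 5 x 5 coefficient matrix over the basis
#' `[1/PPF, 1, PPF, PPF^2, PPF^3] x [1/CO2, 1, CO2, CO2^2, CO2^3]`, with an
#' optional terminal fraction `cqy_min` for post-senescence decline and a
#' documented validity box in (PPF, CO2).
#'
#' The bundled coefficient files are a *synthetic calibration*: the
#' functional forms are the canonical energy-cascade ones, but the
#' response-surface coefficients were constructed from a hyperbolic CO2
#' saturation and a linear high-light attenuation anchored to plausible
#' nominal canopy quantum yields, because the original coefficient tables
#' are not reproduced here.  The files are named `<crop>_synthetic.json`
#' to make this provenance explicit; users with the original tables can
#' supply their own file to [mec_crop()].
#'
#' @param crop a crop identifier (see [mec_crops()]) or a path to a crop
#'   parameter JSON file.
#' @return `mec_crop()` returns an object of class `mec_crop`;
#'   `mec_crops()` returns the character vector of bundled crop ids.
#' @examples
#' mec_crops()
#' lettuce <- mec_crop("lettuce")
#' lettuce$t_M
#' @export
mec_crop <- function(crop) {
  stopifnot(is.character(crop), length(crop) == 1L)
  if (file.exists(crop)) {
    path <- crop
  } else {
    if (!crop %in% mec_crops())
      stop(sprintf("unknown crop '%s'; valid ids: %s", crop,
                   paste(mec_crops(), collapse = ", ")))
    path <- system.file("extdata", "crops",
                        paste0(gsub(" ", "_", crop), "_synthetic.json"),
                        package = "cropnp", mustWork = TRUE)
  }
  as_mec_crop(jsonlite::fromJSON(path, simplifyMatrix = TRUE))
}

#' @rdname mec_crop
#' @export
mec_crops <- function() {
  c("dry bean", "lettuce", "rice", "soybean", "tomato",
    "wheat", "peanut", "sweet potato", "white potato")
}

#' Construct an MEC crop parameter set programmatically
#'
#' Mostly useful for tests and for hypothetical crops; bundled crops should
#' be loaded with [mec_crop()].
#'
#' @param crop_id crop label.
#' @param t_A,t_Q,t_E,t_M developmental time points \[d_AE\].
#' @param f_E edible carbon allocation fraction after `t_E`, in \[0, 1\].
#' @param w_C biomass carbon mass fraction \[g_C g_DW^-1\], in (0, 1).
#' @param cue_max,cue_min 24-h carbon use efficiency plateau and (optional)
#'   terminal value after the post-`t_Q` linear decline.
#' @param a_max asymptotic canopy absorption fraction, in (0, 1\].
#' @param a_exponent canopy-closure power-law exponent.
#' @param cqy_coeffs 5 x 5 canopy quantum yield coefficient matrix (see
#'   [mec_crop()] for the basis convention).
#' @param cqy_min optional terminal canopy quantum yield fraction after
#'   `t_Q` (1 = no decline).
#' @param ppf_range,co2_range validity box of the response surface.
#' @param m_molar_C molar mass of carbon \[g mol^-1\].
#' @return an object of class `mec_crop`.
#' @export
mec_crop_parameters <- function(crop_id, t_A, t_Q, t_E, t_M, f_E, w_C,
                                cue_max, cue_min = NULL,
                                a_max = 0.93, a_exponent = 2,
                                cqy_coeffs, cqy_min = NULL,
                                ppf_range = c(50, 1000),
                                co2_range = c(330, 1300),
                                m_molar_C = 12.011) {
  as_mec_crop(list(
    crop_id = crop_id, t_A = t_A, t_Q = t_Q, t_E = t_E, t_M = t_M,
    f_E = f_E, w_C = w_C, cue_max = cue_max, cue_min = cue_min,
    a_max = a_max, a_exponent = a_exponent,
    cqy_coeffs = cqy_coeffs, cqy_min = cqy_min,
    ppf_range = ppf_range, co2_range = co2_range, m_molar_C = m_molar_C))
}

as_mec_crop <- function(x) {
  need <- c("crop_id", "t_A", "t_Q", "t_E", "t_M", "f_E", "w_C",
            "cue_max", "a_max", "a_exponent", "cqy_coeffs")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("crop parameter set is missing field(s): ",
         paste(miss, collapse = ", "))
  x$cqy_coeffs <- matrix(as.numeric(unlist(x$cqy_coeffs)), 5, 5,
                         byrow = is.list(x$cqy_coeffs))
  if (!is.null(x$cue_min) && !length(x$cue_min)) x$cue_min <- NULL
  if (!is.null(x$cqy_min) && !length(x$cqy_min)) x$cqy_min <- NULL
  x$m_molar_C <- x$m_molar_C %||% 12.011
  x$ppf_range <- as.numeric(x$ppf_range %||% c(50, 1000))
  x$co2_range <- as.numeric(x$co2_range %||% c(330, 1300))
  with(x, {
    if (!(t_A > 0 && t_A <= t_M)) stop("require 0 < t_A <= t_M")
    if (t_E > t_M) stop("require t_E <= t_M")
    if (f_E < 0 || f_E > 1) stop("require 0 <= f_E <= 1")
    if (w_C <= 0 || w_C >= 1) stop("require 0 < w_C < 1")
    if (cue_max <= 0 || cue_max > 1) stop("require 0 < cue_max <= 1")
    if (a_max <= 0 || a_max > 1) stop("require 0 < a_max <= 1")
  })
  structure(x, class = "mec_crop")
}

#' @export
print.mec_crop <- function(x, ...) {
  cat(sprintf("<mec_crop> %s\n", x$crop_id))
  cat(sprintf("  t_A %g, t_Q %g, t_E %g, t_M %g d_AE\n",
              x$t_A, x$t_Q, x$t_E, x$t_M))
  cat(sprintf("  f_E %g, w_C %g, CUE %g%s, A_max %g (n = %g)\n",
              x$f_E, x$w_C, x$cue_max,
              if (is.null(x$cue_min)) "" else sprintf(" -> %g", x$cue_min),
              x$a_max, x$a_exponent))
  invisible(x)
}
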