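#' Physical constants for Boltzmann temperature scaling
#'
#' Bundles the constants used throughout the package: the Boltzmann constant
#' in electron-volt units, the oxygen mass-to-molar conversion factor, and an
#' optional reference temperature for Arrhenius centering.
#'
#' @param k Boltzmann constant, eV K^-1.
#' @param z Oxygen unit conversion, micromol O2 per mg O2.
#' @param t_c Reference temperature in Kelvin, or `NULL` to defer the choice
#'   (downstream code then centers on the grand mean of the observed
#'   temperatures).
#' @return An object of class `phys_constants`.
#' @examples
#' phys_constants()
#' @export
phys_constants <- function(k = 8.617e-5, z = 31.25, t_c = NULL) {
  stopifnot(is.numeric(k), length(k) == 1L, k > 0,
            is.numeric(z), length(z) == 1L, z > 0)
  if (!is.null(t_c)) {
    stopifnot(is.numeric(t_c), length(t_c) == 1L, t_c > 0)
  }
  structure(list(k = k, z = z, t_c = t_c), class = "phys_constants")
}

#' @export
print.phys_constants <- function(x, ...) {
  cat("Physical constants:\n")
  cat(sprintf("  k   = %.4g eV/K (Boltzmann)\n", x$k))
  cat(sprintf("  z   = %.4g umol O2 / mg O2\n", x$z))
  if (is.null(x$t_c)) {
    cat("  T_c = (grand mean of observed temperatures)\n")
  } else {
    cat(sprintf("  T_c = %.2f K\n", x$t_c))
  }
  invisible(x)
}

#' Temperature unit helpers
#'
#' Temperatures cross the I/O boundary in degrees Celsius (how field probes
#' report them) but every thermodynamic expression inside the package works
#' in Kelvin.
#'
#' @param temp_c Temperature in degrees Celsius.
#' @param temp_k Temperature in Kelvin.
#' @return Converted temperature.
#' @export
celsius_to_kelvin <- function(temp_c) temp_c + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(temp_k) temp_k - 273.15

#' Inverse thermal energy 1/kT
#'
#' The Boltzmann inverse-temperature transform used as the covariate in all
#' Arrhenius-type regressions: a rate proportional to `exp(-E/kT)` is
#' ln-linear in `1/kT` with slope `-E`.
#'
#' @param temp_k Temperature in Kelvin; must be positive.
#' @param constants A [phys_constants()] object.
#' @return Inverse thermal energy in eV^-1. Strictly decreasing in
#'   temperature.
#' @examples
#' inv_kT(293.15) # about 39.59 eV^-1
#' @export
inv_kT <- function(temp_k, constants = phys_constants()) {
  if (any(!is.finite(temp_k)) || any(temp_k <= 0)) {
    stop("`temp_k` must be positive and finite (Kelvin)", call. = FALSE)
  }
  1 / (constants$k * temp_k)
}

#' Arrhenius temperature factor relative to a reference temperature
#'
#' Evaluates `exp(-E * (1/kT - 1/kT_c))`, the multiplier by which a rate with
#' apparent activation energy `E` changes between the reference temperature
#' `t_c` and the observation temperature. Equal to 1 at `T = T_c` and for
#' `E = 0`.
#'
#' @param temp_k Observation temperature, Kelvin.
#' @param t_c Reference temperature, Kelvin.
#' @param e Activation energy in eV. Positive values mean the rate increases
#'   with temperature.
#' @param constants A [phys_constants()] object.
#' @return Dimensionless multiplier.
#' @export
arrhenius_factor <- function(temp_k, t_c, e, constants = phys_constants()) {
  exp(-e * (inv_kT(temp_k, constants) - inv_kT(t_c, constants)))
}

#' Activation energy sign convention
#'
#' One place owns the mapping between fitted regression slopes on `1/kT` and
#' reported temperature dependences, so signs stay consistent everywhere.
#'
#' For metabolic rates and biomass modelled as `ln(Y) ~ slope * (1/kT)`, the
#' apparent activation energy is `E = -slope`: a rate that speeds up with
#' warming has a negative slope on inverse temperature and hence positive
#' `E`. For zooplankton densities the field convention reports the decline
#' coefficient itself (a density falling with warming has a positive slope on
#' `1/kT`, reported as a positive `E`); use `convention = "density"` for
#' that reading.
#'
#' @param slope Fitted coefficient on the `1/kT` covariate (eV).
#' @param convention `"rate"` (default, `E = -slope`) or `"density"`
#'   (`E = slope`).
#' @return Activation energy in eV.
#' @export
activation_energy <- function(slope, convention = c("rate", "density")) {
  convention <- match.arg(convention)
  if (convention == "rate") -slope else slope
}
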