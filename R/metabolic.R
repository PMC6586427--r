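#' Metabolic scaling parameters
#'
#' Parameters of the Boltzmann-Arrhenius description of a metabolic rate:
#' normalization constant at the reference temperature, apparent activation
#' energy, and allometric mass exponent.
#'
#' @param b0 Normalization constant at the reference temperature
#'   (gO2 g^-alpha h^-1); must be positive.
#' @param e Activation energy in eV. May be negative for responses that
#'   decline with warming.
#' @param alpha Allometric scaling exponent, typically in (0, 1].
#' @return An object of class `metabolic_params`.
#' @export
metabolic_params <- function(b0 = 1, e = 0.65, alpha = 0.75) {
  stopifnot(is.numeric(b0), length(b0) == 1L, b0 > 0,
            is.numeric(e), length(e) == 1L, is.finite(e),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  structure(list(b0 = b0, e = e, alpha = alpha), class = "metabolic_params")
}

#' Community state: body masses, volume, and mass-corrected biomass
#'
#' Summarises a community of `J` individuals in an ecosystem of volume `V`:
#' total biomass density `M_B = sum(m_i)/V` and the mass-corrected average
#' `<m^(alpha-1)> = sum(m_i^alpha) / sum(m_i)`, which adjusts total biomass
#' for the disproportionate metabolic contribution of small individuals.
#'
#' @param masses Individual body masses in grams; all positive. May be empty
#'   (an azoic ecosystem), in which case biomass is zero.
#' @param volume Ecosystem volume in litres.
#' @param alpha Allometric exponent used for the mass correction.
#' @return An object of class `community_state` with fields `masses`,
#'   `volume`, `n`, `m_b` (g/L), and `mass_corr`.
#' @export
community_state <- function(masses, volume = 1, alpha = 0.75) {
  stopifnot(is.numeric(masses), is.numeric(volume), volume > 0)
  if (length(masses) > 0 && any(masses <= 0)) {
    stop("all body masses must be positive", call. = FALSE)
  }
  mc <- if (length(masses) == 0) NA_real_ else mass_corrected_average(masses, alpha)
  structure(
    list(masses = masses, volume = volume, n = length(masses),
         m_b = sum(masses) / volume, mass_corr = mc, alpha = alpha),
    class = "community_state"
  )
}

#' Mass-corrected average metabolic biomass
#'
#' Computes `<m^(alpha-1)> = sum(m^alpha) / sum(m)`. Equals 1 when
#' `alpha = 1` and `m^(alpha-1)` for a single individual; scaling all masses
#' by `c` multiplies the result by `c^(alpha-1)`.
#'
#' @param masses Positive body masses (g); non-empty.
#' @param alpha Allometric exponent.
#' @return Dimensionless (times g^(alpha-1)) correction factor.
#' @export
mass_corrected_average <- function(masses, alpha) {
  if (length(masses) == 0) stop("`masses` must be non-empty", call. = FALSE)
  if (any(masses <= 0)) stop("all body masses must be positive", call. = FALSE)
  sum(masses^alpha) / sum(masses)
}

#' Per-capita metabolic rate
#'
#' The individual-level Boltzmann-Arrhenius rate
#' `b_i = b0 * exp(-E/kT) * m^alpha`.
#'
#' @param m Body mass in grams; positive.
#' @param temp_k Body temperature, Kelvin.
#' @param params A [metabolic_params()] object.
#' @param constants A [phys_constants()] object.
#' @return Rate in gO2 h^-1.
#' @export
percapita_rate <- function(m, temp_k, params, constants = phys_constants()) {
  if (any(m <= 0)) stop("body mass must be positive", call. = FALSE)
  params$b0 * exp(-params$e * inv_kT(temp_k, constants)) * m^params$alpha
}

#' Ecosystem-scale metabolic rate
#'
#' Aggregates per-capita rates over a community:
#' `B_R = b0(T_c) * exp(-E * (1/kT - 1/kT_c)) * M_B * <m^(alpha-1)>`,
#' on a per-unit-volume basis. The Arrhenius factor is centered on the
#' reference temperature so `b0` is the rate normalization at `T_c`.
#'
#' @param state A [community_state()] object.
#' @param temp_k Ecosystem temperature, Kelvin.
#' @param params A [metabolic_params()] object (its `e` is the apparent
#'   activation energy of the ecosystem rate).
#' @param constants A [phys_constants()] object whose `t_c` must be set.
#' @return Volumetric rate in gO2 L^-1 h^-1. An empty community returns 0
#'   with a warning.
#' @export
ecosystem_rate <- function(state, temp_k, params, constants) {
  stopifnot(inherits(state, "community_state"))
  if (is.null(constants$t_c)) {
    stop("`constants$t_c` (reference temperature) must be set", call. = FALSE)
  }
  if (state$n == 0) {
    warning("empty community: ecosystem rate is 0")
    return(0)
  }
  params$b0 * arrhenius_factor(temp_k, constants$t_c, params$e, constants) *
    state$m_b * state$mass_corr
}

#' Invert an ecosystem rate to total biomass
#'
#' Algebraic inverse of [ecosystem_rate()]:
#' `M_B = B_R * exp(E * (1/kT - 1/kT_c)) / (b0 * <m^(alpha-1)>)`.
#' Round-tripping `M_B -> B_R -> M_B` reproduces the input to machine
#' precision.
#'
#' @param b_r Ecosystem rate, gO2 L^-1 h^-1.
#' @param temp_k Ecosystem temperature, Kelvin.
#' @param params A [metabolic_params()] object.
#' @param mass_corr Mass-corrected average `<m^(alpha-1)>`; positive.
#' @param constants A [phys_constants()] object with `t_c` set.
#' @return Biomass density in g L^-1.
#' @export
biomass_from_rate <- function(b_r, temp_k, params, mass_corr, constants) {
  if (is.null(constants$t_c)) {
    stop("`constants$t_c` (reference temperature) must be set", call. = FALSE)
  }
  if (params$b0 <= 0 || mass_corr <= 0) {
    stop("`b0` and `mass_corr` must be positive (zero divisor)", call. = FALSE)
  }
  b_r / (params$b0 *
           arrhenius_factor(temp_k, constants$t_c, params$e, constants) *
           mass_corr)
}

#' Trophic-cascade theory parameters
#'
#' Treatment-specific normalization constants and mass corrections for the
#' grazer-only (AG) and grazer-plus-predator (AGP) communities, together with
#' the temperature dependences of those terms. The "first-order" metabolic
#' scaling null sets all four `E` terms to zero, predicting a
#' temperature-independent cascade.
#'
#' @param b0_ag,b0_agp Normalization constants; positive.
#' @param masscorr_ag,masscorr_agp Mass-corrected averages; positive.
#' @param e_b_ag,e_b_agp Temperature dependences (eV) of the normalization
#'   constants.
#' @param e_m_ag,e_m_agp Temperature dependences (eV) of the mass terms.
#' @return An object of class `cascade_theory_params`.
#' @export
cascade_theory_params <- function(b0_ag = 1, b0_agp = 1,
                                  masscorr_ag = 1, masscorr_agp = 1,
                                  e_b_ag = 0, e_b_agp = 0,
                                  e_m_ag = 0, e_m_agp = 0) {
  stopifnot(b0_ag > 0, b0_agp > 0, masscorr_ag > 0, masscorr_agp > 0)
  structure(
    list(b0_ag = b0_ag, b0_agp = b0_agp,
         masscorr_ag = masscorr_ag, masscorr_agp = masscorr_agp,
         e_b_ag = e_b_ag, e_b_agp = e_b_agp,
         e_m_ag = e_m_ag, e_m_agp = e_m_agp),
    class = "cascade_theory_params"
  )
}

#' Theoretical log trophic-cascade ratio
#'
#' The expected log ratio of producer biomass with versus without predators,
#' expressed through treatment-specific normalization and mass terms and
#' their temperature dependences:
#' the AG row `ln(b0_ag) + ln(<m^(a-1)>_ag) - (E_b.ag + E_m.ag)/kT` minus the
#' corresponding AGP row. Antisymmetric under swapping the AG and AGP
#' parameter sets, and independent of temperature when all four `E` terms
#' are zero.
#'
#' @param theta A [cascade_theory_params()] object.
#' @param temp_k Temperature, Kelvin.
#' @param constants A [phys_constants()] object.
#' @return Dimensionless log ratio.
#' @export
cascade_theory_lnratio <- function(theta, temp_k,
                                   constants = phys_constants()) {
  stopifnot(inherits(theta, "cascade_theory_params"))
  x <- inv_kT(temp_k, constants)
  row_ag <- log(theta$b0_ag) + log(theta$masscorr_ag) -
    (theta$e_b_ag + theta$e_m_ag) * x
  row_agp <- log(theta$b0_agp) + log(theta$masscorr_agp) -
    (theta$e_b_agp + theta$e_m_agp) * x
  row_ag - row_agp
}
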