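#' Equilibrium (saturation) dissolved-oxygen concentration
#'
#' Oxygen concentration fresh water would hold at equilibrium with the
#' atmosphere at a given temperature. The default `"standard"` mode uses the
#' saturation form `exp(a - b * ln(T + 45.93))` with `a = 7.7117` and
#' `b = 1.31403`, which gives the expected decrease of roughly 1 mg/L per
#' 5 degrees C of warming near 20 C and is strictly decreasing in
#' temperature. A `"literal"` mode evaluates
#' `exp(o2_water - o2_sat * ln(T + 45.93))` with user-supplied terms; it is
#' retained purely for auditability of the correction (the printed form is
#' dimensionally incoherent for typical inputs) and is never the default.
#'
#' @param temp_c Water temperature in degrees Celsius; must exceed -45.93.
#' @param mode `"standard"` or `"literal"`.
#' @param a,b Coefficients of the standard saturation form.
#' @param o2_water,o2_sat Terms of the literal form (required when
#'   `mode = "literal"`).
#' @return Equilibrium oxygen concentration in mg/L.
#' @examples
#' equilibrium_oxygen(20) # about 9.09 mg/L
#' equilibrium_oxygen(25) # about 8.26 mg/L
#' @export
equilibrium_oxygen <- function(temp_c, mode = c("standard", "literal"),
                               a = 7.7117, b = 1.31403,
                               o2_water = NULL, o2_sat = NULL) {
  mode <- match.arg(mode)
  if (any(temp_c <= -45.93, na.rm = TRUE)) {
    stop("`temp_c` must exceed -45.93 C", call. = FALSE)
  }
  if (mode == "standard") {
    exp(a - b * log(temp_c + 45.93))
  } else {
    if (is.null(o2_water) || is.null(o2_sat)) {
      stop("literal mode requires `o2_water` and `o2_sat`", call. = FALSE)
    }
    exp(o2_water - o2_sat * log(temp_c + 45.93))
  }
}

#' Convert oxygen mass concentration to molar concentration
#'
#' @param x Oxygen concentration in mg/L.
#' @param constants A [phys_constants()] object supplying the conversion
#'   factor `z` (micromol per mg; 31.25 for O2).
#' @return Concentration in micromol/L.
#' @examples
#' mg_to_umol(1) # 31.25
#' @export
mg_to_umol <- function(x, constants = phys_constants()) {
  x * constants$z
}

#' Diel dissolved-oxygen series
#'
#' Validates and assembles the nine fields describing one dawn/dusk/dawn
#' oxygen profile. Vectorised: each argument may be a vector, giving one
#' series per element. Times are decimal hours; the second dawn belongs to
#' the following day, so `t_dawn2` is usually `t_dawn + 24`.
#'
#' @param o2_dawn,o2_dusk,o2_dawn2 Dissolved oxygen readings, mg/L
#'   (non-negative).
#' @param temp_dawn,temp_dusk,temp_dawn2 Water temperature at each reading,
#'   degrees Celsius (plausible range 0-45).
#' @param t_dawn,t_dusk,t_dawn2 Observation times in decimal hours; must be
#'   strictly increasing within a series.
#' @return A data frame of class `diel_series`.
#' @export
diel_series <- function(o2_dawn, o2_dusk, o2_dawn2,
                        temp_dawn, temp_dusk, temp_dawn2,
                        t_dawn = 6, t_dusk = 20, t_dawn2 = 30) {
  s <- data.frame(o2_dawn = o2_dawn, o2_dusk = o2_dusk, o2_dawn2 = o2_dawn2,
                  temp_dawn = temp_dawn, temp_dusk = temp_dusk,
                  temp_dawn2 = temp_dawn2,
                  t_dawn = t_dawn, t_dusk = t_dusk, t_dawn2 = t_dawn2)
  ok <- stats::complete.cases(s)
  if (any(s$o2_dawn[ok] < 0 | s$o2_dusk[ok] < 0 | s$o2_dawn2[ok] < 0)) {
    stop("oxygen readings must be non-negative", call. = FALSE)
  }
  temps <- unlist(s[ok, c("temp_dawn", "temp_dusk", "temp_dawn2")])
  if (length(temps) && (any(temps < 0) || any(temps > 45))) {
    stop("temperatures outside plausible range (0-45 C)", call. = FALSE)
  }
  if (any(!(s$t_dawn[ok] < s$t_dusk[ok] & s$t_dusk[ok] < s$t_dawn2[ok]))) {
    stop("times must satisfy t_dawn < t_dusk < t_dawn2", call. = FALSE)
  }
  class(s) <- c("diel_series", "data.frame")
  s
}

# Shared flux estimator for one interval of a diel profile. Returns the
# signed flux, the correction component, and the absolute flux.
flux_interval <- function(o2_start, o2_end, temp_start, temp_end,
                          t_start, t_end, constants, correct, mode) {
  dt <- t_end - t_start
  if (any(!is.na(dt) & dt <= 0)) {
    stop("time interval must be positive", call. = FALSE)
  }
  d_obs <- o2_end - o2_start
  d_eq <- if (correct) {
    equilibrium_oxygen(temp_end, mode = mode) -
      equilibrium_oxygen(temp_start, mode = mode)
  } else {
    0 * d_obs
  }
  signed <- mg_to_umol(d_obs - d_eq, constants) / dt
  list(signed = signed,
       correction = mg_to_umol(d_eq, constants) / dt,
       absolute = abs(signed))
}

#' Net ecosystem production from a diel oxygen profile
#'
#' Daytime oxygen accumulation (photosynthesis minus respiration) estimated
#' from the dawn-to-dusk change in dissolved oxygen, corrected for the
#' change in equilibrium saturation between the two observation
#' temperatures, converted to molar units, and divided by the elapsed time:
#' `|((dO2_day - dO2_E_day) * z) / (t_dusk - t_dawn)|`. The correction
#' vanishes when the bounding temperatures are equal or when
#' `correct = FALSE`.
#'
#' @param s A [diel_series()] (or data frame with its columns).
#' @param constants A [phys_constants()] object.
#' @param correct Apply the temperature-equilibrium correction?
#' @param saturation Saturation model passed to [equilibrium_oxygen()].
#' @return Flux in micromol O2 L^-1 h^-1, as a positive number (absolute
#'   value of the corrected estimate).
#' @examples
#' s <- diel_series(8, 9, 8.2, 20, 20, 20)
#' nep_from_diel(s) # (1 * 31.25) / 14
#' @export
nep_from_diel <- function(s, constants = phys_constants(), correct = TRUE,
                          saturation = "standard") {
  flux_interval(s$o2_dawn, s$o2_dusk, s$temp_dawn, s$temp_dusk,
                s$t_dawn, s$t_dusk, constants, correct, saturation)$absolute
}

#' Ecosystem respiration from a diel oxygen profile
#'
#' Overnight analogue of [nep_from_diel()], using the dusk-to-second-dawn
#' oxygen depletion. Returned as a positive number.
#'
#' @inheritParams nep_from_diel
#' @return Flux in micromol O2 L^-1 h^-1.
#' @export
er_from_diel <- function(s, constants = phys_constants(), correct = TRUE,
                         saturation = "standard") {
  flux_interval(s$o2_dusk, s$o2_dawn2, s$temp_dusk, s$temp_dawn2,
                s$t_dusk, s$t_dawn2, constants, correct, saturation)$absolute
}

#' Estimate NEP and ER for every diel series in a table
#'
#' Appends flux estimates to a tidy table holding one diel oxygen series per
#' row. Rows with incomplete series yield `NA` fluxes and are counted.
#'
#' @param data Data frame with the nine [diel_series()] columns.
#' @param constants A [phys_constants()] object.
#' @param correct Apply the temperature-equilibrium correction?
#' @param saturation Saturation model passed to [equilibrium_oxygen()].
#' @return `data` with columns `nep`, `er` (absolute fluxes,
#'   micromol O2 L^-1 h^-1), `nep_signed`, `er_signed`, `nep_correction`,
#'   `er_correction`, and `flux_corrected`; the number of incomplete series
#'   is attached as attribute `n_missing`.
#' @export
diel_fluxes <- function(data, constants = phys_constants(), correct = TRUE,
                        saturation = "standard") {
  cols <- c("o2_dawn", "o2_dusk", "o2_dawn2",
            "temp_dawn", "temp_dusk", "temp_dawn2",
            "t_dawn", "t_dusk", "t_dawn2")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("missing diel columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ok <- stats::complete.cases(data[cols])
  day <- flux_interval(data$o2_dawn, data$o2_dusk,
                       data$temp_dawn, data$temp_dusk,
                       data$t_dawn, data$t_dusk, constants, correct,
                       saturation)
  night <- flux_interval(data$o2_dusk, data$o2_dawn2,
                         data$temp_dusk, data$temp_dawn2,
                         data$t_dusk, data$t_dawn2, constants, correct,
                         saturation)
  data$nep <- ifelse(ok, day$absolute, NA_real_)
  data$er <- ifelse(ok, night$absolute, NA_real_)
  data$nep_signed <- ifelse(ok, day$signed, NA_real_)
  data$er_signed <- ifelse(ok, night$signed, NA_real_)
  data$nep_correction <- ifelse(ok, day$correction, NA_real_)
  data$er_correction <- ifelse(ok, night$correction, NA_real_)
  data$flux_corrected <- correct
  attr(data, "n_missing") <- sum(!ok)
  data
}
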