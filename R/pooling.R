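#' Confidence interval for a composite (pooled) coefficient
#'
#' A pooled quantity `c' beta` (a linear combination of fixed effects) has
#' standard error `sqrt(c' V c)` from the coefficient covariance matrix; the
#' interval is `estimate +/- q * se` with the normal multiplier
#' `q = 1.96` at the default 95% level (a t-quantile can be supplied via
#' `df`).
#'
#' @param vcov Fixed-effect covariance matrix.
#' @param contrast Numeric contrast vector, same length as the coefficient
#'   vector.
#' @param estimate The composite estimate `c' beta`.
#' @param level Confidence level.
#' @param df Optional degrees of freedom for a t-based multiplier; `NULL`
#'   (default) uses the normal quantile.
#' @return Named vector `c(low, high)` with attribute `se`.
#' @examples
#' composite_ci(diag(2), c(1, 1), 0) # half-width 1.96 * sqrt(2)
#' @export
composite_ci <- function(vcov, contrast, estimate, level = 0.95, df = NULL) {
  vcov <- as.matrix(vcov)
  if (length(contrast) != ncol(vcov)) {
    stop("contrast length (", length(contrast),
         ") does not match coefficient count (", ncol(vcov), ")",
         call. = FALSE)
  }
  se <- sqrt(max(0, drop(t(contrast) %*% vcov %*% contrast)))
  q <- if (is.null(df)) {
    stats::qnorm(1 - (1 - level) / 2)
  } else {
    stats::qt(1 - (1 - level) / 2, df = df)
  }
  structure(c(low = estimate - q * se, high = estimate + q * se), se = se)
}

# Contrast vector selecting a pooled combination of coefficients by name.
# Missing optional names contribute nothing; missing required names error.
pooled_contrast <- function(beta_names, required, optional = character()) {
  miss <- setdiff(required, beta_names)
  if (length(miss)) {
    stop("model lacks coefficient(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  contrast <- stats::setNames(rep(0, length(beta_names)), beta_names)
  contrast[required] <- 1
  contrast[intersect(optional, beta_names)] <- 1
  contrast
}

# Find the coefficient name matching a set of interaction components,
# regardless of the order the model matrix used (R canonicalizes
# "treatment:x" to "x:treatmentAG" when x appears first in the formula).
match_coef <- function(beta_names, components) {
  want <- sort(components)
  hits <- beta_names[vapply(strsplit(beta_names, ":", fixed = TRUE),
                            function(p) identical(sort(p), want), TRUE)]
  if (length(hits)) hits[1] else NA_character_
}

#' Pooled between-ecosystem temperature dependence for one treatment
#'
#' Groups the fixed effects of a within/between-centered fit by the
#' between-ecosystem inverse-temperature covariate: the composite slope for
#' treatment `Z` is `beta_between + beta_{Z x between}` and the composite
#' intercept is `beta_0 + beta_Z` (reference treatment: `beta_between` and
#' `beta_0` alone). The apparent activation energy is minus the composite
#' slope, with a confidence interval from the coefficient covariance.
#'
#' @param fit An `mte_lmm` fit containing the between covariate.
#' @param treatment Treatment level (`"A"`, `"AG"`, `"AGP"`); the factor
#'   reference level needs no interaction coefficients.
#' @param level Confidence level for the interval.
#' @return An object of class `pooled_effect` with fields `treatment`,
#'   `scope`, `slope`, `e` (activation energy, `-slope`), `ci_low`,
#'   `ci_high` (interval on `e`), `se`, and `intercept`.
#' @export
pool_effects <- function(fit, treatment, level = 0.95) {
  stopifnot(inherits(fit, "mte_lmm"))
  nm <- names(fit$beta)
  ref <- if (is.factor(fit$data$treatment)) {
    levels(fit$data$treatment)[1]
  } else {
    "A"
  }
  slope_terms <- "inv_kT_between"
  int_terms <- "(Intercept)"
  if (!identical(treatment, ref)) {
    zc <- paste0("treatment", treatment)
    zbc <- match_coef(nm, c(zc, "inv_kT_between"))
    if (!zc %in% nm) {
      stop("treatment `", treatment, "` absent from model `",
           fit$spec$name, "`", call. = FALSE)
    }
    int_terms <- c(int_terms, zc)
    if (!is.na(zbc)) slope_terms <- c(slope_terms, zbc)
  }
  cs <- pooled_contrast(nm, slope_terms)
  slope <- drop(sum(cs * fit$beta))
  ci_slope <- composite_ci(fit$vcov, cs, slope, level = level)
  e <- activation_energy(slope)
  structure(
    list(treatment = treatment, scope = "between",
         slope = slope, e = e,
         ci_low = -ci_slope[["high"]], ci_high = -ci_slope[["low"]],
         se = attr(ci_slope, "se"),
         intercept = drop(sum(pooled_contrast(nm, int_terms) * fit$beta))),
    class = "pooled_effect"
  )
}

#' Pooled within-ecosystem temperature dependence
#'
#' The within-ecosystem analogue of [pool_effects()]: the slope on weekly
#' temperature deviations is
#' `beta_within + beta_{within x between} * eval_point + beta_{Z x within}`,
#' evaluated at a chosen value of the (grand-mean-centered) between
#' covariate — `eval_point = 0` (default) reads the slope at the grand mean
#' temperature.
#'
#' @inheritParams pool_effects
#' @param eval_point Value of the centered between covariate at which the
#'   within slope is evaluated (eV^-1).
#' @return A `pooled_effect` with `scope = "within"`.
#' @export
pool_within_effects <- function(fit, treatment, eval_point = 0,
                                level = 0.95) {
  stopifnot(inherits(fit, "mte_lmm"))
  nm <- names(fit$beta)
  ref <- if (is.factor(fit$data$treatment)) {
    levels(fit$data$treatment)[1]
  } else {
    "A"
  }
  if (!"inv_kT_within" %in% nm) {
    stop("model `", fit$spec$name, "` lacks the within covariate",
         call. = FALSE)
  }
  contrast <- stats::setNames(rep(0, length(nm)), nm)
  contrast["inv_kT_within"] <- 1
  wb <- "inv_kT_within:inv_kT_between"
  if (wb %in% nm) contrast[wb] <- eval_point
  if (!identical(treatment, ref)) {
    zc <- paste0("treatment", treatment)
    if (!zc %in% nm) {
      stop("treatment `", treatment, "` absent from model `",
           fit$spec$name, "`", call. = FALSE)
    }
    zw <- match_coef(nm, c(zc, "inv_kT_within"))
    if (!is.na(zw)) contrast[zw] <- 1
  }
  slope <- drop(sum(contrast * fit$beta))
  ci_slope <- composite_ci(fit$vcov, contrast, slope, level = level)
  structure(
    list(treatment = treatment, scope = "within",
         slope = slope, e = activation_energy(slope),
         ci_low = -ci_slope[["high"]], ci_high = -ci_slope[["low"]],
         se = attr(ci_slope, "se"),
         intercept = unname(fit$beta["(Intercept)"])),
    class = "pooled_effect"
  )
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf(
    "Pooled %s-ecosystem effect, treatment %s:\n  slope on 1/kT = %.3f eV",
    x$scope, x$treatment, x$slope))
  cat(sprintf("\n  E = %.3f eV  [%.3f, %.3f]  (se %.3f)\n",
              x$e, x$ci_low, x$ci_high, x$se))
  invisible(x)
}

#' Table of pooled activation energies for all treatments
#'
#' @param fit An `mte_lmm` fit from a within/between-centered model.
#' @param treatments Treatment levels to pool over.
#' @param scope `"between"` or `"within"`.
#' @param response Label recorded in the output (e.g. `"chla"`).
#' @return Data frame with one row per treatment: `response`, `treatment`,
#'   `scope`, `slope`, `E`, `ci_low`, `ci_high`, `se`, `intercept`.
#' @export
pooled_effects_table <- function(fit, treatments = c("A", "AG", "AGP"),
                                 scope = c("between", "within"),
                                 response = "y") {
  scope <- match.arg(scope)
  rows <- lapply(treatments, function(trt) {
    p <- if (scope == "between") {
      pool_effects(fit, trt)
    } else {
      pool_within_effects(fit, trt)
    }
    data.frame(response = response, treatment = trt, scope = scope,
               slope = p$slope, E = p$e, ci_low = p$ci_low,
               ci_high = p$ci_high, se = p$se, intercept = p$intercept,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Realized temperature dependence of the trophic cascade in one week
#'
#' The cascade models carry no explicit between-power temperature term: the
#' across-power gradient enters through the power-level random intercepts.
#' The realized week-`w` temperature dependence is therefore estimated by
#' regressing the conditional predictions (fixed effects plus intercept
#' BLUPs) for that week's observations on their Boltzmann inverse
#' temperature; the cascade activation energy is minus that slope.
#'
#' @param fit An `mte_lmm` cascade fit (from [run_model_set()] on a
#'   [center_cascade()] design).
#' @param design The `center_cascade()` design the set was fitted on.
#' @param week Week to evaluate (default 9, the final week).
#' @param constants A [phys_constants()] object.
#' @return List with `e_tc` (eV), `slope`, `week`, and `n` (power levels
#'   used).
#' @export
cascade_temperature_dependence <- function(fit, design, week = 9,
                                           constants = phys_constants()) {
  stopifnot(inherits(fit, "mte_lmm"))
  rows <- design[design$week == week, , drop = FALSE]
  if (nrow(rows) < 3) {
    stop("too few power levels observed in week ", week, call. = FALSE)
  }
  pred <- predict(fit, newdata = rows, re.form = NULL)
  x <- rows$inv_kT_within + rows$inv_kT_between + attr(design, "grand_inv_kT")
  slope <- unname(stats::coef(stats::lm(pred ~ x))[2])
  list(e_tc = activation_energy(slope), slope = slope, week = week,
       n = nrow(rows))
}
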