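#' Specify one candidate mixed model
#'
#' Describes a Gaussian random-intercept model by the fixed-effect terms it
#' includes, using the covariate vocabulary of a [center_design()] table.
#' The intercept is always present, and interaction terms require their main
#' effects.
#'
#' @param name Model label (e.g. `"PBF"`, `"PB3"`, `"TCFull"`).
#' @param terms Character vector drawn from `"inv_kT_within"`,
#'   `"inv_kT_between"`, `"inv_kT_within:inv_kT_between"`, `"treatment"`,
#'   `"treatment:inv_kT_between"`, `"treatment:inv_kT_within"`, `"wk_c"`,
#'   `"inv_kT_within:wk_c"`. May be empty (intercept-only model).
#' @param grouping Random-intercept grouping column, usually `"tank_id"`.
#' @return An object of class `lmm_spec`.
#' @export
lmm_spec <- function(name, terms = character(), grouping = "tank_id") {
  known <- c("inv_kT_within", "inv_kT_between",
             "inv_kT_within:inv_kT_between", "treatment",
             "treatment:inv_kT_between", "treatment:inv_kT_within",
             "wk_c", "inv_kT_within:wk_c")
  bad <- setdiff(terms, known)
  if (length(bad)) {
    stop("unknown term(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (tm in grep(":", terms, value = TRUE)) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% terms)) {
      stop("interaction `", tm, "` requires its main effects", call. = FALSE)
    }
  }
  structure(list(name = name, terms = terms, grouping = grouping),
            class = "lmm_spec")
}

#' @export
print.lmm_spec <- function(x, ...) {
  rhs <- if (length(x$terms)) paste(x$terms, collapse = " + ") else "1"
  cat(sprintf("<lmm_spec> %s: y ~ %s + (1 | %s)\n", x$name, rhs, x$grouping))
  invisible(x)
}

spec_formula <- function(spec) {
  rhs <- if (length(spec$terms)) paste(spec$terms, collapse = " + ") else "1"
  stats::as.formula(paste0("y ~ ", rhs, " + (1 | ", spec$grouping, ")"))
}

#' Fit a Gaussian random-intercept mixed model by maximum likelihood
#'
#' The fitting engine of the package: a linear mixed model with the
#' fixed-effect terms of an [lmm_spec()] and a random intercept per group,
#' estimated by full maximum likelihood (not REML) so that models differing
#' in their fixed effects are comparable by likelihood and AICc. The
#' parameter count is the number of fixed effects plus the random-intercept
#' and residual variances.
#'
#' @param design A [center_design()] table (or any data frame with the
#'   spec's columns and a `y` response).
#' @param spec An [lmm_spec()]; a plain character vector of terms is also
#'   accepted.
#' @param fix_var_group Optionally fix the random-intercept variance. Only
#'   `0` is supported, in which case the model collapses to ordinary least
#'   squares (useful for degenerate designs and as a numerical oracle);
#'   `NULL` (default) estimates it.
#' @return An object of class `mte_lmm` with components `beta` (fixed
#'   effects), `vcov`, `var_group`, `var_resid`, `loglik`, `n_params`,
#'   `n_obs`, `n_groups`, `spec`, and the underlying engine fit.
#' @examples
#' d <- data.frame(y = rnorm(40), inv_kT_within = rnorm(40),
#'                 tank_id = rep(letters[1:8], each = 5))
#' fit <- fit_lmm(d, lmm_spec("m1", "inv_kT_within"))
#' coef(fit)
#' @export
fit_lmm <- function(design, spec, fix_var_group = NULL) {
  if (is.character(spec)) spec <- lmm_spec("model", spec)
  stopifnot(inherits(spec, "lmm_spec"))
  data <- as.data.frame(design)
  if (!"y" %in% names(data)) stop("design must contain `y`", call. = FALSE)

  vars <- unique(unlist(strsplit(spec$terms, ":", fixed = TRUE)))
  miss <- setdiff(c(vars, spec$grouping), names(data))
  if (length(miss)) {
    stop("design lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  if (!is.null(fix_var_group)) {
    if (fix_var_group != 0) {
      stop("only `fix_var_group = 0` is supported", call. = FALSE)
    }
    return(fit_lmm_ols(data, spec))
  }

  groups <- unique(data[[spec$grouping]])
  if (length(groups) < 2) {
    stop("need >= 2 groups for a random intercept; ",
         "use `fix_var_group = 0` for a single group", call. = FALSE)
  }

  fml <- spec_formula(spec)
  fit <- tryCatch(
    lme4::lmer(fml, data = data, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    error = function(e) {
      stop("mixed-model fit failed for `", spec$name, "`: ",
           conditionMessage(e), call. = FALSE)
    }
  )

  vc <- lme4::VarCorr(fit)
  beta <- lme4::fixef(fit)
  ll <- stats::logLik(fit)
  structure(
    list(beta = beta,
         vcov = as.matrix(stats::vcov(fit)),
         var_group = as.numeric(vc[[spec$grouping]][1, 1]),
         var_resid = attr(vc, "sc")^2,
         loglik = as.numeric(ll),
         n_params = attr(ll, "df"),
         n_obs = stats::nobs(fit),
         n_groups = length(groups),
         spec = spec,
         engine = fit,
         data = data),
    class = "mte_lmm"
  )
}

# Ordinary least squares fallback with the group variance pinned at zero.
fit_lmm_ols <- function(data, spec) {
  rhs <- if (length(spec$terms)) paste(spec$terms, collapse = " + ") else "1"
  fit <- stats::lm(stats::as.formula(paste0("y ~ ", rhs)), data = data)
  n <- stats::nobs(fit)
  rss <- sum(stats::residuals(fit)^2)
  sigma2 <- rss / n  # ML, not the unbiased estimator
  p <- length(stats::coef(fit))
  ll <- -n / 2 * (log(2 * pi) + log(ifelse(sigma2 > 0, sigma2, 1)) + 1)
  if (sigma2 == 0) ll <- Inf  # degenerate noiseless fit
  structure(
    list(beta = stats::coef(fit),
         vcov = stats::vcov(fit),
         var_group = 0,
         var_resid = sigma2,
         loglik = ll,
         n_params = p + 2,  # same accounting as the mixed fit
         n_obs = n,
         n_groups = length(unique(data[[spec$grouping]])),
         spec = spec,
         engine = fit,
         data = data),
    class = "mte_lmm"
  )
}

#' @export
print.mte_lmm <- function(x, digits = 4, ...) {
  cat(sprintf("Linear mixed model `%s` (ML), %d obs in %d groups\n",
              x$spec$name, x$n_obs, x$n_groups))
  cat("Fixed effects:\n")
  print(round(x$beta, digits))
  cat(sprintf("Variances: group %.4g, residual %.4g;  logLik %.2f (df %d)\n",
              x$var_group, x$var_resid, x$loglik, x$n_params))
  invisible(x)
}

#' @export
summary.mte_lmm <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  coefs <- cbind(Estimate = object$beta, `Std. Error` = se,
                 `z value` = object$beta / se)
  structure(list(coefficients = coefs, fit = object),
            class = "summary.mte_lmm")
}

#' @export
print.summary.mte_lmm <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficient table:\n")
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' @export
coef.mte_lmm <- function(object, ...) object$beta

#' @export
vcov.mte_lmm <- function(object, ...) object$vcov

#' @export
logLik.mte_lmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
nobs.mte_lmm <- function(object, ...) object$n_obs

#' @export
fitted.mte_lmm <- function(object, ...) stats::fitted(object$engine)

#' @export
residuals.mte_lmm <- function(object, ...) stats::residuals(object$engine)

#' Predict from a fitted mesocosm mixed model
#'
#' @param object An `mte_lmm` fit.
#' @param newdata Optional data frame of covariates; defaults to the fitting
#'   data.
#' @param re.form Random-effect specification as in `lme4`; `NA` (default)
#'   gives population-level predictions, `NULL` conditions on the fitted
#'   group intercepts.
#' @param ... Unused.
#' @return Numeric vector of predictions on the (ln) response scale.
#' @export
predict.mte_lmm <- function(object, newdata = NULL, re.form = NA, ...) {
  if (inherits(object$engine, "lm")) {
    return(stats::predict(object$engine, newdata = newdata))
  }
  if (is.null(newdata)) {
    stats::predict(object$engine, re.form = re.form)
  } else {
    stats::predict(object$engine, newdata = newdata, re.form = re.form,
                   allow.new.levels = TRUE)
  }
}

#' Simulate responses from a fitted mesocosm mixed model
#'
#' @param object An `mte_lmm` fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param ... Passed to the engine's `simulate` method.
#' @return Data frame of simulated responses, one column per draw.
#' @export
simulate.mte_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$engine, nsim = nsim, seed = seed, ...)
}

#' Random-intercept predictions (BLUPs)
#'
#' Conditional modes of the group-level intercept deviations.
#'
#' @param fit An `mte_lmm` fit.
#' @return Named numeric vector, one element per group.
#' @export
group_intercepts <- function(fit) {
  stopifnot(inherits(fit, "mte_lmm"))
  if (inherits(fit$engine, "lm")) {
    grp <- unique(fit$data[[fit$spec$grouping]])
    return(stats::setNames(rep(0, length(grp)), grp))
  }
  re <- lme4::ranef(fit$engine)[[fit$spec$grouping]]
  stats::setNames(re[["(Intercept)"]], rownames(re))
}

#' Residual diagnostics plot
#'
#' @param x An `mte_lmm` fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mte_lmm <- function(x, ...) {
  graphics::plot(fitted(x), residuals(x),
                 xlab = "Fitted values", ylab = "Residuals",
                 main = sprintf("Model %s", x$spec$name), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
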