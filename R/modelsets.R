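#' Small-sample Akaike Information Criterion
#'
#' `AICc = -2 logLik + 2p + 2p(p+1)/(n - p - 1)`, converging to plain AIC as
#' `n` grows.
#'
#' @param loglik Maximised log-likelihood.
#' @param n_params Number of estimated parameters (fixed effects plus
#'   variance components).
#' @param n_obs Number of observations; must exceed `n_params + 1`.
#' @return The AICc value.
#' @examples
#' aicc(-60.78, 6, 79) # 134.73
#' @export
aicc <- function(loglik, n_params, n_obs) {
  if (any(n_obs - n_params - 1 <= 0)) {
    stop("AICc undefined: need n_obs > n_params + 1", call. = FALSE)
  }
  -2 * loglik + 2 * n_params + 2 * n_params * (n_params + 1) /
    (n_obs - n_params - 1)
}

#' Akaike weights from AICc differences
#'
#' @param delta Vector of AICc differences from the best model.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(delta) {
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Rank fitted models by AICc
#'
#' Orders a list of [fit_lmm()] fits by AICc, attaching AICc differences and
#' Akaike weights. All fits must be on the same observation set (identical
#' `n_obs`), otherwise the criteria are not comparable.
#'
#' @param fits List of `mte_lmm` fits.
#' @return An object of class `model_comparison`: a list with the sorted
#'   `fits` and a data frame `table` (model, df, logLik, AICc, delta, weight).
#' @export
rank_models <- function(fits) {
  if (length(fits) == 0) stop("no fits to rank", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, TRUE, "mte_lmm")))
  n <- vapply(fits, function(f) f$n_obs, 0)
  if (length(unique(n)) != 1) {
    stop("fits were made on differing numbers of observations (",
         paste(unique(n), collapse = ", "), "); not comparable", call. = FALSE)
  }
  ic <- vapply(fits, function(f) aicc(f$loglik, f$n_params, f$n_obs), 0)
  ord <- order(ic)
  fits <- fits[ord]
  ic <- ic[ord]
  delta <- ic - ic[1]
  tab <- data.frame(
    model = vapply(fits, function(f) f$spec$name, ""),
    df = vapply(fits, function(f) f$n_params, 0L),
    logLik = vapply(fits, function(f) f$loglik, 0),
    AICc = ic,
    delta = delta,
    weight = akaike_weights(delta),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 2, ...) {
  cat(sprintf("Model comparison (%d models, %d obs in %d groups)\n",
              nrow(x$table), x$fits[[1]]$n_obs, x$fits[[1]]$n_groups))
  tab <- x$table
  tab$logLik <- round(tab$logLik, digits)
  tab$AICc <- round(tab$AICc, digits)
  tab$delta <- round(tab$delta, digits)
  tab$weight <- round(tab$weight, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Conditionally model-averaged coefficient
#'
#' Weighted mean of a coefficient across only the models that contain it,
#' with Akaike weights renormalised over that subset (conditional
#' averaging). Optionally restrict to the equivalence set `delta < delta_max`
#' first.
#'
#' @param comparison A [rank_models()] result.
#' @param term Fixed-effect coefficient name (as in `coef()` of the fits).
#' @param delta_max Only models with AICc difference below this enter the
#'   average (default `Inf`, all models).
#' @return The averaged coefficient (attributes: `weight_total`, the summed
#'   unnormalised weight of the contributing models; `n_models`).
#' @export
model_average_conditional <- function(comparison, term, delta_max = Inf) {
  stopifnot(inherits(comparison, "model_comparison"))
  keep <- comparison$table$delta < delta_max
  fits <- comparison$fits[keep]
  w <- comparison$table$weight[keep]
  has <- vapply(fits, function(f) term %in% names(f$beta), TRUE)
  if (!any(has)) {
    stop("term `", term, "` appears in no model", call. = FALSE)
  }
  est <- vapply(fits[has], function(f) unname(f$beta[term]), 0)
  wsub <- w[has] / sum(w[has])
  structure(sum(wsub * est), weight_total = sum(w[has]),
            n_models = sum(has))
}

# ---- model set catalogues -------------------------------------------------

# Within/between-centered sets (phytoplankton biomass, NEP, ER). Term sets
# reconstructed from the published nested-set description; they reproduce the
# printed df column (3,4,5,5,6,6,8,9,11,12) exactly.
centered_specs <- function(prefix) {
  W <- "inv_kT_within"; B <- "inv_kT_between"
  WB <- "inv_kT_within:inv_kT_between"
  Z <- "treatment"; ZB <- "treatment:inv_kT_between"
  ZW <- "treatment:inv_kT_within"
  sets <- list(
    F    = c(W, B, WB, Z, ZW, ZB),
    `8`  = c(W, B, Z, ZW, ZB),
    `7`  = c(W, B, Z, ZB),
    `6`  = c(W, Z, ZW),
    `5`  = c(W, Z),
    `4`  = c(W, B, WB),
    `3`  = c(W, B),
    `2`  = W,
    `1`  = Z,
    `0`  = character()
  )
  lapply(names(sets), function(nm) {
    lmm_spec(paste0(prefix, nm), sets[[nm]], grouping = "tank_id")
  })
}

# Trophic-cascade set: within-power inverse temperature, centered week, and
# their interaction, grouped by power level.
cascade_specs <- function() {
  W <- "inv_kT_within"; K <- "wk_c"; WK <- "inv_kT_within:wk_c"
  list(
    lmm_spec("TCFull", c(W, K, WK), grouping = "tank_id"),
    lmm_spec("TCmC", c(W, K), grouping = "tank_id"),
    lmm_spec("TCmD", W, grouping = "tank_id"),
    lmm_spec("TCmE", K, grouping = "tank_id"),
    lmm_spec("TCmF", character(), grouping = "tank_id")
  )
}

# Zooplankton density sets: weekly inverse temperature, predator treatment
# (AG vs AGP), and their interaction. The within covariate slot carries the
# grand-centered weekly 1/kT here (densities are modelled on the weekly
# temperature directly, not decomposed).
zoop_specs <- function(prefix) {
  Tt <- "inv_kT_within"; Z <- "treatment"
  TZ <- "treatment:inv_kT_within"
  labels <- c("", "a", "b", "c", "d")
  sets <- list(c(Tt, Z, TZ), Z, Tt, character(), c(Tt, Z))
  lapply(seq_along(sets), function(i) {
    lmm_spec(paste0(prefix, "1", labels[i]), sets[[i]], grouping = "tank_id")
  })
}

#' Candidate model specifications for a named analysis set
#'
#' @param set_name One of `"phyto_biomass"`, `"nep"`, `"er"` (ten nested
#'   within/between-centered models each), `"cascade"` (five models), or
#'   `"zoop_total"`, `"daphnia"`, `"copepod"` (five models each).
#' @return List of [lmm_spec()] objects.
#' @export
model_set_specs <- function(set_name) {
  switch(set_name,
         phyto_biomass = centered_specs("PB"),
         nep = centered_specs("NEP"),
         er = centered_specs("ER"),
         cascade = cascade_specs(),
         zoop_total = zoop_specs("Z"),
         daphnia = zoop_specs("D"),
         copepod = zoop_specs("C"),
         stop("unknown model set: ", set_name, call. = FALSE))
}

#' Fit and rank a full nested model set
#'
#' Fits every candidate model of a named set on the identical listwise-
#' complete row set (complete cases across the union of all terms) and ranks
#' them by AICc.
#'
#' @param design A [center_design()] table appropriate for the set (for
#'   `"cascade"`, from [center_cascade()]; for zooplankton sets, restricted
#'   to AG/AGP tanks with the weekly inverse temperature in
#'   `inv_kT_within`).
#' @param set_name See [model_set_specs()].
#' @return A [rank_models()] comparison.
#' @export
run_model_set <- function(design, set_name) {
  specs <- model_set_specs(set_name)
  vars <- unique(unlist(lapply(specs, function(s) {
    unlist(strsplit(s$terms, ":", fixed = TRUE))
  })))
  vars <- c("y", vars, specs[[1]]$grouping)
  data <- as.data.frame(design)
  data <- data[stats::complete.cases(data[intersect(vars, names(data))]), ,
               drop = FALSE]
  fits <- lapply(specs, function(s) fit_lmm(data, s))
  rank_models(fits)
}

#' Write a model comparison in the published table layout
#'
#' Emits one row per model with its coefficient estimates (blank where a
#' term is absent), df, logLik, AICc, delta, and weight, in a byte-stable
#' column order.
#'
#' @param comparison A [rank_models()] result.
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "model_comparison"))
  all_terms <- unique(unlist(lapply(comparison$fits,
                                    function(f) names(f$beta))))
  rows <- lapply(comparison$fits, function(f) {
    est <- stats::setNames(rep(NA_real_, length(all_terms)), all_terms)
    est[names(f$beta)] <- f$beta
    est
  })
  coefs <- do.call(rbind, rows)
  out <- cbind(model = comparison$table$model,
               as.data.frame(round(coefs, 4)),
               comparison$table[c("df", "logLik", "AICc", "delta", "weight")])
  out$logLik <- round(out$logLik, 2)
  out$AICc <- round(out$AICc, 2)
  out$delta <- round(out$delta, 2)
  out$weight <- round(out$weight, 3)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
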