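#' Run configuration for the analysis pipeline
#'
#' Exactly one input source must be given: either a CSV path (`input`) or a
#' synthetic-experiment configuration (`synthetic`).
#'
#' @param input Path to an observation CSV, or `NULL`.
#' @param synthetic A [synthetic_config()], or `NULL`.
#' @param outdir Output directory (created if absent).
#' @param seed Integer seed used where the run draws random numbers.
#' @param sets Model sets to run in [cmd_analyze()].
#' @param saturation Saturation model for the oxygen correction
#'   (`"standard"` or `"literal"`).
#' @param correct Apply the oxygen temperature-equilibrium correction?
#' @param t_c Reference temperature policy: `"grand-mean"` or a numeric
#'   value in Kelvin.
#' @param col_map Optional column mapping passed to [read_mesocosm()].
#' @param verbose Emit per-stage messages?
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, synthetic = NULL, outdir = ".",
                       seed = 1L,
                       sets = c("phyto_biomass", "nep", "er", "cascade",
                                "zoop_total", "daphnia", "copepod"),
                       saturation = "standard", correct = TRUE,
                       t_c = "grand-mean", col_map = NULL, verbose = TRUE) {
  if (is.null(input) == is.null(synthetic)) {
    stop("exactly one of `input` or `synthetic` must be given",
         call. = FALSE)
  }
  known <- c("phyto_biomass", "nep", "er", "cascade", "zoop_total",
             "daphnia", "copepod")
  bad <- setdiff(sets, known)
  if (length(bad)) {
    stop("unknown model set(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(t_c, "grand-mean") && !is.numeric(t_c)) {
    stop("`t_c` must be \"grand-mean\" or a numeric Kelvin value",
         call. = FALSE)
  }
  structure(
    list(input = input, synthetic = synthetic, outdir = outdir,
         seed = as.integer(seed), sets = sets, saturation = saturation,
         correct = correct, t_c = t_c, col_map = col_map,
         verbose = verbose),
    class = "run_config"
  )
}

run_constants <- function(config) {
  t_c <- if (identical(config$t_c, "grand-mean")) NULL else config$t_c
  phys_constants(t_c = t_c)
}

say <- function(config, ...) {
  if (isTRUE(config$verbose)) message(sprintf(...))
}

load_run_data <- function(config) {
  if (!is.null(config$input)) {
    read_mesocosm(config$input, col_map = config$col_map)
  } else {
    syn <- config$synthetic
    syn$seed <- config$seed
    generate_experiment(syn)$data
  }
}

#' Generate and write a synthetic dataset
#'
#' Writes the observation table (`dataset.csv`) and the generating truth
#' (`truth.json`) to the configured output directory. Byte-identical across
#' repeated invocations with the same seed.
#'
#' @param config A [run_config()] with a `synthetic` source.
#' @return Invisibly, a list with the written paths.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$synthetic)) {
    stop("cmd_simulate requires a synthetic input source", call. = FALSE)
  }
  syn <- config$synthetic
  syn$seed <- config$seed
  experiment <- generate_experiment(syn)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(config$outdir, "dataset.csv")
  truth_path <- file.path(config$outdir, "truth.json")
  write_mesocosm(experiment$data, data_path)
  truth <- experiment$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say(config, "wrote %d rows (%d tanks) to %s", nrow(experiment$data),
      length(unique(experiment$data$tank_id)), data_path)
  invisible(list(data = data_path, truth = truth_path))
}

#' Append NEP/ER flux estimates to a dataset
#'
#' Runs the diel-oxygen flux estimators over every row and writes
#' `fluxes.csv`; reports how many rows carry a complete diel series.
#'
#' @param config A [run_config()].
#' @return Invisibly, the flux-augmented data frame.
#' @export
cmd_fluxes <- function(config) {
  stopifnot(inherits(config, "run_config"))
  data <- load_run_data(config)
  fluxed <- flux_table(data, constants = run_constants(config),
                       correct = config$correct,
                       saturation = config$saturation)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$outdir, "fluxes.csv")
  utils::write.csv(as.data.frame(fluxed), path, row.names = FALSE)
  say(config, "flux estimates: %d of %d rows have a diel series (%d missing)",
      nrow(fluxed) - attr(fluxed, "n_missing"), nrow(fluxed),
      attr(fluxed, "n_missing"))
  invisible(fluxed)
}

# Adapter between the canonical observation schema (temperature columns in
# C with _C suffixes) and the diel estimator's column vocabulary.
flux_table <- function(data, constants = phys_constants(), correct = TRUE,
                       saturation = "standard") {
  d <- as.data.frame(data)
  d$temp_dawn <- d$temp_dawn_C
  d$temp_dusk <- d$temp_dusk_C
  d$temp_dawn2 <- d$temp_dawn2_C
  out <- diel_fluxes(d, constants = constants, correct = correct,
                     saturation = saturation)
  out$temp_dawn <- out$temp_dusk <- out$temp_dawn2 <- NULL
  out
}

#' Run the full analysis and write its data products
#'
#' Assembles fluxes, centers designs, fits and ranks every requested model
#' set, pools coefficients into composite activation energies per
#' treatment, and builds the trophic-cascade series. Writes one comparison
#' CSV per set, `pooled_effects.csv`, and `cascade_series.csv` to the
#' output directory.
#'
#' @param config A [run_config()].
#' @return Invisibly, a `mesocosm_analysis` object (see
#'   [mesocosm_analysis()]).
#' @export
cmd_analyze <- function(config) {
  stopifnot(inherits(config, "run_config"))
  data <- load_run_data(config)
  res <- mesocosm_analysis(data, constants = run_constants(config),
                           sets = config$sets, correct = config$correct,
                           saturation = config$saturation,
                           verbose = config$verbose)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(res$comparisons)) {
    write_comparison(res$comparisons[[nm]],
                     file.path(config$outdir, paste0("table_", nm, ".csv")))
  }
  if (!is.null(res$pooled)) {
    utils::write.csv(res$pooled,
                     file.path(config$outdir, "pooled_effects.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$cascade_series)) {
    utils::write.csv(res$cascade_series,
                     file.path(config$outdir, "cascade_series.csv"),
                     row.names = FALSE)
  }
  invisible(res)
}

#' Full mesocosm analysis in memory
#'
#' The programmatic face of [cmd_analyze()]: estimates fluxes, runs the
#' requested model sets, and pools temperature dependences.
#'
#' @param data A mesocosm observation table.
#' @param constants A [phys_constants()] object.
#' @param sets Model sets to run.
#' @param correct,saturation Oxygen-correction options.
#' @param verbose Emit per-stage row accounting messages?
#' @return An object of class `mesocosm_analysis`: a list with
#'   `comparisons` (one [rank_models()] result per set), `pooled` (composite
#'   between-ecosystem activation energies per response and treatment),
#'   `cascade_series`, `e_tc` (week-9 cascade temperature dependence, when
#'   the cascade set ran), `zoop_e` (conditionally averaged density
#'   temperature coefficients), and `designs`.
#' @export
mesocosm_analysis <- function(data,
                              constants = phys_constants(),
                              sets = c("phyto_biomass", "nep", "er",
                                       "cascade", "zoop_total", "daphnia",
                                       "copepod"),
                              correct = TRUE, saturation = "standard",
                              verbose = FALSE) {
  cfg <- list(verbose = verbose)
  fluxed <- flux_table(data, constants = constants, correct = correct,
                       saturation = saturation)
  say(cfg, "fluxes: %d of %d rows complete", nrow(fluxed) -
        attr(fluxed, "n_missing"), nrow(fluxed))

  comparisons <- list()
  designs <- list()
  pooled <- NULL
  treatments_present <- intersect(c("A", "AG", "AGP"),
                                  unique(as.character(data$treatment)))

  centered_sets <- list(phyto_biomass = "chla_ug_L", nep = "nep", er = "er")
  for (nm in intersect(names(centered_sets), sets)) {
    design <- center_design(fluxed, centered_sets[[nm]], constants = constants)
    say(cfg, "%s: %d design rows (%d dropped)", nm, nrow(design),
        attr(design, "n_dropped"))
    comp <- run_model_set(design, nm)
    comparisons[[nm]] <- comp
    designs[[nm]] <- design
    pooled <- rbind(pooled,
                    pool_from_comparison(comp, treatments_present, nm))
  }

  cascade_series <- NULL
  e_tc <- NULL
  if ("cascade" %in% sets && all(c("AG", "AGP") %in% data$treatment)) {
    cascade_series <- build_cascade_series(fluxed)
    cdesign <- center_cascade(cascade_series, constants = constants)
    say(cfg, "cascade: %d pair-weeks", nrow(cdesign))
    comp <- run_model_set(cdesign, "cascade")
    comparisons[["cascade"]] <- comp
    designs[["cascade"]] <- cdesign
    e_tc <- cascade_temperature_dependence(comp$fits[[1]], cdesign,
                                           week = max(cdesign$week),
                                           constants = constants)
  }

  zoop_cols <- list(zoop_total = NULL, daphnia = "daphnia_per10L",
                    copepod = "copepod_per10L")
  zoop_e <- list()
  if (all(c("AG", "AGP") %in% data$treatment)) {
    for (nm in intersect(names(zoop_cols), sets)) {
      zd <- zoop_design(fluxed, zoop_cols[[nm]], constants = constants)
      say(cfg, "%s: %d design rows", nm, nrow(zd))
      comp <- run_model_set(zd, nm)
      comparisons[[nm]] <- comp
      designs[[nm]] <- zd
      zoop_e[[nm]] <- zoop_density_E(comp)
    }
  }

  structure(
    list(comparisons = comparisons, pooled = pooled,
         cascade_series = cascade_series, e_tc = e_tc, zoop_e = zoop_e,
         designs = designs, fluxes = fluxed),
    class = "mesocosm_analysis"
  )
}

# Pool composite between-ecosystem effects from the highest-ranked model
# that carries the needed coefficients for each treatment.
pool_from_comparison <- function(comparison, treatments, response) {
  rows <- lapply(treatments, function(trt) {
    for (fit in comparison$fits) {
      p <- tryCatch(pool_effects(fit, trt), error = function(e) NULL)
      if (!is.null(p)) {
        return(data.frame(response = response, treatment = trt,
                          scope = "between", model = fit$spec$name,
                          slope = p$slope, E = p$e, ci_low = p$ci_low,
                          ci_high = p$ci_high, se = p$se,
                          intercept = p$intercept,
                          stringsAsFactors = FALSE))
      }
    }
    NULL
  })
  do.call(rbind, rows)
}

# Design table for zooplankton density models: AG/AGP tanks, ln(count+1)
# response, grand-centered weekly 1/kT in the temperature covariate slot.
zoop_design <- function(data, count_col = NULL,
                        constants = phys_constants()) {
  d <- as.data.frame(data)
  d <- d[d$treatment %in% c("AG", "AGP"), , drop = FALSE]
  counts <- if (is.null(count_col)) {
    d$daphnia_per10L + d$copepod_per10L
  } else {
    d[[count_col]]
  }
  out <- center_design(d, response = counts, constants = constants,
                       transform = "log1p")
  # densities are modelled on the weekly temperature directly
  out$inv_kT_within <- out$inv_kT_within + out$inv_kT_between
  out
}

#' Conditionally averaged temperature coefficient of a density model set
#'
#' The temperature dependence of a zooplankton density, reported in the
#' density convention: the Akaike-weighted average (over models containing
#' it) of the coefficient on grand-centered weekly `1/kT`. Positive values
#' mean density declines with warming.
#'
#' @param comparison A [rank_models()] result from a zooplankton set.
#' @return The averaged coefficient (eV), or `NA` if no candidate model
#'   contains the temperature term.
#' @export
zoop_density_E <- function(comparison) {
  out <- tryCatch(
    model_average_conditional(comparison, "inv_kT_within"),
    error = function(e) NA_real_
  )
  as.numeric(out)
}

#' @export
print.mesocosm_analysis <- function(x, ...) {
  cat("Mesocosm analysis\n")
  for (nm in names(x$comparisons)) {
    best <- x$comparisons[[nm]]$table[1, ]
    cat(sprintf("  %-14s best %-7s (AICc %.2f, w %.2f) of %d models\n",
                nm, best$model, best$AICc, best$weight,
                nrow(x$comparisons[[nm]]$table)))
  }
  if (!is.null(x$e_tc)) {
    cat(sprintf("  cascade temperature dependence (week %d): E_TC = %.2f eV\n",
                x$e_tc$week, x$e_tc$e_tc))
  }
  if (length(x$zoop_e)) {
    for (nm in names(x$zoop_e)) {
      cat(sprintf("  %-14s density temperature coefficient: %.2f eV\n",
                  nm, x$zoop_e[[nm]]))
    }
  }
  invisible(x)
}
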