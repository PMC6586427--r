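#' Canonical mesocosm observation columns
#'
#' Column names of the tidy one-row-per-ecosystem-per-week observation table
#' the package consumes and emits.
#'
#' @return Character vector of canonical column names.
#' @export
mesocosm_columns <- function() {
  c("tank_id", "treatment", "watts", "week", "temp_week_C", "chla_ug_L",
    "o2_dawn", "o2_dusk", "o2_dawn2", "t_dawn", "t_dusk", "t_dawn2",
    "temp_dawn_C", "temp_dusk_C", "temp_dawn2_C",
    "daphnia_per10L", "copepod_per10L")
}

# Columns that must be present and parse; diel oxygen fields may be missing
# (those rows carry flux = NA downstream).
required_mesocosm_columns <- function() {
  c("tank_id", "treatment", "watts", "week", "temp_week_C", "chla_ug_L")
}

#' Read and validate a mesocosm observation table
#'
#' Loads a CSV with one row per ecosystem-week, optionally renaming columns
#' from another dialect via `col_map`, and validates each row against the
#' design invariants: treatment in {A, AG, AGP}, week in 2-9, non-negative
#' chlorophyll and zooplankton counts, unique (tank, week) pairs. Rows
#' failing a row-level invariant are dropped and logged (attribute
#' `rejected`, with reasons); rows whose diel oxygen fields are missing are
#' kept with those fields `NA`. Structural problems (unknown treatment code,
#' duplicate tank-week, missing required columns, empty file) are hard
#' errors.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(chla_ug_L = "Chla")`.
#' @return A validated data frame of class `mesocosm_data`, sorted by tank
#'   and week, with attribute `rejected` describing dropped rows.
#' @export
read_mesocosm <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("empty dataset: ", path, call. = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw)) {
        stop("mapped column not in file: ", src, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  validate_mesocosm(raw)
}

#' Validate an in-memory mesocosm observation table
#'
#' @param data Data frame with (at least) the required canonical columns.
#' @return A `mesocosm_data` data frame; see [read_mesocosm()].
#' @export
validate_mesocosm <- function(data) {
  miss <- setdiff(required_mesocosm_columns(), names(data))
  if (length(miss)) {
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_trt <- setdiff(unique(as.character(data$treatment)), c("A", "AG", "AGP"))
  if (length(bad_trt)) {
    stop("unknown treatment code(s): ", paste(bad_trt, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(data$tank_id, data$week, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate (tank_id, week) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }

  for (col in c("watts", "week", "temp_week_C", "chla_ug_L")) {
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
  }
  reasons <- character(nrow(data))
  flag <- function(bad, why) {
    bad <- !is.na(bad) & bad
    reasons[bad & reasons == ""] <<- why
  }
  flag(is.na(data$week) | data$week < 2 | data$week > 9,
       "week outside 2-9")
  flag(is.na(data$temp_week_C), "unparseable weekly temperature")
  flag(is.na(data$chla_ug_L), "unparseable chlorophyll")
  flag(data$chla_ug_L < 0, "negative chlorophyll")
  for (col in c("daphnia_per10L", "copepod_per10L")) {
    if (col %in% names(data)) {
      data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
      flag(data[[col]] < 0, paste("negative", col))
    }
  }

  rejected <- data.frame(row = which(reasons != ""),
                         reason = reasons[reasons != ""])
  if (nrow(rejected)) {
    message(nrow(rejected), " row(s) rejected during validation")
  }
  out <- data[reasons == "", , drop = FALSE]
  out <- out[order(out$tank_id, out$week), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  class(out) <- c("mesocosm_data", "data.frame")
  out
}

#' Write a mesocosm observation table
#'
#' Inverse of [read_mesocosm()]: a written table read back reproduces all
#' records.
#'
#' @param data A mesocosm observation data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mesocosm <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Natural-log transform with unit offset for count data
#'
#' `ln(x + 1)`, the transform used for zooplankton densities so that weeks
#' with zero observed individuals (most likely detection failures at low
#' density) enter the models as `ln(1) = 0`.
#'
#' @param count Non-negative counts.
#' @return Transformed values.
#' @export
ln_plus_one <- function(count) {
  if (any(!is.na(count) & count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  log(count + 1)
}

#' Build a within/between mean-centered design table
#'
#' Decomposes the Boltzmann inverse temperature of every observation into a
#' between-ecosystem component (each tank's mean inverse temperature,
#' centered on the grand mean) and a within-ecosystem component (weekly
#' deviations from the tank mean), the covariates of the mixed models. The
#' response is ln-transformed; rows with missing or non-positive response
#' are dropped and counted. The decomposition is exact:
#' `inv_kT_within + inv_kT_between + grand mean = 1/kT_wj` for every row.
#'
#' @param data A mesocosm observation table (canonical columns).
#' @param response Column to model (e.g. `"chla_ug_L"`, `"nep"`, `"er"`), or
#'   a numeric vector of length `nrow(data)`.
#' @param constants A [phys_constants()] object; if its `t_c` is `NULL` the
#'   grand mean of the observed temperatures defines the centering point
#'   (and is recorded in the attributes).
#' @param transform Response transform: `"log"` (default; positive values
#'   required, others dropped), `"log1p"` (counts), or `"identity"`.
#' @return Data frame of class `design_table` with columns `y`,
#'   `inv_kT_within`, `inv_kT_between`, `treatment` (factor, reference
#'   first), `week`, `wk_c` (week centered on its mean), `tank_id`, `watts`;
#'   attributes `grand_inv_kT`, `t_c` (Kelvin), `n_dropped`.
#' @export
center_design <- function(data, response, constants = phys_constants(),
                          transform = c("log", "log1p", "identity")) {
  transform <- match.arg(transform)
  y_raw <- if (is.character(response) && length(response) == 1L) {
    if (!response %in% names(data)) {
      stop("response column not found: ", response, call. = FALSE)
    }
    data[[response]]
  } else {
    stopifnot(length(response) == nrow(data))
    response
  }

  temp_k <- celsius_to_kelvin(data$temp_week_C)
  x <- inv_kT(temp_k, constants)
  tank <- as.character(data$tank_id)
  tank_mean <- tapply(x, tank, mean)

  single <- names(table(tank))[table(tank) < 2]
  if (length(single)) {
    warning("tank(s) with a single week; within-ecosystem deviation set ",
            "to 0 for: ", paste(single, collapse = ", "))
  }

  grand <- if (is.null(constants$t_c)) {
    mean(tank_mean)
  } else {
    inv_kT(constants$t_c, constants)
  }

  x_bar <- tank_mean[tank]
  keep <- !is.na(y_raw)
  y <- switch(transform,
              log = {
                pos <- keep & y_raw > 0
                dropped_zero <- keep & !pos
                keep <- pos
                log(y_raw)
              },
              log1p = ln_plus_one(y_raw),
              identity = y_raw)

  trt <- factor(as.character(data$treatment),
                levels = intersect(c("A", "AG", "AGP"),
                                   unique(as.character(data$treatment))))
  out <- data.frame(
    y = y,
    inv_kT_within = as.numeric(x - x_bar),
    inv_kT_between = as.numeric(x_bar - grand),
    treatment = trt,
    week = data$week,
    tank_id = tank,
    watts = data$watts,
    stringsAsFactors = FALSE
  )
  out <- out[keep, , drop = FALSE]
  out$wk_c <- out$week - mean(out$week)
  rownames(out) <- NULL
  attr(out, "grand_inv_kT") <- as.numeric(grand)
  attr(out, "t_c") <- 1 / (constants$k * grand)
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("design_table", "data.frame")
  out
}

#' Pair predator and predator-free tanks into a trophic-cascade series
#'
#' For every heater power level and week where both the AGP and the AG tank
#' at that power have positive chlorophyll, computes the log response ratio
#' `ln(chla_AGP / chla_AG)` (positive values mean predators increase
#' producer biomass) and the mean of the pair's weekly temperatures. Power
#' levels lacking either partner are skipped with a message.
#'
#' @param data A mesocosm observation table containing AG and AGP tanks.
#' @return Data frame with columns `watts`, `week`, `ln_ratio`,
#'   `temp_week_C` (pair mean), one row per complete pair-week.
#' @export
build_cascade_series <- function(data) {
  ag <- data[data$treatment == "AG", c("watts", "week", "chla_ug_L",
                                       "temp_week_C")]
  agp <- data[data$treatment == "AGP", c("watts", "week", "chla_ug_L",
                                         "temp_week_C")]
  unmatched <- union(setdiff(unique(ag$watts), unique(agp$watts)),
                     setdiff(unique(agp$watts), unique(ag$watts)))
  if (length(unmatched)) {
    message("skipping unmatched power level(s): ",
            paste(sort(unmatched), collapse = ", "))
  }
  m <- merge(ag, agp, by = c("watts", "week"), suffixes = c("_ag", "_agp"))
  ok <- !is.na(m$chla_ug_L_ag) & !is.na(m$chla_ug_L_agp) &
    m$chla_ug_L_ag > 0 & m$chla_ug_L_agp > 0
  m <- m[ok, , drop = FALSE]
  out <- data.frame(
    watts = m$watts,
    week = m$week,
    ln_ratio = log(m$chla_ug_L_agp) - log(m$chla_ug_L_ag),
    temp_week_C = (m$temp_week_C_ag + m$temp_week_C_agp) / 2
  )
  out <- out[order(out$watts, out$week), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Center a trophic-cascade series for model fitting
#'
#' Builds the design for the cascade mixed models: response `ln_ratio`,
#' within-power-level centered Boltzmann inverse temperature, numeric week
#' centered on its mean, grouping by power level.
#'
#' @param cascade Output of [build_cascade_series()].
#' @param constants A [phys_constants()] object.
#' @return A `design_table` with `tank_id` set to the power level (the
#'   grouping key of the cascade models).
#' @export
center_cascade <- function(cascade, constants = phys_constants()) {
  d <- data.frame(tank_id = paste0("W", cascade$watts),
                  treatment = "AG",   # placeholder; no trophic term here
                  watts = cascade$watts,
                  week = cascade$week,
                  temp_week_C = cascade$temp_week_C,
                  chla_ug_L = 1)
  out <- center_design(d, response = cascade$ln_ratio, constants = constants,
                       transform = "identity")
  out
}
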