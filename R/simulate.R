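#' Configuration for a synthetic heated-mesocosm experiment
#'
#' Bundles the design and generating parameters of a simulated experiment:
#' 30 tanks (10 heater power levels crossed with three trophic treatments),
#' weekly observations from week 2 to week 9, a declining seasonal
#' temperature baseline with heater offsets, ln-linear Boltzmann structure
#' in chlorophyll and oxygen fluxes with treatment-specific slopes,
#' tank-level random intercepts, Poisson zooplankton counts, and a fixed
#' fraction of missing diel-oxygen records.
#'
#' Default effect sizes follow the fitted values reported for this
#' experimental design (chlorophyll full-model coefficients, NEP/ER
#' top-model coefficients, a -0.23 predator effect on ln Daphnia density, a
#' 1.21 eV copepod decline) and tank mean temperatures spanning roughly
#' 19.7-26.1 C. Noise levels are documented package choices (see the
#' methods vignette), not reported quantities.
#'
#' @param n_power_levels Number of heater power levels (watts 0, 50, ...,
#'   in steps of 50).
#' @param treatments Trophic treatments to cross with power.
#' @param weeks Observation weeks.
#' @param seed Root RNG seed; every component derives a named substream
#'   from it, so the output is byte-identical for a fixed seed.
#' @param temp_model List: `baseline_start` (C, week-2 unheated baseline),
#'   `weekly_decline` (C/week), `heater_gain` (C per 100 W),
#'   `weekly_noise_sd` (C).
#' @param chla_model List of true coefficients on the ln scale (`beta0`,
#'   `beta_within`, `beta_between`, `beta_wb`, and named vectors
#'   `beta_treat`, `beta_treat_between`, `beta_treat_within` over AG/AGP),
#'   plus `var_group` and `var_resid`.
#' @param flux_model Lists `nep` and `er` with `beta0`, `beta_within`,
#'   `beta_between`, `beta_treat`, `beta_treat_between`, `var_group`,
#'   `var_resid`; fluxes are in micromol O2/L/h on the exp scale.
#' @param zoop_model List: `daphnia_log_mean`, `copepod_log_mean`
#'   (ln expected count per 10 L at the grand mean temperature),
#'   `daphnia_predator_effect` (on the log mean), `daphnia_invkT_slope`,
#'   `copepod_invkT_slope` (per eV^-1 of grand-centered weekly 1/kT).
#' @param missing_diel Number of tank-weeks whose diel oxygen series is
#'   dropped (21 of 240 by default).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_power_levels = 10,
    treatments = c("A", "AG", "AGP"),
    weeks = 2:9,
    seed = 1L,
    temp_model = list(baseline_start = 22.5, weekly_decline = 0.8,
                      heater_gain = 1.42, weekly_noise_sd = 1.5),
    chla_model = list(beta0 = 2.05, beta_within = -0.52, beta_between = 1.30,
                      beta_wb = 1.34,
                      beta_treat = c(AG = -0.3, AGP = -0.1),
                      beta_treat_between = c(AG = 4.0, AGP = 0.3),
                      beta_treat_within = c(AG = 0.3, AGP = 0.0),
                      var_group = 0.04, var_resid = 0.09),
    flux_model = list(
      nep = list(beta0 = -6.42, beta_within = 0.29, beta_between = -1.40,
                 beta_treat = c(AG = 0.10, AGP = 0.15),
                 beta_treat_between = c(AG = 0.30, AGP = 0.50),
                 var_group = 0.04, var_resid = 0.0625),
      er = list(beta0 = -6.09, beta_within = 0.11, beta_between = -1.32,
                beta_treat = c(AG = 0.10, AGP = 0.15),
                beta_treat_between = c(AG = 0.20, AGP = 0.40),
                var_group = 0.04, var_resid = 0.0625)),
    zoop_model = list(daphnia_log_mean = 0.0, copepod_log_mean = 0.9,
                      daphnia_predator_effect = -0.23,
                      daphnia_invkT_slope = 0.0,
                      copepod_invkT_slope = 1.21),
    missing_diel = 21) {
  stopifnot(n_power_levels >= 1, length(weeks) >= 2,
            all(treatments %in% c("A", "AG", "AGP")),
            chla_model$var_group >= 0, chla_model$var_resid >= 0,
            missing_diel >= 0)
  structure(
    list(n_power_levels = n_power_levels, treatments = treatments,
         weeks = weeks, seed = as.integer(seed), temp_model = temp_model,
         chla_model = chla_model, flux_model = flux_model,
         zoop_model = zoop_model, missing_diel = missing_diel),
    class = "synthetic_config"
  )
}

# Named RNG substreams: each component draws under its own seed derived
# from the root, so changing one component's settings cannot perturb the
# draws of another. Offsets keep seeds well inside 32-bit range.
substream_seed <- function(config, component) {
  offsets <- c(temperature = 101, chla = 211, flux = 307, zoop = 401,
               missing = 503)
  (abs(as.numeric(config$seed)) * 1009) %% 2147480000 + offsets[[component]]
}

with_substream <- function(config, component, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(substream_seed(config, component))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# Design skeleton: one row per tank-week.
design_skeleton <- function(config) {
  watts <- (seq_len(config$n_power_levels) - 1) * 50
  tanks <- expand.grid(watts = watts, treatment = config$treatments,
                       stringsAsFactors = FALSE)
  tanks$tank_id <- sprintf("%s_%03d", tanks$treatment, tanks$watts)
  out <- merge(tanks, data.frame(week = config$weeks))
  out <- out[order(out$tank_id, out$week), ]
  rownames(out) <- NULL
  out[c("tank_id", "treatment", "watts", "week")]
}

#' Simulate weekly mean tank temperatures
#'
#' `T(tank, week) = baseline_start - weekly_decline * (week - first week) +
#' heater_gain * watts / 100 + noise`. Paired tanks at the same power level
#' share the same realized temperature within a week (they share the
#' thermal environment), so expected temperatures depend on power, not
#' treatment.
#'
#' @param config A [synthetic_config()].
#' @return Design skeleton data frame with a `temp_week_C` column.
#' @export
simulate_temperatures <- function(config) {
  skel <- design_skeleton(config)
  tm <- config$temp_model
  noise <- with_substream(config, "temperature", {
    n <- config$n_power_levels * length(config$weeks)
    matrix(stats::rnorm(n, 0, tm$weekly_noise_sd),
           nrow = config$n_power_levels,
           dimnames = list(NULL, config$weeks))
  })
  power_idx <- skel$watts / 50 + 1
  week_idx <- match(skel$week, config$weeks)
  skel$temp_week_C <- tm$baseline_start -
    tm$weekly_decline * (skel$week - config$weeks[1]) +
    tm$heater_gain * skel$watts / 100 +
    noise[cbind(power_idx, week_idx)]
  skel
}

# Centered covariates of the generating model, computed exactly as the
# analysis will compute them (tank means of weekly 1/kT, grand mean over
# tanks).
generating_covariates <- function(temps, constants = phys_constants()) {
  x <- inv_kT(celsius_to_kelvin(temps$temp_week_C), constants)
  tank_mean <- tapply(x, temps$tank_id, mean)
  grand <- mean(tank_mean)
  list(x_within = as.numeric(x - tank_mean[temps$tank_id]),
       x_between = as.numeric(tank_mean[temps$tank_id] - grand),
       x_grand_centered = as.numeric(x - grand),
       grand = grand)
}

# Linear predictor of an ln response under the generating coefficients.
ln_linear_predictor <- function(temps, cov, m) {
  eta <- m$beta0 +
    m$beta_within * cov$x_within +
    m$beta_between * cov$x_between
  if (!is.null(m$beta_wb)) {
    eta <- eta + m$beta_wb * cov$x_within * cov$x_between
  }
  for (trt in names(m$beta_treat)) {
    z <- as.numeric(temps$treatment == trt)
    eta <- eta + m$beta_treat[[trt]] * z
    if (!is.null(m$beta_treat_between)) {
      eta <- eta + m$beta_treat_between[[trt]] * z * cov$x_between
    }
    if (!is.null(m$beta_treat_within)) {
      eta <- eta + m$beta_treat_within[[trt]] * z * cov$x_within
    }
  }
  eta
}

draw_group_effects <- function(temps, var_group) {
  tanks <- unique(temps$tank_id)
  u <- stats::rnorm(length(tanks), 0, sqrt(var_group))
  stats::setNames(u, tanks)
}

#' Simulate chlorophyll-a concentrations
#'
#' Draws tank-level random intercepts and residuals, evaluates the
#' generating ln-linear Boltzmann model on the centered covariates of the
#' simulated temperatures, and exponentiates. In the deterministic limit
#' (`var_group = var_resid = 0`) the three treatments form exact ln-linear
#' fans against inverse temperature.
#'
#' @param config A [synthetic_config()].
#' @param temps Output of [simulate_temperatures()].
#' @return `temps` with a `chla_ug_L` column; the realized tank intercepts
#'   and linear predictor are attached as attribute `truth`.
#' @export
simulate_chla <- function(config, temps) {
  m <- config$chla_model
  cov <- generating_covariates(temps)
  eta <- ln_linear_predictor(temps, cov, m)
  draws <- with_substream(config, "chla", {
    u <- draw_group_effects(temps, m$var_group)
    e <- stats::rnorm(nrow(temps), 0, sqrt(m$var_resid))
    list(u = u, e = e)
  })
  ln_chla <- eta + draws$u[temps$tank_id] + draws$e
  temps$chla_ug_L <- exp(as.numeric(ln_chla))
  attr(temps, "truth") <- list(tank_intercepts = draws$u, eta = eta,
                               covariates = cov)
  temps
}

#' Simulate diel oxygen series consistent with latent fluxes
#'
#' Draws latent true NEP and ER per tank-week from the flux generating
#' models, then constructs a dawn/dusk/dawn dissolved-oxygen profile whose
#' estimator output reproduces those fluxes exactly: dawn oxygen is
#' anchored at the saturation value for the dawn temperature, and the dusk
#' and second-dawn readings are built by inverting the corrected flux
#' estimators. A configured number of tank-weeks then lose their diel
#' series (missing at random).
#'
#' @param config A [synthetic_config()].
#' @param temps Output of [simulate_temperatures()].
#' @param constants A [phys_constants()] object.
#' @return `temps` with the nine diel columns (`NA` for missing series);
#'   latent fluxes attached as attribute `truth`.
#' @export
simulate_diel_oxygen <- function(config, temps,
                                 constants = phys_constants()) {
  cov <- generating_covariates(temps, constants)
  draw_flux <- function(m) {
    eta <- ln_linear_predictor(temps, cov, m)
    u <- draw_group_effects(temps, m$var_group)
    e <- stats::rnorm(nrow(temps), 0, sqrt(m$var_resid))
    exp(as.numeric(eta + u[temps$tank_id] + e))
  }
  fluxes <- with_substream(config, "flux", {
    list(nep = draw_flux(config$flux_model$nep),
         er = draw_flux(config$flux_model$er))
  })

  t_dawn <- 6; t_dusk <- 20; t_dawn2 <- 30
  temp_dawn <- pmax(0.5, temps$temp_week_C - 1.5)
  temp_dusk <- temps$temp_week_C + 1.5
  temp_dawn2 <- pmax(0.5, temps$temp_week_C - 1.5)

  # Invert the corrected estimators. Day: o2_dusk = o2_dawn + nep*(dt)/z +
  # d[O2]_E; night: o2_dawn2 = o2_dusk - er*(dt)/z + d[O2]_E.
  eq_dawn <- equilibrium_oxygen(temp_dawn)
  eq_dusk <- equilibrium_oxygen(temp_dusk)
  eq_dawn2 <- equilibrium_oxygen(temp_dawn2)
  o2_dawn <- eq_dawn
  o2_dusk <- o2_dawn + fluxes$nep * (t_dusk - t_dawn) / constants$z +
    (eq_dusk - eq_dawn)
  o2_dawn2 <- o2_dusk - fluxes$er * (t_dawn2 - t_dusk) / constants$z +
    (eq_dawn2 - eq_dusk)
  if (any(o2_dusk < 0) || any(o2_dawn2 < 0)) {
    warning("constructed dissolved-oxygen reading below 0; ",
            "clamping fluxes for the affected rows")
    bad <- o2_dusk < 0 | o2_dawn2 < 0
    fluxes$nep[bad] <- 0
    fluxes$er[bad] <- 0
    o2_dusk[bad] <- o2_dawn[bad] + (eq_dusk - eq_dawn)[bad]
    o2_dawn2[bad] <- o2_dusk[bad] + (eq_dawn2 - eq_dusk)[bad]
  }

  drop_idx <- with_substream(config, "missing", {
    if (config$missing_diel > 0) {
      sample(nrow(temps), min(config$missing_diel, nrow(temps)))
    } else {
      integer()
    }
  })

  temps$o2_dawn <- o2_dawn
  temps$o2_dusk <- o2_dusk
  temps$o2_dawn2 <- o2_dawn2
  temps$t_dawn <- t_dawn
  temps$t_dusk <- t_dusk
  temps$t_dawn2 <- t_dawn2
  temps$temp_dawn_C <- temp_dawn
  temps$temp_dusk_C <- temp_dusk
  temps$temp_dawn2_C <- temp_dawn2
  diel_cols <- c("o2_dawn", "o2_dusk", "o2_dawn2",
                 "t_dawn", "t_dusk", "t_dawn2",
                 "temp_dawn_C", "temp_dusk_C", "temp_dawn2_C")
  temps[drop_idx, diel_cols] <- NA
  attr(temps, "truth") <- list(nep = fluxes$nep, er = fluxes$er,
                               missing_rows = sort(drop_idx))
  temps
}

#' Simulate zooplankton counts
#'
#' Poisson counts per 10 L with log-mean linear in the grand-centered weekly
#' Boltzmann inverse temperature; predators (AGP) shift the Daphnia log-mean
#' by the configured effect. Algae-only tanks carry no zooplankton columns
#' (NA).
#'
#' @param config A [synthetic_config()].
#' @param temps Output of [simulate_temperatures()].
#' @return `temps` with `daphnia_per10L` and `copepod_per10L` columns.
#' @export
simulate_zooplankton <- function(config, temps) {
  zm <- config$zoop_model
  cov <- generating_covariates(temps)
  has_zoop <- temps$treatment %in% c("AG", "AGP")
  pred <- as.numeric(temps$treatment == "AGP")
  log_mu_d <- zm$daphnia_log_mean + zm$daphnia_invkT_slope *
    cov$x_grand_centered + zm$daphnia_predator_effect * pred
  log_mu_c <- zm$copepod_log_mean + zm$copepod_invkT_slope *
    cov$x_grand_centered
  counts <- with_substream(config, "zoop", {
    list(d = stats::rpois(nrow(temps), exp(log_mu_d)),
         c = stats::rpois(nrow(temps), exp(log_mu_c)))
  })
  temps$daphnia_per10L <- ifelse(has_zoop, counts$d, NA_real_)
  temps$copepod_per10L <- ifelse(has_zoop, counts$c, NA_real_)
  temps
}

#' Generate a complete synthetic mesocosm experiment
#'
#' Composes the four simulators into one canonical-schema observation table
#' plus a truth record sufficient to compute exact recovery errors for any
#' estimate: the generating parameters, realized tank intercepts, latent
#' fluxes, and centered covariates.
#'
#' @param config A [synthetic_config()].
#' @return List with `data` (a validated `mesocosm_data` table; 240 rows in
#'   30 tanks at the default design) and `truth`.
#' @examples
#' exp1 <- generate_experiment(synthetic_config(seed = 42))
#' nrow(exp1$data)
#' @export
generate_experiment <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  temps <- simulate_temperatures(config)
  chla <- simulate_chla(config, temps)
  diel <- simulate_diel_oxygen(config, temps)
  zoop <- simulate_zooplankton(config, temps)

  data <- chla
  chla_truth <- attr(chla, "truth")
  diel_cols <- c("o2_dawn", "o2_dusk", "o2_dawn2", "t_dawn", "t_dusk",
                 "t_dawn2", "temp_dawn_C", "temp_dusk_C", "temp_dawn2_C")
  data[diel_cols] <- diel[diel_cols]
  data$daphnia_per10L <- zoop$daphnia_per10L
  data$copepod_per10L <- zoop$copepod_per10L
  data <- data[mesocosm_columns()]
  data <- validate_mesocosm(data)

  truth <- list(
    config = config,
    tank_intercepts = chla_truth$tank_intercepts,
    chla_eta = chla_truth$eta,
    covariates = chla_truth$covariates,
    nep = attr(diel, "truth")$nep,
    er = attr(diel, "truth")$er,
    missing_rows = attr(diel, "truth")$missing_rows
  )
  list(data = data, truth = truth)
}
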