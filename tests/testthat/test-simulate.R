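test_that("the default design matches the experimental layout", {
  exp1 <- default_experiment()
  d <- exp1$data
  expect_equal(nrow(d), 240)
  expect_equal(length(unique(d$tank_id)), 30)
  expect_equal(sort(unique(d$watts)), seq(0, 450, by = 50))
  expect_equal(sort(unique(d$week)), 2:9)
  expect_equal(table(d$treatment)[["A"]], 80)
  expect_equal(sum(!is.na(d$o2_dawn)), 219)
  expect_equal(length(exp1$truth$missing_rows), 21)
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_experiment(synthetic_config(seed = 123))
  b <- generate_experiment(synthetic_config(seed = 123))
  expect_identical(as.data.frame(a$data), as.data.frame(b$data))
  expect_identical(a$truth$nep, b$truth$nep)

  c2 <- generate_experiment(synthetic_config(seed = 124))
  expect_identical(as.data.frame(c2$data)[c("tank_id", "treatment", "watts",
                                            "week")],
                   as.data.frame(a$data)[c("tank_id", "treatment", "watts",
                                           "week")])
  expect_false(identical(c2$data$chla_ug_L, a$data$chla_ug_L))
})

test_that("component substreams are independent of each other", {
  base <- synthetic_config(seed = 5)
  tweaked <- synthetic_config(seed = 5)
  tweaked$zoop_model$copepod_log_mean <- 2.5
  a <- generate_experiment(base)
  b <- generate_experiment(tweaked)
  expect_identical(a$data$temp_week_C, b$data$temp_week_C)
  expect_identical(a$data$chla_ug_L, b$data$chla_ug_L)
  expect_false(identical(a$data$copepod_per10L, b$data$copepod_per10L))
})

test_that("temperature model composes baseline, decline, heater, and noise", {
  cfg <- synthetic_config(seed = 2)
  cfg$temp_model <- list(baseline_start = 20, weekly_decline = 0,
                         heater_gain = 0, weekly_noise_sd = 0)
  temps <- simulate_temperatures(cfg)
  expect_true(all(temps$temp_week_C == 20))

  cfg$temp_model$weekly_decline <- 0.5
  cfg$temp_model$heater_gain <- 1.42
  temps2 <- simulate_temperatures(cfg)
  # same power level implies identical temperatures across treatments
  by_pw <- split(temps2$temp_week_C, paste(temps2$watts, temps2$week))
  expect_true(all(vapply(by_pw, function(v) max(v) - min(v), 0) == 0))
  # coldest vs warmest tank means differ by heater_gain * 4.5
  tank_means <- tapply(temps2$temp_week_C, temps2$tank_id, mean)
  expect_equal(max(tank_means) - min(tank_means), 1.42 * 4.5,
               tolerance = 1e-10)
  # declining trend within a tank
  one <- temps2[temps2$tank_id == temps2$tank_id[1], ]
  expect_true(all(diff(one$temp_week_C[order(one$week)]) < 0))

  # default parameters put tank means in the observed experimental range
  dflt <- simulate_temperatures(synthetic_config(seed = 3))
  rng <- range(tapply(dflt$temp_week_C, dflt$tank_id, mean))
  expect_gt(rng[1], 17); expect_lt(rng[2], 29)
})

test_that("deterministic chlorophyll forms exact ln-linear treatment fans", {
  cfg <- noiseless_config()
  temps <- simulate_temperatures(cfg)
  chla <- simulate_chla(cfg, temps)
  cov <- mesotherm:::generating_covariates(chla)
  m <- cfg$chla_model
  for (trt in c("A", "AG", "AGP")) {
    rows <- chla$treatment == trt
    z <- as.numeric(trt != "A")
    pred <- m$beta0 +
      (if (trt == "A") 0 else m$beta_treat[[trt]]) +
      (m$beta_within +
         (if (trt == "A") 0 else m$beta_treat_within[[trt]])) *
        cov$x_within[rows] +
      (m$beta_between +
         (if (trt == "A") 0 else m$beta_treat_between[[trt]])) *
        cov$x_between[rows] +
      m$beta_wb * cov$x_within[rows] * cov$x_between[rows]
    expect_equal(log(chla$chla_ug_L[rows]), pred, tolerance = 1e-12)
  }
})

test_that("chlorophyll spans a strong gradient in the grazer treatment", {
  # the default generating slope for the grazer-only treatment implies a
  # standing-stock decline of three orders of magnitude across a 10 C
  # span of ecosystem temperature (19.7 -> 29.7 C)
  m <- synthetic_config()$chla_model
  slope_ag <- m$beta_between + m$beta_treat_between[["AG"]]
  dx <- inv_kT(celsius_to_kelvin(19.7)) - inv_kT(celsius_to_kelvin(29.7))
  expect_gt(slope_ag * dx, log(1000))

  # and the realised data show a far steeper decline with predators absent
  # than in the other treatments
  d <- default_experiment()$data
  drop_by_trt <- sapply(c("A", "AG", "AGP"), function(trt) {
    rows <- d[d$treatment == trt, ]
    means <- tapply(log(rows$chla_ug_L), rows$watts, mean)
    unname(means[as.character(0)] - means[as.character(450)])
  })
  expect_gt(drop_by_trt[["AG"]], drop_by_trt[["A"]] + 2)
  expect_gt(drop_by_trt[["AG"]], drop_by_trt[["AGP"]] + 2)
  expect_gt(drop_by_trt[["AG"]], log(50))
})

test_that("diel construction inverts the flux estimators exactly", {
  exp1 <- default_experiment()
  fluxed <- mesotherm:::flux_table(exp1$data)
  ok <- !is.na(fluxed$nep)
  expect_equal(sum(ok), 219)
  expect_lt(max(abs(fluxed$nep[ok] - exp1$truth$nep[ok])), 1e-10)
  expect_lt(max(abs(fluxed$er[ok] - exp1$truth$er[ok])), 1e-10)

  # zero fluxes and equal temperatures give a flat profile
  cfg <- noiseless_config()
  cfg$flux_model$nep$beta0 <- -Inf
  cfg$flux_model$er$beta0 <- -Inf
  temps <- simulate_temperatures(cfg)
  diel <- simulate_diel_oxygen(cfg, temps)
  expect_equal(diel$o2_dusk - diel$o2_dawn,
               equilibrium_oxygen(diel$temp_dusk_C) -
                 equilibrium_oxygen(diel$temp_dawn_C))
})

test_that("zooplankton counts carry the configured structure", {
  exp1 <- default_experiment()
  d <- exp1$data
  expect_true(all(is.na(d$daphnia_per10L[d$treatment == "A"])))
  expect_true(all(d$daphnia_per10L[d$treatment != "A"] >= 0))
  expect_true(all(d$daphnia_per10L[d$treatment != "A"] ==
                    round(d$daphnia_per10L[d$treatment != "A"])))

  # vanishing rate produces all-zero counts (exercising ln(x+1))
  cfg <- synthetic_config(seed = 9)
  cfg$zoop_model$daphnia_log_mean <- -50
  temps <- simulate_temperatures(cfg)
  z <- simulate_zooplankton(cfg, temps)
  expect_true(all(z$daphnia_per10L[z$treatment != "A"] == 0))
  expect_equal(unique(ln_plus_one(z$daphnia_per10L[z$treatment != "A"])), 0)

  # Monte-Carlo mean of ln(count+1) increases with the intercept
  lo <- synthetic_config(seed = 11); hi <- synthetic_config(seed = 11)
  lo$zoop_model$copepod_log_mean <- 0.2
  hi$zoop_model$copepod_log_mean <- 2.0
  zl <- simulate_zooplankton(lo, simulate_temperatures(lo))
  zh <- simulate_zooplankton(hi, simulate_temperatures(hi))
  expect_gt(mean(ln_plus_one(zh$copepod_per10L), na.rm = TRUE),
            mean(ln_plus_one(zl$copepod_per10L), na.rm = TRUE))

  # predator suppression of Daphnia on the ln scale, in expectation
  cfg2 <- synthetic_config(seed = 13)
  cfg2$zoop_model$daphnia_log_mean <- 3  # high counts: ln is near-linear
  z2 <- simulate_zooplankton(cfg2, simulate_temperatures(cfg2))
  m_ag <- mean(log(z2$daphnia_per10L[z2$treatment == "AG"] + 1))
  m_agp <- mean(log(z2$daphnia_per10L[z2$treatment == "AGP"] + 1))
  expect_lt(abs((m_agp - m_ag) - cfg2$zoop_model$daphnia_predator_effect),
            0.12)
})

test_that("fitting the generating model back recovers the coefficients", {
  cfg <- synthetic_config(seed = 19)
  exp1 <- generate_experiment(cfg)
  des <- center_design(exp1$data, "chla_ug_L")
  fit <- fit_lmm(des, model_set_specs("phyto_biomass")[[1]])
  b <- coef(fit)
  se <- sqrt(diag(fit$vcov))
  m <- cfg$chla_model
  truth <- c(`(Intercept)` = m$beta0,
             inv_kT_within = m$beta_within,
             inv_kT_between = m$beta_between,
             `inv_kT_within:inv_kT_between` = m$beta_wb,
             treatmentAG = m$beta_treat[["AG"]],
             treatmentAGP = m$beta_treat[["AGP"]],
             `inv_kT_between:treatmentAG` = m$beta_treat_between[["AG"]],
             `inv_kT_between:treatmentAGP` = m$beta_treat_between[["AGP"]])
  z <- abs(b[names(truth)] - truth) / se[names(truth)]
  # all generating coefficients within 3 standard errors
  expect_true(all(z < 3))
})
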