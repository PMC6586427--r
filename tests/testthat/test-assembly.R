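test_that("reading a written dataset round-trips all records", {
  d <- default_experiment()$data
  path <- withr::local_tempfile(fileext = ".csv")
  write_mesocosm(d, path)
  back <- read_mesocosm(path)
  expect_equal(nrow(back), 240)
  expect_equal(length(unique(back$tank_id)), 30)
  expect_equal(as.data.frame(back)[mesocosm_columns()],
               as.data.frame(d)[mesocosm_columns()])
})

test_that("structural problems in input tables are hard errors", {
  d <- as.data.frame(default_experiment()$data)
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(paste(mesocosm_columns(), collapse = ","), path)
  expect_error(read_mesocosm(path), "empty")

  bad_trt <- d
  bad_trt$treatment[5] <- "AXP"
  write.csv(bad_trt, path, row.names = FALSE)
  expect_error(read_mesocosm(path), "AXP")

  dup <- rbind(d, d[17, ])
  write.csv(dup, path, row.names = FALSE)
  expect_error(read_mesocosm(path), "duplicate")

  expect_error(validate_mesocosm(d[, setdiff(names(d), "chla_ug_L")]),
               "chla_ug_L")
  expect_error(read_mesocosm(file.path(tempdir(), "no-such-file.csv")),
               "not found")
})

test_that("rows violating invariants are rejected and logged, not fatal", {
  d <- as.data.frame(default_experiment()$data)
  d$chla_ug_L <- as.character(d$chla_ug_L)
  d$chla_ug_L[10] <- "not-a-number"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, path, row.names = FALSE)
  expect_message(got <- read_mesocosm(path), "rejected")
  expect_equal(nrow(got), 239)
  rej <- attr(got, "rejected")
  expect_equal(nrow(rej), 1)
  expect_match(rej$reason, "chlorophyll")
})

test_that("column mapping adapts foreign dialects", {
  d <- as.data.frame(default_experiment()$data)
  names(d)[names(d) == "chla_ug_L"] <- "Chla"
  names(d)[names(d) == "tank_id"] <- "Tank"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, path, row.names = FALSE)
  got <- read_mesocosm(path, col_map = c(chla_ug_L = "Chla",
                                         tank_id = "Tank"))
  expect_equal(nrow(got), 240)
  expect_true(all(c("chla_ug_L", "tank_id") %in% names(got)))
  expect_error(read_mesocosm(path, col_map = c(chla_ug_L = "Chlorophyll")),
               "Chlorophyll")
})

test_that("ln(x+1) transform handles zero counts and preserves order", {
  expect_identical(ln_plus_one(0), 0)
  expect_equal(ln_plus_one(2), log(3))
  expect_equal(ln_plus_one(2), 1.0986, tolerance = 1e-4)
  counts <- c(0, 1, 3, 9, 50)
  expect_true(all(diff(ln_plus_one(counts)) > 0))
  expect_error(ln_plus_one(-1), "non-negative")
})

test_that("centering decomposes inverse temperature exactly", {
  d <- default_experiment()$data
  des <- center_design(d, "chla_ug_L")
  x <- inv_kT(celsius_to_kelvin(d$temp_week_C))
  recon <- des$inv_kT_within + des$inv_kT_between + attr(des, "grand_inv_kT")
  expect_equal(recon, x, tolerance = 1e-12)

  # within deviations sum to zero per tank; between is constant per tank
  within_sums <- tapply(des$inv_kT_within, des$tank_id, sum)
  expect_true(all(abs(within_sums) < 1e-12))
  between_spread <- tapply(des$inv_kT_between, des$tank_id,
                           function(v) max(v) - min(v))
  expect_true(all(between_spread == 0))
  # tank-level between values center on zero
  expect_lt(abs(mean(tapply(des$inv_kT_between, des$tank_id, unique))),
            1e-12)
})

test_that("centering handles constant-temperature and two-tank fixtures", {
  const_d <- data.frame(tank_id = "t1", treatment = "A", watts = 0,
                        week = 2:5, temp_week_C = 20, chla_ug_L = 3)
  des <- center_design(const_d, "chla_ug_L")
  expect_true(all(des$inv_kT_within == 0))

  two <- data.frame(tank_id = rep(c("t1", "t2"), each = 2),
                    treatment = "A", watts = 0, week = c(2, 3, 2, 3),
                    temp_week_C = c(20, 30, 25, 25), chla_ug_L = 2)
  des2 <- center_design(two, "chla_ug_L")
  x1 <- mean(inv_kT(celsius_to_kelvin(c(20, 30))))
  x2 <- inv_kT(celsius_to_kelvin(25))
  expect_equal(unique(des2$inv_kT_between[des2$tank_id == "t1"]),
               x1 - mean(c(x1, x2)))
  expect_equal(sum(tapply(des2$inv_kT_between, des2$tank_id, unique)), 0)

  single <- data.frame(tank_id = c("t1", "t2", "t2"), treatment = "A",
                       watts = 0, week = c(2, 2, 3),
                       temp_week_C = c(20, 21, 23), chla_ug_L = 1)
  expect_warning(des3 <- center_design(single, "chla_ug_L"), "single week")
  expect_equal(des3$inv_kT_within[des3$tank_id == "t1"], 0)
})

test_that("rows without a usable response are dropped and counted", {
  exp1 <- default_experiment()
  fluxed <- mesotherm:::flux_table(exp1$data)
  des <- center_design(fluxed, "nep")
  expect_equal(nrow(des), 219)
  expect_equal(attr(des, "n_dropped"), 21)

  with_zero <- as.data.frame(exp1$data)
  with_zero$chla_ug_L[c(3, 40)] <- 0
  des0 <- center_design(with_zero, "chla_ug_L")
  expect_equal(nrow(des0), 238)
  expect_equal(attr(des0, "n_dropped"), 2)
})

test_that("cascade pairing builds the log response ratio per power-week", {
  d <- data.frame(
    tank_id = c("AG_000", "AGP_000", "AG_050", "AGP_050"),
    treatment = c("AG", "AGP", "AG", "AGP"),
    watts = c(0, 0, 50, 50), week = 2,
    temp_week_C = c(20, 20.4, 22, 21.6),
    chla_ug_L = c(1, 10, 4, 4)
  )
  cs <- build_cascade_series(d)
  expect_equal(nrow(cs), 2)
  expect_equal(cs$ln_ratio[cs$watts == 0], log(10))
  expect_equal(cs$ln_ratio[cs$watts == 50], 0)
  expect_equal(cs$temp_week_C, c(20.2, 21.8))

  # swapping the treatment labels negates every ratio
  d_swap <- d
  d_swap$treatment <- c("AGP", "AG", "AGP", "AG")
  expect_equal(build_cascade_series(d_swap)$ln_ratio, -cs$ln_ratio)

  # unmatched power levels are skipped with a message
  expect_message(cs2 <- build_cascade_series(d[-4, ]), "unmatched")
  expect_equal(nrow(cs2), 1)
})

test_that("full-design cascade series has one row per complete pair-week", {
  d <- as.data.frame(default_experiment()$data)
  expect_equal(nrow(build_cascade_series(d)), 80)
  d$chla_ug_L[which(d$treatment == "AG" & d$week == 5)[1]] <- NA
  expect_equal(nrow(build_cascade_series(d)), 79)
})
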