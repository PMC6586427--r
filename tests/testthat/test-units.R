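test_that("inverse thermal energy transform is correct and monotone", {
  k <- 8.617e-5
  expect_equal(inv_kT(293.15), 1 / (k * 293.15))
  expect_equal(inv_kT(293.15), 39.587, tolerance = 1e-4)
  expect_equal(inv_kT(303.15), 38.281, tolerance = 1e-4)
  grid <- seq(270, 320, by = 2.5)
  expect_true(all(diff(inv_kT(grid)) < 0))
  expect_error(inv_kT(0), "positive")
  expect_error(inv_kT(-5), "positive")
})

test_that("Arrhenius factor is 1 at the reference point and log-linear in 1/kT", {
  expect_equal(arrhenius_factor(298.15, 298.15, e = 0.9), 1)
  expect_equal(arrhenius_factor(310, 290, e = 0), 1)
  expect_equal(arrhenius_factor(303.15, 293.15, e = 0.65), 2.337,
               tolerance = 1e-3)
  # recover -E as the regression slope of log(factor) on 1/kT
  for (e in c(-0.4, 0.32, 0.65, 1.2)) {
    temps <- seq(275, 315, length.out = 25)
    x <- inv_kT(temps)
    slope <- unname(coef(lm(log(arrhenius_factor(temps, 295, e)) ~ x))[2])
    expect_equal(slope, -e, tolerance = 1e-10)
  }
})

test_that("per-capita rate follows the Boltzmann-Arrhenius form", {
  p0 <- metabolic_params(b0 = 3.2, e = 0, alpha = 0)
  expect_equal(percapita_rate(0.1, 280, p0), 3.2)
  expect_equal(percapita_rate(5, 310, p0), 3.2)
  p1 <- metabolic_params(b0 = 1, e = 0.2, alpha = 1)
  expect_equal(percapita_rate(2, 300, p1), 2 * percapita_rate(1, 300, p1))
  p2 <- metabolic_params(b0 = 1, e = 0.65, alpha = 1)
  expect_equal(percapita_rate(1, 293.15, p2), exp(-0.65 * inv_kT(293.15)))
  expect_equal(percapita_rate(1, 293.15, p2), 6.6e-12, tolerance = 0.01)
  expect_error(percapita_rate(0, 300, p1), "positive")
})

test_that("mass-corrected average matches its definition and scaling law", {
  expect_equal(mass_corrected_average(c(0.2, 3, 17), alpha = 1), 1)
  m <- 4.2
  expect_equal(mass_corrected_average(m, alpha = 0.75), m^(0.75 - 1))
  expect_equal(mass_corrected_average(c(1, 8), 0.75), (1 + 8^0.75) / 9)
  expect_equal(mass_corrected_average(c(1, 8), 0.75), 0.6396,
               tolerance = 1e-4)
  # scale covariance: masses * c -> result * c^(alpha - 1)
  masses <- c(0.5, 1.2, 9)
  for (cc in c(0.1, 2, 30)) {
    expect_equal(mass_corrected_average(cc * masses, 0.6),
                 cc^(0.6 - 1) * mass_corrected_average(masses, 0.6))
  }
  expect_error(mass_corrected_average(numeric(), 0.75), "non-empty")
})

test_that("ecosystem rate aggregates community state and inverts exactly", {
  const <- phys_constants(t_c = 293.15)
  p <- metabolic_params(b0 = 2, e = 0.65, alpha = 1)
  st <- community_state(c(0.3, 0.7), volume = 1, alpha = 1)
  expect_equal(ecosystem_rate(st, 293.15, p, const), 2 * 1.0)

  # one 8-g individual, alpha = 0.75: mass correction 8^0.75/8
  p75 <- metabolic_params(b0 = 1.5, e = 0.4, alpha = 0.75)
  st8 <- community_state(8, volume = 1, alpha = 0.75)
  expect_equal(st8$mass_corr, 8^0.75 / 8)
  expect_equal(ecosystem_rate(st8, 300, p75, const),
               1.5 * arrhenius_factor(300, 293.15, 0.4) * 8 * 8^(-0.25))

  # halving all masses at alpha = 1 halves the rate
  st_half <- community_state(c(0.15, 0.35), volume = 1, alpha = 1)
  expect_equal(ecosystem_rate(st_half, 305, p, const),
               ecosystem_rate(st, 305, p, const) / 2)

  expect_warning(out <- ecosystem_rate(community_state(numeric()), 300, p,
                                       const), "empty")
  expect_equal(out, 0)
})

test_that("biomass inversion round-trips the ecosystem rate to machine precision", {
  const <- phys_constants(t_c = 295)
  set.seed(11)
  for (i in 1:25) {
    alpha <- runif(1, 0.4, 1)
    st <- community_state(rexp(sample(1:12, 1), rate = 2) + 0.01,
                          volume = runif(1, 0.5, 400), alpha = alpha)
    p <- metabolic_params(b0 = runif(1, 0.1, 5), e = runif(1, -1, 1.5),
                          alpha = alpha)
    temp <- runif(1, 278, 315)
    b_r <- ecosystem_rate(st, temp, p, const)
    m_b <- biomass_from_rate(b_r, temp, p, st$mass_corr, const)
    expect_equal(m_b, st$m_b, tolerance = 1e-12)
  }
  # at T = T_c the inversion is plain division
  p <- metabolic_params(b0 = 2, e = 0.8, alpha = 1)
  expect_equal(biomass_from_rate(1, 295, p, mass_corr = 0.5, const), 1)
  expect_error(biomass_from_rate(1, 295, p, mass_corr = 0, const), "divisor")
})

test_that("theoretical cascade log-ratio honours its symmetries", {
  const <- phys_constants()
  sym <- cascade_theory_params(b0_ag = 2, b0_agp = 2, masscorr_ag = 0.7,
                               masscorr_agp = 0.7, e_b_ag = 0.3,
                               e_b_agp = 0.3, e_m_ag = 0.1, e_m_agp = 0.1)
  for (temp in c(280, 295, 310)) {
    expect_equal(cascade_theory_lnratio(sym, temp, const), 0)
  }

  # first-order null: all E terms 0 makes the ratio temperature-independent
  null1 <- cascade_theory_params(b0_ag = 3, b0_agp = 1.2, masscorr_ag = 0.5,
                                 masscorr_agp = 0.9)
  vals <- sapply(c(278, 293, 308), function(temp) {
    cascade_theory_lnratio(null1, temp, const)
  })
  expect_equal(max(vals) - min(vals), 0)

  # single nonzero temperature dependence
  th <- cascade_theory_params(e_b_ag = 0.2)
  expect_equal(cascade_theory_lnratio(th, 293.15, const),
               -0.2 * inv_kT(293.15))
  expect_equal(cascade_theory_lnratio(th, 293.15, const), -7.92,
               tolerance = 1e-3)

  # antisymmetry under swapping the AG and AGP parameter sets
  a <- cascade_theory_params(b0_ag = 2.5, b0_agp = 0.8, masscorr_ag = 0.4,
                             masscorr_agp = 0.9, e_b_ag = 0.25,
                             e_b_agp = -0.1, e_m_ag = 0.05, e_m_agp = 0.3)
  b <- cascade_theory_params(b0_ag = 0.8, b0_agp = 2.5, masscorr_ag = 0.9,
                             masscorr_agp = 0.4, e_b_ag = -0.1,
                             e_b_agp = 0.25, e_m_ag = 0.3, e_m_agp = 0.05)
  for (temp in c(285, 300)) {
    expect_equal(cascade_theory_lnratio(a, temp, const),
                 -cascade_theory_lnratio(b, temp, const))
  }
})

test_that("activation energy sign conventions are coherent", {
  expect_equal(activation_energy(-0.65), 0.65)
  expect_equal(activation_energy(1.21, convention = "density"), 1.21)
  # a rate ~ exp(-E/kT) with positive E yields a negative slope on 1/kT
  temps <- seq(280, 310, 5)
  x <- inv_kT(temps)
  rate <- 2 * exp(-0.5 * x)
  slope <- unname(coef(lm(log(rate) ~ x))[2])
  expect_equal(activation_energy(slope), 0.5, tolerance = 1e-10)
})
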