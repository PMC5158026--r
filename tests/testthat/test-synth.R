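test_that("lognormal moment matching reproduces the closed form", {
  par <- lognormal_from_mean_median(2.20, 1.73)
  expect_equal(unname(par["meanlog"]), log(1.73))
  expect_equal(unname(par["sdlog"]), sqrt(2 * log(2.20 / 1.73)))
  # degenerate: mean = median is a point mass
  par0 <- lognormal_from_mean_median(3, 3)
  expect_equal(unname(par0["sdlog"]), 0)
  expect_error(lognormal_from_mean_median(1.5, 2), "mean < median")
  expect_error(lognormal_from_mean_median(1, 0))
})

test_that("matched lognormals reproduce mean and median within Monte-Carlo error", {
  n <- 1e5
  for (mm in list(c(2.20, 1.73), c(3.28, 2.98), c(1.67, 1.30))) {
    par <- lognormal_from_mean_median(mm[1], mm[2])
    x <- withr::with_seed(7, rlnorm(n, par["meanlog"], par["sdlog"]))
    se_mean <- sd(x) / sqrt(n)
    # asymptotic SE of the sample median: 1 / (2 f(med) sqrt(n))
    se_med <- 1 / (2 * dlnorm(mm[2], par["meanlog"], par["sdlog"]) * sqrt(n))
    expect_lt(abs(mean(x) - mm[1]), 3 * se_mean)
    expect_lt(abs(median(x) - mm[2]), 3 * se_med)
  }
})

test_that("non-growing truth parameters preserve the published means", {
  pars <- truth_params("nongrowing")
  m_load <- exp(pars$load["meanlog"] + pars$load["sdlog"]^2 / 2)
  m_unload <- exp(pars$unload["meanlog"] + pars$unload["sdlog"]^2 / 2)
  expect_equal(unname(m_load), 0.69)
  expect_equal(unname(m_unload), 1.67)
  # sdlog reused from the growing group per phase
  grow <- truth_params("growing")
  expect_equal(unname(pars$load["sdlog"]), unname(grow$load["sdlog"]))
  expect_equal(unname(pars$unload["sdlog"]), unname(grow$unload["sdlog"]))
})

test_that("truth pairs are hysteretic in distribution, strictly when clipped", {
  pars <- truth_params("growing")
  tru <- withr::with_seed(11, sample_truth_stiffness(2000, pars))
  expect_gt(mean(tru$k_unload_true), mean(tru$k_load_true))
  expect_gt(median(tru$k_unload_true), median(tru$k_load_true))
  expect_gt(mean(tru$k_unload_true >= tru$k_load_true), 0.85)
  strict <- withr::with_seed(11, sample_truth_stiffness(2000, pars, strict = TRUE))
  expect_true(all(strict$k_unload_true >= strict$k_load_true))
})

test_that("cohort sampling matches the species diameter distribution", {
  co <- sample_cohort("lily", 40, seed = 3)
  expect_lt(abs(mean(co$diameter_um) - 17.4), 3 * 2.5 / sqrt(40))
  expect_true(all(co$diameter_um > 0))
  expect_true(all(co$wall_thickness_um >= 0.1 & co$wall_thickness_um <= 0.3))
  expect_true(all(co$turgor_mpa >= 0.1 & co$turgor_mpa <= 0.4))

  # degenerate spread: all diameters exactly at the mean
  sp <- species_preset("lily")
  sp$tube_diameter_sd_um <- 1e-12
  co0 <- sample_cohort(sp, 5, seed = 1)
  expect_equal(co0$diameter_um, rep(17.4, 5), tolerance = 1e-9)

  # determinism
  expect_identical(sample_cohort("lily", 10, seed = 9), sample_cohort("lily", 10, seed = 9))
  expect_error(sample_cohort("lily", 5, seed = 1, turgor_range = c(0.4, 0.1)))
})

test_that("apex attenuation is the squared contact-angle cosine", {
  expect_equal(apex_attenuation(50, 8.7), 1)
  expect_equal(apex_attenuation(8.7, 8.7), 1)
  expect_equal(apex_attenuation(0, 8.7), 0)
  expect_equal(apex_attenuation(8.7 / 2, 8.7), 0.25) # cos^2(60 deg)
  x <- seq(0, 20, by = 0.5)
  f <- apex_attenuation(x, 8.7)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) >= 0))
})

test_that("noiseless linear curves show the series-spring raw slope", {
  # k_true 3 N/m against a 6 N/m sensor: raw dF/dz = 1/(1/3 + 1/6) = 2 N/m
  cu <- synthesize_curve(3, 3,
    sensor = quiet_sensor(6), beta = 0, contact_offset = 2
  )
  slope <- raw_contact_slope(cu, z_from = 2.3, z_to = max(cu$z_um) - 0.05)
  expect_equal(slope, 2, tolerance = 1e-6)

  # rigid-sensor limit: raw slope equals the sample stiffness
  cu2 <- synthesize_curve(3, 3,
    sensor = quiet_sensor(1e9), beta = 0, contact_offset = 2
  )
  slope2 <- raw_contact_slope(cu2, z_from = 2.3, z_to = max(cu2$z_um) - 0.05)
  expect_equal(slope2, 3, tolerance = 1e-6)
})

test_that("curves respect the protocol contract", {
  proto <- indentation_protocol()
  cu <- synthesize_curve(2.2, 3.3, sensor = sensor_spec(), seed = 4)
  expect_gte(nrow(cu), 50)
  # maximal force reached within one noise sd
  expect_lt(abs(max(cu$force_uN) - proto$max_force_un), 5 * 0.010 + 1e-9)
  # single global maximum region at the turn; baseline starts near zero
  expect_lt(abs(cu$force_uN[1]), 5 * 0.010)
  expect_equal(which.max(cu$z_um), which.max(cu$force_uN), tolerance = 3)
  # unreachable max force within stage travel is reported
  expect_error(
    synthesize_curve(0.05, 0.05, sensor = quiet_sensor(), beta = 0),
    "travel limit"
  )
  expect_error(synthesize_curve(-1, 1), "stiffness")
})

test_that("cohort simulation is deterministic and carries its answer key", {
  co <- sample_cohort("lily", 4, seed = 21)
  s1 <- simulate_cohort(co, indentations = 9, seed = 5)
  s2 <- simulate_cohort(co, indentations = 9, seed = 5)
  expect_identical(s1$curves, s2$curves)
  expect_identical(s1$manifest$curve_index, s2$manifest$curve_index)
  expect_equal(length(s1$curves), 9)
  # round-robin distribution: 9 = 3 + 2 + 2 + 2
  expect_equal(
    as.integer(table(s1$manifest$curve_index$tube_id)[co$tube_id]),
    c(3L, 2L, 2L, 2L)
  )
  expect_true(all(s1$manifest$curve_index$distance_from_tip_um >= 50))
  # capillary default stays two orders of magnitude below the stiffness
  expect_lte(
    s1$manifest$sensor$capillary_slope_nm,
    0.011 * median(co$k_load_true)
  )
})
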