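test_that("contact detection is exact on noiseless curves", {
  cu <- synthesize_curve(2.5, 3.5, sensor = quiet_sensor(), contact_offset = 2)
  ct <- detect_contact(cu)
  dz <- diff(cu$z_um[1:2])
  expect_lt(abs(ct$z0 - 2), dz)
})

test_that("contact detection stays within 3 sample spacings under noise", {
  err <- vapply(1:100, function(s) {
    k <- withr::with_seed(s, rlnorm(1, log(1.73), 0.69))
    cu <- synthesize_curve(k, 1.5 * k,
      sensor = sensor_spec(k_sensor = 10, force_noise_sd = 10, capillary_slope = 0.02),
      contact_offset = 2, seed = s
    )
    ct <- detect_contact(cu)
    abs(ct$z0 - 2) / diff(cu$z_um[1:2])
  }, numeric(1))
  expect_lt(stats::quantile(err, 0.95), 3)
  expect_lt(median(err), 1.5)
})

test_that("a curve without contact raises a clean error", {
  cu <- synthesize_curve(2, 3, sensor = quiet_sensor(), contact_offset = 2)
  flat <- cu
  flat$force_uN <- withr::with_seed(1, rnorm(nrow(cu), 0, 0.01))
  class(flat) <- class(cu)
  expect_error(detect_contact(flat), "no contact")
  expect_error(detect_contact(cu[1:30, ]), "pre-contact")
})

test_that("sensor cancellation recovers the truth exactly on linear curves", {
  for (ratio in c(0.5, 1, 5, 50)) {
    k_true <- 2.2
    ks <- ratio * k_true
    cu <- synthesize_curve(k_true, k_true,
      sensor = quiet_sensor(ks), beta = 0, contact_offset = 2
    )
    rec <- process_curve(cu, k_sensor = ks)
    expect_lt(abs(rec$k_load - k_true) / k_true, 1e-3)
    expect_lt(abs(rec$k_unload - k_true) / k_true, 1e-3)
    expect_gt(rec$r2_load, 0.999999)
  }
})

test_that("an infinite sensor stiffness is the identity correction", {
  cu <- synthesize_curve(2, 3, sensor = quiet_sensor(1e12), beta = 0)
  ct <- detect_contact(cu)
  pc <- cancel_sensor(cu, ct, k_sensor = Inf)
  sel <- which(cu$z_um >= ct$z0)
  expect_equal(pc$delta_um, cu$z_um[sel] - ct$z0, tolerance = 1e-12)
  # applying a null correction twice changes nothing
  pc2 <- cancel_sensor(cu, ct, k_sensor = Inf)
  expect_identical(pc$delta_um, pc2$delta_um)
})

test_that("a wrong sensor stiffness is flagged via negative indentations", {
  cu <- synthesize_curve(5, 7.5, sensor = quiet_sensor(5), beta = 0)
  ct <- detect_contact(cu)
  # claiming a much softer sensor than real over-subtracts deflection
  expect_warning(cancel_sensor(cu, ct, k_sensor = 2), "negative indentation")
})

test_that("apparent stiffness is the window slope", {
  # exact synthetic line F = 2 delta
  pc <- tibble::tibble(
    delta_um = seq(0, 2, length.out = 200),
    force_uN = 2 * seq(0, 2, length.out = 200),
    phase = "load"
  )
  class(pc) <- c("processed_curve", class(pc))
  for (w in c(0.1, 0.2, 0.5)) {
    st <- apparent_stiffness(pc, "load", window = w)
    expect_equal(st$k_nm, 2, tolerance = 1e-12)
    expect_equal(st$r2, 1)
  }
  expect_error(apparent_stiffness(pc[1:9, ], "load"), "too few")
})

test_that("the window slope of a nonlinear curve matches the analytic value", {
  k_true <- 2.2
  for (beta in c(0.05, 0.1, 0.2)) {
    cu <- synthesize_curve(k_true, k_true,
      sensor = quiet_sensor(), beta = beta, contact_offset = 2
    )
    rec <- process_curve(cu, k_sensor = 10)
    expected <- analytic_window_slope(k_true, beta)
    expect_equal(rec$k_load, expected, tolerance = 2e-3)
  }
})

test_that("measured hysteresis follows the generated truth ordering", {
  ok <- vapply(1:100, function(s) {
    kl <- withr::with_seed(s, rlnorm(1, log(1.73), 0.69))
    ku <- kl * withr::with_seed(s + 500, exp(abs(rnorm(1, 0.3, 0.2))))
    cu <- synthesize_curve(kl, ku, sensor = sensor_spec(capillary_slope = 0), seed = s)
    rec <- process_curve(cu, k_sensor = 10)
    rec$k_unload >= rec$k_load
  }, logical(1))
  expect_true(all(ok))
})

test_that("neglecting a 1% capillary slope biases stiffness by under 2%", {
  # at the study's measured stiffness levels (0.69-3.28 N/m) against the
  # 10 N/m sensor; the bias scales as cap * (1 + k/ks) * (1/k + 1/ks)
  for (k_true in c(0.69, 1.73, 2.20, 3.28)) {
    cu <- synthesize_curve(k_true, k_true,
      sensor = sensor_spec(
        k_sensor = 10, force_noise_sd = 0,
        capillary_slope = 0.01 * k_true
      ),
      beta = 0, contact_offset = 2
    )
    rec <- process_curve(cu, k_sensor = 10)
    expect_lt(abs(rec$k_load - k_true) / k_true, 0.02)
  }
})

test_that("end-to-end recovery is exact on noiseless linear cohorts", {
  co <- sample_cohort("lily", 6, seed = 2)
  sim <- simulate_cohort(co,
    indentations = 12, seed = 3,
    sensor = quiet_sensor(), beta = 0
  )
  rec <- process_cohort(sim)
  truth <- sim$manifest$tubes
  for (i in seq_len(nrow(rec))) {
    tr <- truth[truth$tube_id == rec$tube_id[i], ]
    expect_lt(abs(rec$k_load[i] - tr$k_load_true) / tr$k_load_true, 1e-3)
    expect_lt(abs(rec$k_unload[i] - tr$k_unload_true) / tr$k_unload_true, 1e-3)
  }
})
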