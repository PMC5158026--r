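make_records <- function(k_load, k_unload = k_load + 1,
                         tube_id = paste0("t", seq_along(k_load)),
                         group = "growing", distance = 60) {
  tibble::tibble(
    curve_id = paste0("c", seq_along(k_load)), tube_id = tube_id,
    group = group, distance_from_tip_um = distance,
    k_load = k_load, k_unload = k_unload,
    r2_load = 1, r2_unload = 1, z0_um = 2, window = 0.2
  )
}

test_that("cohort statistics pool indentations, not tube averages", {
  rec <- make_records(c(1, 2, 3), tube_id = c("t1", "t1", "t2"))
  st <- cohort_statistics(rec)
  load <- st[st$phase == "load", ]
  expect_equal(load$mean_nm, 2)
  expect_equal(load$median_nm, 2)
  expect_equal(load$n_tubes, 2L)
  expect_equal(load$m_indentations, 3L)
  expect_gte(load$m_indentations, load$n_tubes)
  # pooled convention: repeated indentations of one tube shift the mean
  rec2 <- make_records(c(1, 1, 1, 5), tube_id = c("a", "a", "a", "b"))
  expect_equal(cohort_statistics(rec2)$mean_nm[1], 2)
  expect_error(cohort_statistics(make_records(3)), "at least 2")
})

test_that("identical groups give a null comparison", {
  rec <- dplyr::bind_rows(
    make_records(c(1, 2, 3, 4), group = "a"),
    make_records(c(1, 2, 3, 4), group = "b")
  )
  cmp <- compare_groups(rec, "a", "b")
  expect_equal(cmp$estimate, 0)
  expect_equal(cmp$p.value, 1)
})

test_that("small-sample permutation p equals exhaustive enumeration", {
  rec <- dplyr::bind_rows(
    make_records(c(5.0, 4.0), group = "a"),
    make_records(c(1.0, 2.0), group = "b")
  )
  cmp <- compare_groups(rec, "a", "b")
  # brute force over all choose(4, 2) = 6 label splits
  pooled <- c(5, 4, 1, 2)
  splits <- utils::combn(4, 2)
  tper <- apply(splits, 2, function(i) mean(pooled[i]) - mean(pooled[-i]))
  tobs <- mean(c(5, 4)) - mean(c(1, 2))
  p_exh <- mean(abs(tper) >= abs(tobs) - 1e-12)
  expect_equal(cmp$p.value, p_exh)
  expect_match(cmp$method, "exact")
})

test_that("tidy and glance expose the comparison results", {
  rec <- dplyr::bind_rows(
    make_records(c(3, 4, 5), group = "a"),
    make_records(c(1, 1.5, 2), group = "b")
  )
  cmp <- compare_groups(rec, "a", "b", phase = "unload")
  td <- tidy(cmp)
  expect_equal(td$estimate, mean(c(3, 4, 5)) - mean(c(1, 1.5, 2)))
  expect_equal(td$phase, "unload")
  expect_equal(glance(cmp)$p.value, cmp$p.value)
})

test_that("growing vs non-growing cohorts separate significantly at study scale", {
  pvals <- vapply(1:5, function(s) {
    g <- sample_cohort("lily", 19, seed = s, group = "growing")
    ng <- sample_cohort("lily", 11, seed = s + 100, group = "nongrowing")
    simg <- simulate_cohort(g, indentations = 135, seed = s + 200)
    simn <- simulate_cohort(ng, indentations = 71, seed = s + 300)
    rec <- dplyr::bind_rows(process_cohort(simg), process_cohort(simn))
    compare_groups(rec, "growing", "nongrowing",
      n_perm = 999, seed = s
    )$p.value
  }, numeric(1))
  expect_true(all(pvals < 0.05))
})

test_that("the apex profile detects the built-in dome softening", {
  co <- sample_cohort("lily", 6, seed = 31)
  # uniform geometry and truth isolate the distance effect; distances start
  # where the attenuated stiffness still reaches 5 uN within the stage travel
  co$diameter_um <- 17.4
  co$k_load_true <- 2.2
  co$k_unload_true <- 3.3
  dists <- rep(seq(3, 17, by = 2), length.out = 72)
  sim <- simulate_cohort(co,
    indentations = 72, seed = 32, distances = dists,
    attenuate = TRUE
  )
  prof <- apex_profile(process_cohort(sim), bin_width = 2)
  # the profile rises over the dome then plateaus on the shank, so the
  # rank correlation is positive but tied at the top
  expect_gt(attr(prof, "rho"), 0.5)
  expect_lt(attr(prof, "p.value"), 0.05)
  expect_gt(prof$mean_nm[nrow(prof)], 3 * prof$mean_nm[1])

  # attenuation off: no gradient
  sim0 <- simulate_cohort(co,
    indentations = 72, seed = 32, distances = dists,
    attenuate = FALSE
  )
  prof0 <- apex_profile(process_cohort(sim0), bin_width = 2)
  expect_gt(attr(prof0, "p.value"), 0.05)

  # degenerate: a single bin is refused
  rec1 <- process_cohort(sim)
  rec1$distance_from_tip_um <- 3
  expect_error(apex_profile(rec1), "single distance bin")
})
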