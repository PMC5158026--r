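#' Reference apparent-stiffness statistics
#'
#' The published shank-region apparent-stiffness statistics used to calibrate
#' the empirical-mode generator: growing tubes (19 tubes, 135 indentations)
#' with loading mean/median 2.20/1.73 N/m and unloading mean/median
#' 3.28/2.98 N/m, and non-growing tubes (11 tubes, 71 indentations) with
#' loading mean 0.69 N/m and unloading mean 1.67 N/m (medians not reported).
#'
#' @return A tibble with columns `group`, `phase`, `mean_nm`, `median_nm`,
#'   `n_tubes`, `m_indentations`.
#' @export
cfm_reference_stats <- function() {
  tibble(
    group = rep(c("growing", "nongrowing"), each = 2),
    phase = rep(c("load", "unload"), 2),
    mean_nm = c(2.20, 3.28, 0.69, 1.67),
    median_nm = c(1.73, 2.98, NA_real_, NA_real_),
    n_tubes = c(19L, 19L, 11L, 11L),
    m_indentations = c(135L, 135L, 71L, 71L)
  )
}

#' Lognormal parameters from a mean and a median
#'
#' The unique lognormal with the given median and mean has
#' `meanlog = log(median)` and `sdlog^2 = 2 log(mean / median)`, from the
#' moment relations `median = exp(meanlog)` and
#' `mean = exp(meanlog + sdlog^2 / 2)`.
#'
#' @param mean Distribution mean (must be >= median).
#' @param median Distribution median (> 0).
#' @return Named numeric vector `c(meanlog, sdlog)` (usable directly with
#'   `rlnorm()`).
#' @examples
#' lognormal_from_mean_median(2.20, 1.73)
#' @export
lognormal_from_mean_median <- function(mean, median) {
  if (!(median > 0)) abort("median must be > 0")
  if (mean < median) {
    abort("mean < median: no lognormal has a mean below its median")
  }
  c(meanlog = log(median), sdlog = sqrt(2 * log(mean / median)))
}

#' Truth-distribution parameters for a measurement group
#'
#' Lognormal parameters of the per-tube true loading and unloading apparent
#' stiffness. For the growing group both phases are matched to the published
#' mean and median. For the non-growing group only means were published; the
#' growing group's `sdlog` is reused per phase and `meanlog` set to
#' `log(mean) - sdlog^2 / 2`, the minimal assumption that preserves the mean.
#'
#' @param group `"growing"` or `"nongrowing"`.
#' @return A list with elements `load` and `unload`, each
#'   `c(meanlog, sdlog)`, plus `group`.
#' @export
truth_params <- function(group = c("growing", "nongrowing")) {
  group <- match.arg(group)
  ref <- cfm_reference_stats()
  g <- function(gr, ph) ref[ref$group == gr & ref$phase == ph, ]
  grow_l <- lognormal_from_mean_median(g("growing", "load")$mean_nm, g("growing", "load")$median_nm)
  grow_u <- lognormal_from_mean_median(g("growing", "unload")$mean_nm, g("growing", "unload")$median_nm)
  if (group == "growing") {
    return(list(load = grow_l, unload = grow_u, group = group))
  }
  mk <- function(mean, sdlog) {
    sdlog <- unname(sdlog)
    c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  }
  list(
    load = mk(g("nongrowing", "load")$mean_nm, grow_l["sdlog"]),
    unload = mk(g("nongrowing", "unload")$mean_nm, grow_u["sdlog"]),
    group = group
  )
}

#' Draw correlated loading/unloading truth stiffness pairs
#'
#' Bivariate lognormal with the given marginals and a Gaussian copula of
#' correlation `rho` (default 0.8). Because the loading marginal has the
#' heavier right tail, no coupling can make `k_unload >= k_load` hold for
#' every draw while preserving both marginals; by default the marginals are
#' preserved exactly and the ordering holds in distribution (and for the
#' large majority of tubes). With `strict = TRUE` pairs are clipped to
#' `k_unload >= k_load`, which biases the unloading marginal slightly
#' upwards.
#'
#' @param n Number of pairs.
#' @param params A list as returned by [truth_params()].
#' @param rho Copula correlation in `[-1, 1]`.
#' @param strict Enforce `k_unload >= k_load` per pair by clipping.
#' @return A tibble with columns `k_load_true`, `k_unload_true` (N/m).
#' @export
sample_truth_stiffness <- function(n, params, rho = 0.8, strict = FALSE) {
  stopifnot(n >= 1, abs(rho) <= 1)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  kl <- exp(params$load["meanlog"] + params$load["sdlog"] * z1)
  ku <- exp(params$unload["meanlog"] + params$unload["sdlog"] * z2)
  if (strict) ku <- pmax(ku, kl)
  tibble(k_load_true = unname(kl), k_unload_true = unname(ku))
}

#' Simulate a cohort of virtual pollen tubes
#'
#' Draws tube geometry and, depending on the mode, either an empirical truth
#' stiffness pair (lognormal matched to the published group statistics) or a
#' mechanistic truth (Young's modulus drawn uniformly, loading stiffness
#' computed from the pressurized-shell forward model). Diameters are i.i.d.
#' normal truncated at zero; wall thickness and turgor are uniform over their
#' configured ranges (defaults follow the lily literature: wall thickness
#' 0.1-0.3 um, turgor 0.1-0.4 MPa).
#'
#' @param species A preset name (`"lily"`, `"arabidopsis"`) or a list as
#'   returned by [species_preset()].
#' @param n_tubes Number of tubes (>= 1).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param mode `"empirical"` or `"mechanistic"`.
#' @param group Measurement group; sets the empirical truth distribution and
#'   the `growing` flag.
#' @param thickness_range,turgor_range Uniform sampling ranges for wall
#'   thickness (um) and turgor (MPa).
#' @param E_range Uniform sampling range of the true Young's modulus (MPa),
#'   mechanistic mode only.
#' @param rho Loading/unloading copula correlation (empirical mode).
#' @param strict_hysteresis Clip pairs to `k_unload >= k_load`
#'   (see [sample_truth_stiffness()]).
#' @param hysteresis_ratio Unloading/loading stiffness ratio used in
#'   mechanistic mode; default is the ratio of the published growing-group
#'   means (3.28 / 2.20).
#' @param nu Poisson ratio of the wall (mechanistic mode).
#' @return A tibble with one row per tube: `tube_id`, `diameter_um`,
#'   `wall_thickness_um`, `turgor_mpa`, `growing`, `group`, `k_load_true`,
#'   `k_unload_true` (N/m), and `E_true_mpa` (mechanistic mode, else `NA`).
#' @examples
#' sample_cohort("lily", n_tubes = 5, seed = 1)
#' @export
sample_cohort <- function(species = "lily", n_tubes, seed,
                          mode = c("empirical", "mechanistic"),
                          group = c("growing", "nongrowing"),
                          thickness_range = c(0.1, 0.3),
                          turgor_range = c(0.1, 0.4),
                          E_range = c(20, 400),
                          rho = 0.8, strict_hysteresis = FALSE,
                          hysteresis_ratio = NULL, nu = 0.3) {
  mode <- match.arg(mode)
  group <- match.arg(group)
  if (is.character(species)) species <- species_preset(species)
  stopifnot(n_tubes >= 1)
  for (rg in list(thickness_range, turgor_range, E_range)) {
    if (length(rg) != 2 || rg[1] > rg[2]) abort("invalid range: need c(min, max) with min <= max")
    if (rg[1] <= 0) abort("physical ranges must be positive")
  }
  mu <- species$tube_diameter_mean_um
  sdd <- species$tube_diameter_sd_um

  withr::with_seed(seed, {
    # truncated normal at 0 by rejection; mean > 3 sd so rejections are rare
    d <- rnorm(n_tubes, mu, sdd)
    while (any(bad <- d <= 0)) d[bad] <- rnorm(sum(bad), mu, sdd)
    th <- runif(n_tubes, thickness_range[1], thickness_range[2])
    pg <- runif(n_tubes, turgor_range[1], turgor_range[2])

    if (mode == "empirical") {
      tru <- sample_truth_stiffness(n_tubes, truth_params(group),
        rho = rho, strict = strict_hysteresis
      )
      e_true <- rep(NA_real_, n_tubes)
    } else {
      e_true <- runif(n_tubes, E_range[1], E_range[2])
      ratio <- hysteresis_ratio %||% (3.28 / 2.20)
      kl <- vapply(seq_len(n_tubes), function(i) {
        pr <- shell_problem(
          E = e_true[i], t = th[i], d = d[i], p = pg[i], nu = nu
        )
        shell_stiffness(pr)$k_model
      }, numeric(1))
      tru <- tibble(k_load_true = kl, k_unload_true = ratio * kl)
    }

    tibble(
      tube_id = sprintf("tube_%03d", seq_len(n_tubes)),
      diameter_um = d,
      wall_thickness_um = th,
      turgor_mpa = pg,
      growing = group == "growing",
      group = group,
      k_load_true = tru$k_load_true,
      k_unload_true = tru$k_unload_true,
      E_true_mpa = e_true
    )
  })
}
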