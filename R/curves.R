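#' Detect the contact point of a raw curve
#'
#' A baseline line is fitted to the first 20% of the approach (removing the
#' capillary background slope); contact is the first sample whose detrended
#' force exceeds `threshold` baseline standard deviations for at least
#' `run_length` consecutive samples. The contact displacement `z0` is then
#' refined by intersecting a short line fit just past the crossing with the
#' baseline line, which removes the systematic lateness of a pure threshold
#' crossing under noise.
#'
#' @param curve A `raw_curve` (tibble with `time_s`, `z_um`, `force_uN`).
#' @param baseline_fraction Fraction of the approach used for the baseline
#'   fit (default 0.2); must contain at least 20 samples.
#' @param threshold Detection threshold in baseline standard deviations.
#' @param run_length Required consecutive above-threshold samples.
#' @param refine_n Samples in the post-crossing refinement fit.
#' @return A list with `index` (first above-threshold sample), `z0` (refined
#'   contact displacement, um), `baseline` (intercept, slope of the baseline
#'   line) and `noise_sd` (baseline residual SD, uN).
#' @export
detect_contact <- function(curve, baseline_fraction = 0.2, threshold = 5,
                           run_length = 5, refine_n = 25) {
  z <- curve$z_um
  f <- curve$force_uN
  turn <- which.max(z)
  nb <- floor(baseline_fraction * turn)
  if (nb < 20) abort("too few pre-contact samples for a baseline fit (need >= 20)")
  # The baseline window starts as the first 20% of the approach and shrinks
  # iteratively to stay clear of the detected contact: on soft samples the
  # stage travels far past contact, so a fixed fraction would swallow contact
  # data and inflate the noise estimate.
  idx <- turn
  for (it in 1:10) {
    bl <- lm(f[1:nb] ~ z[1:nb])
    b <- unname(coef(bl))
    res_sd <- sd(bl$residuals)
    thr <- threshold * res_sd + 1e-9
    resid_app <- f[1:turn] - (b[1] + b[2] * z[1:turn])
    above <- resid_app > thr
    # first index starting a run of run_length above-threshold samples
    run <- stats::filter(as.numeric(above), rep(1, run_length), sides = 1)
    hit <- which(run == run_length)
    if (length(hit) == 0) abort("no contact: force never exceeds the baseline threshold")
    idx <- hit[1] - run_length + 1L
    nb_new <- max(20L, floor(0.6 * idx))
    if (nb_new >= nb) break
    nb <- nb_new
  }

  # refine z0 by a piecewise-linear (hinge) changepoint fit on the detrended
  # approach: flat baseline up to the candidate contact, linear ramp beyond.
  # The forward window grows until the force is well clear of the noise, so
  # soft samples get proportionally longer windows; the threshold crossing
  # itself is systematically late by ~threshold/slope, which the hinge fit
  # removes.
  jfwd <- idx
  while (jfwd < turn && resid_app[jfwd] < 8 * thr &&
    jfwd - idx < max(refine_n, 600L)) {
    jfwd <- jfwd + 1L
  }
  jfwd <- min(max(jfwd, idx + refine_n - 1L), turn)
  c_lo <- max(nb + 1L, idx - (jfwd - idx) - run_length)
  cand <- c_lo:min(idx + run_length, jfwd - 5L)
  z0 <- z[idx]
  if (length(cand) >= 2) {
    win <- c_lo:jfwd
    r <- resid_app[win]
    zw <- z[win]
    # suffix sums over the window for O(1) ramp fits per candidate
    s_r2 <- rev(cumsum(rev(r^2)))
    s_rz <- rev(cumsum(rev(r * zw)))
    s_r <- rev(cumsum(rev(r)))
    s_z <- rev(cumsum(rev(zw)))
    s_z2 <- rev(cumsum(rev(zw^2)))
    n_sfx <- rev(seq_along(win))
    sse <- vapply(cand, function(cc) {
      k <- cc - c_lo + 2L # first ramp sample position within win
      zc <- z[cc]
      num <- s_rz[k] - zc * s_r[k]
      den <- s_z2[k] - 2 * zc * s_z[k] + n_sfx[k] * zc^2
      alpha <- if (den > 0) max(num / den, 0) else 0
      s_r2[1] - s_r2[k] + # flat part
        (s_r2[k] - 2 * alpha * num + alpha^2 * den)
    }, numeric(1))
    z0 <- z[cand[which.min(sse)]]
  }
  list(index = idx, z0 = z0, baseline = b, noise_sd = res_sd)
}

#' Cancel the sensor compliance from a raw curve
#'
#' The sensor is a spring in series with the sample, so part of the recorded
#' stage displacement is sensor deflection. The true indentation is
#' `delta = (z - z0) - F / k_sensor` for every in-contact sample. The force
#' is zeroed at the baseline value extrapolated to the contact point; the
#' residual capillary *slope* is deliberately not removed (it is two orders
#' of magnitude below the sample stiffness and its neglect biases the
#' stiffness by under 2%). Phases are split at the global force maximum.
#'
#' @param curve A `raw_curve`.
#' @param contact A contact descriptor from [detect_contact()]; computed on
#'   the fly if missing.
#' @param k_sensor Sensor stiffness, N/m (`Inf` = rigid sensor, identity
#'   correction).
#' @return A `processed_curve`: tibble with `delta_um`, `force_uN`, `phase`
#'   (`"load"`/`"unload"`), and contact metadata in attributes. Warns when
#'   more than 10% of in-contact indentations come out negative (symptom of
#'   a wrong `k_sensor` or contact point).
#' @export
cancel_sensor <- function(curve, contact = NULL, k_sensor) {
  if (!(k_sensor > 0)) abort("k_sensor must be > 0")
  if (is.null(contact)) contact <- detect_contact(curve)
  z <- curve$z_um
  f0 <- contact$baseline[1] + contact$baseline[2] * contact$z0
  f <- curve$force_uN - f0

  imax <- which.max(f)
  # z rises monotonically then falls, so the in-contact region z >= z0 is one
  # contiguous block spanning both phases
  sel <- which(z >= contact$z0)
  delta <- (z[sel] - contact$z0) - f[sel] / k_sensor
  phase <- ifelse(sel <= imax, "load", "unload")
  # diagnose only on loading: an unloading branch may legitimately dip below
  # the contact point (residual deformation / adhesion-like hysteresis)
  if (mean(delta[phase == "load"] < 0) > 0.10) {
    warn("more than 10% of loading samples have negative indentation; k_sensor or z0 may be wrong")
  }
  out <- tibble(delta_um = delta, force_uN = f[sel], phase = phase)
  attr(out, "meta") <- attr(curve, "meta")
  attr(out, "contact") <- contact
  attr(out, "k_sensor_nm") <- k_sensor
  class(out) <- c("processed_curve", class(out))
  out
}

#' Apparent stiffness of one phase
#'
#' Ordinary least-squares slope of force vs indentation restricted to the
#' region of maximum load: samples with `F >= (1 - window) * F_max`. The
#' default window is the top 20% of the force range.
#'
#' @param processed A `processed_curve` from [cancel_sensor()].
#' @param phase `"load"` or `"unload"`.
#' @param window Window fraction of the force range (default 0.2).
#' @return A one-row tibble: `phase`, `k_nm` (slope, N/m), `r2`, `n_window`,
#'   `window`. Errors when fewer than 10 samples fall in the window.
#' @export
apparent_stiffness <- function(processed, phase = c("load", "unload"),
                               window = 0.2) {
  phase <- match.arg(phase)
  if (!(window > 0 && window < 1)) abort("window must be in (0, 1)")
  fmax <- max(processed$force_uN)
  seg <- processed[processed$phase == phase &
    processed$force_uN >= (1 - window) * fmax, ]
  if (nrow(seg) < 10) {
    abort(sprintf("too few samples (%d) in the %s maximum-load window", nrow(seg), phase))
  }
  fit <- lm(force_uN ~ delta_um, data = seg)
  ssr <- sum(fit$residuals^2)
  sst <- sum((seg$force_uN - mean(seg$force_uN))^2)
  tibble(
    phase = phase,
    k_nm = unname(coef(fit)[2]),
    r2 = if (sst > 0) max(0, 1 - ssr / sst) else 1,
    n_window = nrow(seg),
    window = window
  )
}

#' Process one raw curve into a stiffness record
#'
#' Runs contact detection, sensor cancellation and window slope fits for both
#' phases.
#'
#' @param curve A `raw_curve`.
#' @param k_sensor Sensor stiffness, N/m.
#' @param window Window fraction (default 0.2).
#' @param ... Passed to [detect_contact()].
#' @return A one-row tibble: curve metadata (`curve_id`, `tube_id`, `group`,
#'   `distance_from_tip_um` when present), `k_load`, `k_unload` (N/m),
#'   `r2_load`, `r2_unload`, `z0_um`, `window`.
#' @export
process_curve <- function(curve, k_sensor, window = 0.2, ...) {
  ct <- detect_contact(curve, ...)
  pc <- cancel_sensor(curve, ct, k_sensor)
  kl <- apparent_stiffness(pc, "load", window)
  ku <- apparent_stiffness(pc, "unload", window)
  meta <- attr(curve, "meta") %||% list()
  tibble(
    curve_id = meta$curve_id %||% NA_character_,
    tube_id = meta$tube_id %||% NA_character_,
    group = meta$group %||% NA_character_,
    distance_from_tip_um = meta$distance_from_tip_um %||% NA_real_,
    k_load = kl$k_nm, k_unload = ku$k_nm,
    r2_load = kl$r2, r2_unload = ku$r2,
    z0_um = ct$z0, window = window
  )
}

#' Process a cohort of raw curves
#'
#' @param cohort A `cfm_cohort` (from [simulate_cohort()] or [read_cohort()]).
#' @param window Window fraction (default 0.2).
#' @param k_sensor Sensor stiffness override; defaults to the manifest value.
#' @return A tibble of stiffness records, one row per indentation.
#' @examples
#' co <- sample_cohort("lily", 3, seed = 1)
#' sim <- simulate_cohort(co, indentations = 6, seed = 2)
#' process_cohort(sim)
#' @export
process_cohort <- function(cohort, window = 0.2, k_sensor = NULL) {
  stopifnot(inherits(cohort, "cfm_cohort"))
  ks <- k_sensor %||% cohort$manifest$sensor$k_sensor_nm
  purrr::map_dfr(cohort$curves, process_curve, k_sensor = ks, window = window)
}
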