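#' Force-sensor specification
#'
#' @param k_sensor Sensor (cantilever/MEMS) stiffness, N/m. The sensor acts
#'   as a spring in series with the sample; its deflection `F / k_sensor` is
#'   part of the recorded stage displacement and is cancelled during
#'   processing.
#' @param force_noise_sd Additive Gaussian force noise, nN.
#' @param capillary_slope Weak background stiffness (N/m) from capillary
#'   forces on the immersed tip, acting over the whole stage travel. `NULL`
#'   means "choose at cohort-simulation time as 1% of the cohort's median
#'   loading stiffness", consistent with a background two orders of magnitude
#'   below the sample stiffness.
#' @return An object of class `sensor_spec`.
#' @export
sensor_spec <- function(k_sensor = 10, force_noise_sd = 10, capillary_slope = NULL) {
  if (!(k_sensor > 0)) abort("k_sensor must be > 0")
  if (force_noise_sd < 0) abort("force_noise_sd must be >= 0")
  structure(
    list(
      k_sensor_nm = k_sensor,
      force_noise_sd_nn = force_noise_sd,
      capillary_slope_nm = capillary_slope
    ),
    class = "sensor_spec"
  )
}

#' Micro-indentation protocol
#'
#' Defaults follow the published protocol: 5 uN maximal load, 2 um/s
#' loading/unloading speed, 800 nm tip diameter. The sample rate is an
#' instrument setting (500 Hz gives hundreds of samples per phase at 2 um/s).
#'
#' @param max_force Maximal loading force, uN.
#' @param speed Stage speed, um/s (loading and unloading).
#' @param sample_rate Sampling rate, Hz.
#' @param tip_diameter Indenter tip diameter, um.
#' @return An object of class `indentation_protocol`.
#' @export
indentation_protocol <- function(max_force = 5, speed = 2, sample_rate = 500,
                                 tip_diameter = 0.8) {
  if (!(max_force > 0 && speed > 0 && sample_rate > 0 && tip_diameter > 0)) {
    abort("max_force, speed, sample_rate and tip_diameter must be > 0")
  }
  structure(
    list(
      max_force_un = max_force, speed_um_s = speed,
      sample_rate_hz = sample_rate, tip_diameter_um = tip_diameter
    ),
    class = "indentation_protocol"
  )
}

#' Apical stiffness attenuation factor
#'
#' On the hemispherical apical dome the indentation direction meets the wall
#' at a contact angle below 90 degrees, so only a fraction of the reaction
#' force is sensed along the indentation axis. With `phi = acos(min(x/R, 1))`
#' the projected factor is `cos(phi)^2 = min(x/R, 1)^2`: 0 at the very tip
#' (tangential contact), 1 on the cylindrical shank (`x >= R`).
#'
#' @param distance_from_tip Distance from the tube tip along the axis, um.
#' @param tube_radius Tube radius, um.
#' @return Attenuation factor in `[0, 1]` (vectorised).
#' @examples
#' apex_attenuation(c(0, 4.35, 8.7, 50), tube_radius = 8.7)
#' @export
apex_attenuation <- function(distance_from_tip, tube_radius) {
  if (any(distance_from_tip < 0)) abort("distance_from_tip must be >= 0")
  if (!(tube_radius > 0)) abort("tube_radius must be > 0")
  pmin(distance_from_tip / tube_radius, 1)^2
}

#' Window slope factor of the mildly nonlinear contact law
#'
#' The generator's loading law is `F(delta) = k0 * delta * (1 + beta *
#' delta / delta_max)`. The ordinary least-squares slope of `F` vs `delta`
#' restricted to the region of maximum load (`F >= (1 - w) * F_max`) is
#' `factor(beta, w) * k0` with `factor > 1` for `beta > 0`. The generator
#' divides by this factor so that a tube's truth stiffness *is* the apparent
#' (window) stiffness an ideal noiseless fit recovers; `beta = 0` gives
#' factor 1 and exact closed forms.
#'
#' @param beta Relative quadratic nonlinearity (default 0.1).
#' @param window Window fraction `w` of the force range (default 0.2).
#' @return Scalar slope factor (>= 1 for `beta >= 0`).
#' @export
window_slope_factor <- function(beta, window = 0.2) {
  if (beta == 0) return(1)
  dm <- 1 / (1 + beta) # delta_max for k0 = 1, F_max = 1
  d <- seq(0, dm, length.out = 4001)
  f <- d * (1 + beta * d / dm)
  sel <- f >= (1 - window) * f[length(f)]
  unname(coef(lm(f[sel] ~ d[sel]))[2])
}

# Invert z - z0 = u + F(u)/ks for the contact law F(u) = k0*u*(1 + beta*u/du).
# Stable quadratic root; A >= 0 is the available travel past contact.
.contact_indentation <- function(A, k0, beta, du, ks) {
  b1 <- 1 + k0 / ks
  if (beta == 0) return(A / b1)
  c2 <- k0 * beta / (du * ks)
  2 * A / (b1 + sqrt(b1^2 + 4 * c2 * A))
}

#' Synthesize one raw force-displacement recording
#'
#' Emulates a single CFM indentation: the stage approaches at constant speed,
#' the tip contacts the tube at `contact_offset`, force follows a mildly
#' nonlinear contact law up to the protocol's maximal force, then the stage
#' retracts and force follows the (stiffer) unloading branch. The recorded
#' stage displacement includes the sensor's own deflection (`z =
#' contact_offset + delta + F / k_sensor`, springs in series), a weak
#' capillary background slope, and additive Gaussian force noise -- i.e. the
#' inverse of every correction the processing pipeline applies.
#'
#' @param k_load_true,k_unload_true True apparent loading/unloading stiffness
#'   of the tube, N/m (the window slope an ideal fit recovers; see
#'   [window_slope_factor()]).
#' @param sensor A [sensor_spec()]; `capillary_slope = NULL` is treated as 0
#'   for a single curve.
#' @param protocol An [indentation_protocol()].
#' @param contact_offset Stage travel before contact, um.
#' @param distance_from_tip Indentation position along the tube, um; with
#'   `attenuate = TRUE` and a finite `tube_radius`, positions on the apical
#'   dome attenuate the effective stiffness by [apex_attenuation()].
#' @param tube_radius Tube radius, um (`Inf` disables the dome geometry).
#' @param beta Loading-law nonlinearity (default 0.1; 0 gives exact lines).
#' @param attenuate Apply the apical attenuation factor.
#' @param seed Optional integer seed for the noise.
#' @param travel_limit Maximum stage travel, um; reaching the maximal force
#'   must be possible within it.
#' @param meta Named list of metadata stored on the curve (e.g. `tube_id`,
#'   `group`).
#' @return A `raw_curve`: a tibble with columns `time_s`, `z_um`, `force_uN`
#'   and metadata in attributes.
#' @examples
#' cu <- synthesize_curve(3, 6, sensor_spec(force_noise_sd = 0), seed = 1)
#' head(cu)
#' @export
synthesize_curve <- function(k_load_true, k_unload_true = k_load_true,
                             sensor = sensor_spec(),
                             protocol = indentation_protocol(),
                             contact_offset = 2, distance_from_tip = Inf,
                             tube_radius = Inf, beta = 0.1, attenuate = TRUE,
                             seed = NULL, travel_limit = 100, meta = list()) {
  if (!(k_load_true > 0 && k_unload_true > 0)) abort("truth stiffness must be > 0")
  if (beta < 0) abort("beta must be >= 0")
  ks <- sensor$k_sensor_nm
  fmax <- protocol$max_force_un
  att <- if (attenuate && is.finite(tube_radius)) {
    apex_attenuation(min(distance_from_tip, tube_radius), tube_radius)
  } else {
    1
  }
  if (att <= 0) abort("attenuation factor is 0 at the very tip: no reaction force")
  sf <- window_slope_factor(beta)
  k0l <- att * k_load_true / sf
  k0u <- att * k_unload_true / sf

  dl <- fmax / (k0l * (1 + beta)) # loading indentation at max force
  du <- fmax / (k0u * (1 + beta)) # unloading contact depth range
  dr <- dl - du                   # residual indentation where unloading force hits 0
  z_turn <- contact_offset + dl + fmax / ks
  if (z_turn > travel_limit) {
    abort(sprintf(
      "max_force unreachable within stage travel limit (need %.2f um, limit %.2f um)",
      z_turn, travel_limit
    ))
  }

  dt <- 1 / protocol$sample_rate_hz
  n_up <- max(ceiling(z_turn / (protocol$speed_um_s * dt)), 49)
  z_up <- seq(0, z_turn, length.out = n_up + 1)
  z <- c(z_up, rev(z_up)[-1])
  n <- length(z)
  phase_up <- seq_len(n) <= n_up + 1

  z0 <- contact_offset
  f <- numeric(n)
  # loading branch
  iu <- which(phase_up & z > z0)
  if (length(iu)) {
    u <- .contact_indentation(z[iu] - z0, k0l, beta, dl, ks)
    f[iu] <- k0l * u * (1 + beta * u / dl)
  }
  # unloading branch: indentation measured from the residual depth dr
  idn <- which(!phase_up & z > z0 + dr + 1e-12)
  if (length(idn)) {
    u <- .contact_indentation(z[idn] - z0 - dr, k0u, beta, du, ks)
    f[idn] <- k0u * u * (1 + beta * u / du)
  }

  cap <- sensor$capillary_slope_nm %||% 0
  f <- f + cap * z
  noise_un <- sensor$force_noise_sd_nn / 1000
  if (noise_un > 0) {
    f <- f + if (is.null(seed)) {
      rnorm(n, 0, noise_un)
    } else {
      withr::with_seed(seed, rnorm(n, 0, noise_un))
    }
  }

  out <- tibble(time_s = (seq_len(n) - 1) * dt, z_um = z, force_uN = f)
  attr(out, "meta") <- utils::modifyList(
    list(
      distance_from_tip_um = distance_from_tip,
      contact_offset_um = contact_offset,
      beta = beta
    ),
    meta
  )
  class(out) <- c("raw_curve", class(out))
  out
}

#' Simulate raw curves for a whole cohort
#'
#' Distributes indentations over the tubes of a cohort (round-robin), samples
#' indentation positions, and synthesizes one raw curve per indentation. The
#' result carries a manifest -- the seed, sensor, protocol and the per-tube
#' ground truth -- which is the hidden answer key for recovery tests and the
#' source of `k_sensor` during processing.
#'
#' @param cohort A cohort tibble from [sample_cohort()].
#' @param indentations Total number of indentations (distributed round-robin
#'   over tubes), or a per-tube integer vector. Default 7 per tube.
#' @param sensor A [sensor_spec()].
#' @param protocol An [indentation_protocol()].
#' @param seed Integer seed; fixed seed gives a fully deterministic cohort.
#' @param distance_range Uniform sampling range of the indentation position
#'   (um from the tip); the default 50-150 um stays on the shank (>= 50 um),
#'   where the published group statistics were measured.
#' @param distances Optional explicit vector of positions (recycled), e.g. an
#'   apex scan; overrides `distance_range`.
#' @param contact_offset,beta,attenuate,travel_limit Passed to
#'   [synthesize_curve()].
#' @return An object of class `cfm_cohort`: a list with `curves` (named list
#'   of `raw_curve`) and `manifest` (schema version, seed, sensor, protocol,
#'   truth table, curve index).
#' @examples
#' co <- sample_cohort("lily", 3, seed = 1)
#' sim <- simulate_cohort(co, indentations = 6, seed = 2)
#' names(sim$curves)
#' @export
simulate_cohort <- function(cohort, indentations = NULL,
                            sensor = sensor_spec(),
                            protocol = indentation_protocol(), seed,
                            distance_range = c(50, 150), distances = NULL,
                            contact_offset = 2, beta = 0.1, attenuate = TRUE,
                            travel_limit = 100) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1)
  n_tubes <- nrow(cohort)
  if (is.null(indentations)) indentations <- 7L * n_tubes
  if (length(indentations) == 1) {
    m <- as.integer(indentations)
    per <- rep(m %/% n_tubes, n_tubes)
    extra <- m %% n_tubes
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  } else {
    stopifnot(length(indentations) == n_tubes)
    per <- as.integer(indentations)
  }
  tube_of <- rep(seq_len(n_tubes), per)
  m <- length(tube_of)
  if (m < 1) abort("at least one indentation is required")

  cap <- sensor$capillary_slope_nm %||% (0.01 * median(cohort$k_load_true))
  if (cap > 0.02 * median(cohort$k_load_true)) {
    abort("capillary_slope exceeds 2% of the cohort's median stiffness")
  }
  sensor$capillary_slope_nm <- cap

  withr::with_seed(seed, {
    dist <- if (is.null(distances)) {
      runif(m, distance_range[1], distance_range[2])
    } else {
      rep_len(distances, m)
    }
    curves <- vector("list", m)
    for (i in seq_len(m)) {
      tb <- cohort[tube_of[i], ]
      curves[[i]] <- synthesize_curve(
        k_load_true = tb$k_load_true, k_unload_true = tb$k_unload_true,
        sensor = sensor, protocol = protocol,
        contact_offset = contact_offset,
        distance_from_tip = dist[i], tube_radius = tb$diameter_um / 2,
        beta = beta, attenuate = attenuate, seed = NULL,
        travel_limit = travel_limit,
        meta = list(
          curve_id = sprintf("curve_%04d", i),
          tube_id = tb$tube_id, group = tb$group
        )
      )
    }
  })
  names(curves) <- sprintf("curve_%04d", seq_len(m))

  index <- tibble(
    curve_id = names(curves),
    tube_id = cohort$tube_id[tube_of],
    group = cohort$group[tube_of],
    distance_from_tip_um = dist
  )
  manifest <- list(
    schema_version = .schema_version,
    species = attr(cohort, "species") %||% NA_character_,
    seed = seed,
    sensor = unclass(sensor),
    protocol = unclass(protocol),
    contact_offset_um = contact_offset,
    beta = beta,
    attenuate = attenuate,
    tubes = cohort,
    curve_index = index
  )
  structure(list(curves = curves, manifest = manifest), class = "cfm_cohort")
}
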