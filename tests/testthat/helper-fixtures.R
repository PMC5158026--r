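# Shared fixtures and independent oracles used across the suite.

quiet_sensor <- function(k_sensor = 10) {
  sensor_spec(k_sensor = k_sensor, force_noise_sd = 0, capillary_slope = 0)
}

# finite-difference slope of a raw curve's in-contact loading segment,
# independent of the processing pipeline
raw_contact_slope <- function(curve, z_from, z_to) {
  sel <- curve$z_um >= z_from & curve$z_um <= z_to &
    seq_along(curve$z_um) <= which.max(curve$z_um)
  z <- curve$z_um[sel]
  f <- curve$force_uN[sel]
  mean(diff(f) / diff(z))
}

# analytic OLS slope of the generator's loading law over the top-force
# window, computed by dense evaluation of the exact F(delta) expression
analytic_window_slope <- function(k_true, beta, window = 0.2, n = 20001) {
  sf <- tubecfm::window_slope_factor(beta, window)
  k0 <- k_true / sf
  dm <- 1 / (k0 * (1 + beta)) # F_max = 1
  d <- seq(0, dm, length.out = n)
  f <- k0 * d * (1 + beta * d / dm)
  sel <- f >= (1 - window) * max(f)
  unname(coef(lm(f[sel] ~ d[sel]))[2])
}

# Navier series for a simply supported rectangular plate Lx x Ly under a
# uniform circular patch load (radius a) at the centre: independent
# plate-limit oracle (sine basis in both directions, no curvature terms)
plate_patch_stiffness <- function(E, t, nu, Lx, Ly, a, mmax = 1200, nmax = 1200) {
  D <- E * t^3 / (12 * (1 - nu^2))
  m <- seq(1, mmax, by = 2)
  n <- seq(1, nmax, by = 2)
  lam <- m * pi / Lx
  mu <- n * pi / Ly
  k2 <- outer(lam^2, mu^2, "+")
  kk <- sqrt(k2)
  patch <- 2 * besselJ(kk * a, 1) / (kk * a)
  sm <- sin(lam * Lx / 2)
  sn <- sin(mu * Ly / 2)
  q <- patch * (4 / (Lx * Ly)) * outer(sm, sn)
  w <- sum(q * outer(sm, sn) / (D * k2^2))
  1 / w
}

make_growing_cohort <- function(seed, n_tubes = 19, m = 135, ...) {
  co <- sample_cohort("lily", n_tubes, seed = seed, group = "growing")
  simulate_cohort(co, indentations = m, seed = seed + 1000L, ...)
}
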