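#' Membrane pretension of a pressurized cylinder
#'
#' Pressure-vessel membrane forces of a thin-walled cylinder under internal
#' pressure: hoop tension `N_theta = p R`, axial tension `N_x = p R / 2`.
#'
#' @param p Internal (turgor) pressure, MPa.
#' @param R Cylinder radius, um.
#' @return Named numeric vector `c(N_theta, N_x)` in N/m.
#' @examples
#' pretension(0.2, 8.7)
#' @export
pretension <- function(p, R) {
  if (p < 0 || R <= 0) abort("need p >= 0 and R > 0")
  c(N_theta = p * R, N_x = p * R / 2)
}

#' Bending rigidity of the wall
#'
#' `D = E t^3 / (12 (1 - nu^2))`, in uN um (MPa um^3).
#'
#' @param E Young's modulus, MPa.
#' @param t Wall thickness, um.
#' @param nu Poisson ratio.
#' @return Bending rigidity, uN um.
#' @export
bending_rigidity <- function(E, t, nu = 0.3) {
  if (!(E > 0 && t > 0)) abort("E and t must be > 0")
  E * t^3 / (12 * (1 - nu^2))
}

#' Forward-model problem specification
#'
#' Geometry, material and load of the indentation forward model: a turgid,
#' linear-elastic, thin-walled circular cylinder of radius `R`, wall
#' thickness `t` and length `L`, simply supported at its ends, loaded by a
#' uniform radial pressure over a circular patch of radius `a` (half the
#' indenter tip diameter) at mid-length.
#'
#' @param E Young's modulus of the wall, MPa.
#' @param t Wall thickness, um (thin-shell regime `t / R <= 0.2`).
#' @param d Tube diameter, um (alternative to `R`).
#' @param R Tube radius, um.
#' @param p Turgor pressure, MPa (>= 0).
#' @param nu Poisson ratio in `[0, 0.5)`.
#' @param L Shell length, um; default `20 R` (end effects decay within the
#'   bending boundary layer, well short of the ends).
#' @param a Load patch radius, um; default 0.4 (800 nm tip).
#' @param F_max Reference load, uN (the model is linear, so the stiffness
#'   does not depend on it).
#' @return An object of class `shell_problem`.
#' @examples
#' shell_problem(E = 100, t = 0.2, d = 17.4, p = 0.2)
#' @export
shell_problem <- function(E, t, d = NULL, R = NULL, p, nu = 0.3,
                          L = NULL, a = 0.4, F_max = 5) {
  if (is.null(R)) {
    if (is.null(d)) abort("supply the tube diameter d or radius R")
    R <- d / 2
  }
  L <- L %||% (20 * R)
  if (!(E > 0 && t > 0 && R > 0 && L > 0 && a > 0)) abort("all dimensions must be > 0")
  if (p < 0) abort("p must be >= 0")
  if (t / R > 0.2) abort("thin-shell assumption violated: t/R > 0.2")
  if (L < 10 * R) abort("L must be >= 10 R to keep end effects away from the load")
  if (nu < 0 || nu >= 0.5) abort("nu must be in [0, 0.5)")
  structure(
    list(E = E, t = t, R = R, L = L, p = p, nu = nu, a = a, F_max = F_max),
    class = "shell_problem"
  )
}

# Fourier basis of the prestressed Donnell operator on a simply supported
# cylinder, for a patch load at mid-length. Only geometry (R, L, a) and the
# cutoff wavenumber enter; material and pressure scale precomputed vectors:
#   denom_mn = E * (ct(nu) t^3 k^4 + t lam^4 / (R^2 k^4)) + p * R (lam^2/2 + kap^2)
# with ct(nu) = 1 / (12 (1 - nu^2)). QS carries the patch-load Fourier
# coefficients, normalisation and the evaluation at the load centre, so that
#   w_center = sum(QS / denom),  k_model = F / w_center = 1 / sum(QS / denom).
.shell_basis <- function(R, L, a, kmax) {
  m <- seq(1, max(ceiling(kmax * L / pi), 5), by = 2) # even modes vanish at L/2
  lam <- m * pi / L
  n <- 0:max(ceiling(kmax * R), 4)
  kap <- n / R
  k2 <- outer(lam^2, kap^2, "+")
  k4 <- k2 * k2
  kk <- sqrt(k2)
  # uniform unit force over a disc of radius a: coefficient 2 J1(k a) / (k a)
  patch <- 2 * besselJ(kk * a, 1) / (kk * a)
  cn <- ifelse(n == 0, 2 * pi * R, pi * R)
  sgn <- sin(lam * L / 2) # = +-1 for odd m
  qs <- patch * (sgn / (L / 2)) * rep(1 / cn, each = length(lam)) * sgn
  list(
    k4 = as.vector(k4),
    memb = as.vector(outer(lam^4, rep(1, length(n))) / (R^2 * k4)),
    pret = as.vector(outer(lam^2 / 2, kap^2, "+") * R),
    qs = as.vector(qs),
    m_modes = length(lam), n_modes = length(n), kmax = kmax
  )
}

.shell_k_value <- function(basis, E, t, p, nu) {
  ct <- 1 / (12 * (1 - nu^2))
  denom <- E * (ct * t^3 * basis$k4 + t * basis$memb) + p * basis$pret
  1 / sum(basis$qs / denom)
}

.shell_kmax0 <- function(problem) {
  with(problem, {
    D <- bending_rigidity(E, t, nu)
    k_pret <- if (p > 0) (p * R / D)^0.25 else 0
    k_memb <- (E * t / (R^2 * D))^0.25
    max(2 * k_pret, 2 * k_memb, 4 / sqrt(R * t), 6 / a)
  })
}

#' Indentation stiffness of a pressurized thin shell (Fourier solution)
#'
#' Solves the linearized (Donnell) shallow-shell equations for the radial
#' deflection of a pressurized, simply supported cylinder under a uniform
#' circular patch load at mid-length, by double Fourier series. The modal
#' stiffness combines bending (`D k^4`), membrane stretching
#' (`E t lam^4 / (R^2 k^4)`) and the pressure pretension
#' (`N_x lam^2 + N_theta kap^2`). The apparent stiffness is
#' `k_model = F / w(load centre)`. The series is truncated adaptively: the
#' cutoff wavenumber is grown until the relative change falls below `tol`.
#'
#' @param problem A [shell_problem()].
#' @param tol Relative series-tail tolerance (default 1e-4).
#' @param kmax Optional fixed cutoff wavenumber (1/um); disables adaptivity
#'   (used for fixed-truncation comparisons).
#' @param growth Cutoff growth factor per adaptive round.
#' @param max_rounds Maximum adaptive rounds; non-convergence is reported via
#'   `converged = FALSE`, never silently.
#' @return A one-row tibble: `k_model` (N/m), `converged`, `rel_tail`,
#'   `kmax` (cutoff used), `m_modes`, `n_modes`.
#' @examples
#' shell_stiffness(shell_problem(E = 100, t = 0.2, d = 17.4, p = 0.2))
#' @export
shell_stiffness <- function(problem, tol = 1e-4, kmax = NULL, growth = 1.6,
                            max_rounds = 6) {
  stopifnot(inherits(problem, "shell_problem"))
  if (!is.null(kmax)) {
    b <- .shell_basis(problem$R, problem$L, problem$a, kmax)
    k <- .shell_k_value(b, problem$E, problem$t, problem$p, problem$nu)
    return(tibble(
      k_model = k, converged = NA, rel_tail = NA_real_,
      kmax = kmax, m_modes = b$m_modes, n_modes = b$n_modes
    ))
  }
  km <- .shell_kmax0(problem)
  b <- .shell_basis(problem$R, problem$L, problem$a, km)
  k_prev <- .shell_k_value(b, problem$E, problem$t, problem$p, problem$nu)
  for (i in seq_len(max_rounds)) {
    km <- km * growth
    b <- .shell_basis(problem$R, problem$L, problem$a, km)
    k <- .shell_k_value(b, problem$E, problem$t, problem$p, problem$nu)
    tail <- abs(k - k_prev) / abs(k)
    if (tail < tol) {
      return(tibble(
        k_model = k, converged = TRUE, rel_tail = tail,
        kmax = km, m_modes = b$m_modes, n_modes = b$n_modes
      ))
    }
    k_prev <- k
  }
  warn(sprintf("shell series not converged at kmax = %.1f (tail %.2g)", km, tail))
  tibble(
    k_model = k, converged = FALSE, rel_tail = tail,
    kmax = km, m_modes = b$m_modes, n_modes = b$n_modes
  )
}

#' Fast stiffness-vs-modulus evaluator
#'
#' Freezes the Fourier basis of a problem (geometry, pressure and truncation)
#' and returns a cheap function of the Young's modulus alone -- the workhorse
#' of the inversion. The truncation is chosen adaptively at `E_ref`; the
#' lower end of the modulus bracket is the most demanding (the pretension
#' boundary layer is sharpest there), so `E_ref` defaults to it.
#'
#' @param problem A [shell_problem()]; its `E` is ignored in the returned
#'   function.
#' @param E_ref Modulus at which the truncation is converged, MPa.
#' @param tol Relative series-tail tolerance.
#' @return A function `f(E)` returning `k_model` in N/m. Because the basis is
#'   fixed, `f` is exactly linear in `E` when `p = 0`.
#' @export
shell_stiffness_fun <- function(problem, E_ref = problem$E, tol = 1e-4) {
  stopifnot(inherits(problem, "shell_problem"))
  pr <- problem
  pr$E <- E_ref
  b <- .shell_basis_adaptive(pr, tol = tol)
  function(E) .shell_k_value(b, E, pr$t, pr$p, pr$nu)
}

# basis whose truncation is converged (relative tail < tol) for the given
# reference problem; returned for reuse across material parameters
.shell_basis_adaptive <- function(problem, tol = 1e-4, growth = 1.6,
                                  max_rounds = 6) {
  km <- .shell_kmax0(problem)
  k_prev <- NULL
  b <- .shell_basis(problem$R, problem$L, problem$a, km)
  k_prev <- .shell_k_value(b, problem$E, problem$t, problem$p, problem$nu)
  for (i in seq_len(max_rounds)) {
    km <- km * growth
    b <- .shell_basis(problem$R, problem$L, problem$a, km)
    k <- .shell_k_value(b, problem$E, problem$t, problem$p, problem$nu)
    if (abs(k - k_prev) / abs(k) < tol) {
      return(b)
    }
    k_prev <- k
  }
  warn(sprintf("shell basis not converged at kmax = %.1f", km))
  b
}

#' Parameter scan of the forward model
#'
#' Evaluates the model stiffness along a grid of one parameter, holding the
#' others fixed -- the parametric-study analogue used to show that turgor,
#' wall thickness, diameter and modulus all shape the apparent stiffness.
#' Stiffness increases strictly in `E`, `t` and `p`; the diameter trend is
#' reported without asserting a sign.
#'
#' @param base A [shell_problem()] providing the fixed parameters.
#' @param parameter One of `"E"`, `"t"`, `"p"`, `"d"`.
#' @param values Grid of parameter values.
#' @param ... Passed to [shell_stiffness()].
#' @return A tibble with `parameter`, `value`, `k_model`, `converged`.
#' @export
monotonicity_scan <- function(base, parameter = c("E", "t", "p", "d"),
                              values, ...) {
  parameter <- match.arg(parameter)
  stopifnot(inherits(base, "shell_problem"))
  purrr::map_dfr(values, function(v) {
    pr <- base
    if (parameter == "d") {
      pr <- shell_problem(
        E = base$E, t = base$t, R = v / 2, p = base$p, nu = base$nu,
        a = base$a, F_max = base$F_max
      )
    } else {
      pr[[parameter]] <- v
    }
    res <- shell_stiffness(pr, ...)
    tibble(
      parameter = parameter, value = v,
      k_model = res$k_model, converged = res$converged
    )
  })
}
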