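#' Finite-difference oracle for the shell stiffness
#'
#' Independent discretization of the same prestressed Donnell equations used
#' by [shell_stiffness()]: second-order central differences on the developed
#' cylinder surface (13-point biharmonic built as the squared 5-point
#' Laplacian), periodic circumferentially, simply supported at the ends, with
#' the coupled deflection/Airy-stress system
#' \deqn{D \nabla^4 w - N_x w_{xx} - N_\theta w_{ss} - \Phi_{xx}/R = q,
#'   \qquad \nabla^4 \Phi + (E t / R) w_{xx} = 0.}
#' The patch load is sampled on the grid and rescaled to unit total force.
#' Because the operator has constant coefficients and is periodic in the
#' circumferential direction, the finite-difference system is solved exactly
#' mode-by-mode: a DFT diagonalizes the circumferential direction and each
#' mode requires one small banded sparse solve in the axial direction.
#'
#' Intended as a verification oracle (tests, convergence studies), not as the
#' production solver.
#'
#' @param problem A [shell_problem()].
#' @param h Target grid spacing, um. Must resolve the patch radius and the
#'   bending boundary layer `sqrt(R t)` with at least 4 points each.
#' @return Stiffness `F / w(load centre)` in N/m (numeric scalar).
#' @examples
#' \donttest{
#' pr <- shell_problem(E = 100, t = 0.2, d = 17.4, p = 0.2, a = 1)
#' shell_stiffness_fd(pr, h = 0.25)
#' }
#' @export
shell_stiffness_fd <- function(problem, h = 0.1) {
  stopifnot(inherits(problem, "shell_problem"))
  R <- problem$R
  L <- problem$L
  a <- problem$a
  if (a / h < 4 - 1e-9 || sqrt(R * problem$t) / h < 4 - 1e-9) {
    abort(sprintf(
      "grid too coarse: h = %.3g does not resolve the patch radius (%.3g) or boundary layer (%.3g) with >= 4 points",
      h, a, sqrt(R * problem$t)
    ))
  }
  D <- bending_rigidity(problem$E, problem$t, problem$nu)
  nt <- pretension(problem$p, R)
  Nth <- nt["N_theta"]
  Nx <- nt["N_x"]

  nx <- 2L * ceiling(L / h / 2) # even: a node sits exactly at x = L/2
  hx <- L / nx
  ns <- 2L * ceiling(2 * pi * R / h / 2)
  hs <- 2 * pi * R / ns
  ni <- nx - 1L
  xi <- (1:ni) * hx
  sl <- (0:(ns - 1)) * hs
  sl[sl > pi * R] <- sl[sl > pi * R] - 2 * pi * R

  # unit total force over the patch, sampled on the grid
  q <- matrix(0, ni, ns)
  q[outer((xi - L / 2)^2, sl^2, "+") <= a^2] <- 1
  if (sum(q) == 0) abort("patch not resolved by the grid")
  q <- q / (sum(q) * hx * hs)
  qh <- t(apply(q, 1, function(row) Re(fft(row)))) # load is even in s

  Tm <- Matrix::bandSparse(ni,
    k = c(-1L, 0L, 1L),
    diagonals = list(rep(1, ni - 1), rep(-2, ni), rep(1, ni - 1))
  ) / hx^2
  Id <- Matrix::Diagonal(ni)
  icen <- which.min(abs(xi - L / 2))
  etr <- problem$E * problem$t / R

  wc <- 0
  for (j in 0:(ns / 2)) {
    sig <- 2 * (cos(2 * pi * j / ns) - 1) / hs^2
    lap <- Tm + sig * Id
    bih <- lap %*% lap
    A <- rbind(
      cbind(D * bih - Nx * Tm - Nth * sig * Id, -(1 / R) * Tm),
      cbind(etr * Tm, bih)
    )
    sol <- Matrix::solve(A, c(qh[, j + 1], rep(0, ni)))
    wj <- sol[icen]
    wc <- wc + if (j == 0 || j == ns / 2) wj else 2 * wj
  }
  1 / (wc / ns)
}
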