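#' Physiological parameter ranges for the inversion
#'
#' The box over which measured stiffness is inverted: wall thickness, turgor
#' and tube diameter ranges plus the modulus search bracket. Defaults: wall
#' thickness 0.1-0.3 um and turgor 0.1-0.4 MPa (lily literature values),
#' diameter 12.4-22.4 um (published mean +/- 2 SD), modulus bracket
#' 1-1000 MPa. A range may be a single value (degenerate axis).
#'
#' @param t_range Wall-thickness range, um.
#' @param p_range Turgor range, MPa.
#' @param d_range Tube-diameter range, um.
#' @param E_bracket Modulus search bracket, MPa (should cover at least
#'   1-1000).
#' @param n_grid Grid points per (non-degenerate) axis.
#' @return An object of class `param_ranges`.
#' @export
param_ranges <- function(t_range = c(0.1, 0.3), p_range = c(0.1, 0.4),
                         d_range = c(12.4, 22.4), E_bracket = c(1, 1000),
                         n_grid = 10) {
  chk <- function(rg, name) {
    if (length(rg) == 1) rg <- c(rg, rg)
    if (length(rg) != 2 || rg[1] > rg[2] || rg[1] <= 0) {
      abort(sprintf("invalid %s: need positive c(min, max) with min <= max", name))
    }
    rg
  }
  structure(
    list(
      t_range = chk(t_range, "t_range"), p_range = chk(p_range, "p_range"),
      d_range = chk(d_range, "d_range"),
      E_bracket = chk(E_bracket, "E_bracket"),
      n_grid = as.integer(n_grid)
    ),
    class = "param_ranges"
  )
}

.axis_grid <- function(rg, n) {
  if (rg[1] == rg[2]) rg[1] else seq(rg[1], rg[2], length.out = n)
}

#' Invert the forward model for the Young's modulus
#'
#' Finds the modulus at which the shell model reproduces a measured apparent
#' stiffness, for fixed wall thickness, turgor and diameter. The model
#' stiffness is continuous and strictly increasing in `E`, so the root is
#' unique when it exists; it is found by Brent root-finding on `log(E)` to a
#' relative tolerance of 1e-3. A target outside the attainable stiffness
#' range of the bracket yields status `"incompatible"` (with the attainable
#' range reported), not an error.
#'
#' @param k_target Measured apparent (loading) stiffness, N/m.
#' @param t,p,d Wall thickness (um), turgor (MPa), tube diameter (um).
#' @param E_bracket Modulus search bracket, MPa.
#' @param nu Poisson ratio.
#' @param a Load patch radius, um.
#' @param rel_tol Relative tolerance on `E`.
#' @param kfun Optional prebuilt evaluator from [shell_stiffness_fun()]
#'   (internal fast path).
#' @return A one-row tibble: `E_mpa`, `k_model`, `status` (`"ok"` /
#'   `"incompatible"`), `k_lo`, `k_hi` (attainable range over the bracket).
#' @examples
#' \donttest{
#' invert_modulus(2.20, t = 0.2, p = 0.2, d = 17.4)
#' }
#' @export
invert_modulus <- function(k_target, t, p, d, E_bracket = c(1, 1000),
                           nu = 0.3, a = 0.4, rel_tol = 1e-3, kfun = NULL) {
  if (!(k_target > 0)) abort("k_target must be > 0")
  if (is.null(kfun)) {
    pr <- shell_problem(E = E_bracket[1], t = t, d = d, p = p, nu = nu, a = a)
    kfun <- shell_stiffness_fun(pr, E_ref = E_bracket[1])
  }
  k_lo <- kfun(E_bracket[1])
  k_hi <- kfun(E_bracket[2])
  if (k_target < k_lo || k_target > k_hi) {
    return(tibble(
      E_mpa = NA_real_, k_model = NA_real_, status = "incompatible",
      k_lo = k_lo, k_hi = k_hi
    ))
  }
  root <- uniroot(
    function(u) kfun(exp(u)) - k_target,
    interval = log(E_bracket), tol = rel_tol,
    f.lower = k_lo - k_target, f.upper = k_hi - k_target
  )
  e <- exp(root$root)
  tibble(E_mpa = e, k_model = kfun(e), status = "ok", k_lo = k_lo, k_hi = k_hi)
}

#' Parameter combinations compatible with a measured stiffness
#'
#' Scans the physiological box on a grid of (wall thickness, turgor,
#' diameter); at every grid point the modulus is inverted against the target
#' stiffness. Grid points whose attainable stiffness range misses the target
#' by at most `tolerance * k_target` at a bracket edge contribute the edge
#' modulus ("similar stiffness" within tolerance); points further away are
#' incompatible. The spread `E_max / E_min` over the compatible rows
#' quantifies how ill-determined a single-modulus attribution is.
#'
#' @param k_target Measured apparent loading stiffness, N/m.
#' @param tolerance Relative stiffness-matching tolerance (default 0.10).
#' @param ranges A [param_ranges()].
#' @param nu Poisson ratio.
#' @param a Load patch radius, um.
#' @return An object of class `compatible_set`: list with `table` (tibble of
#'   compatible rows `t_um`, `p_mpa`, `d_um`, `E_mpa`, `k_model`), `E_min`,
#'   `E_max`, `k_target`, `tolerance`, `ranges`, `n_grid_points`, and
#'   attainable-stiffness diagnostics. Use [generics::tidy()] /
#'   [generics::glance()].
#' @examples
#' \donttest{
#' cs <- compatible_set(2.20, ranges = param_ranges(n_grid = 4))
#' glance(cs)
#' }
#' @export
compatible_set <- function(k_target, tolerance = 0.10,
                           ranges = param_ranges(), nu = 0.3, a = 0.4) {
  stopifnot(inherits(ranges, "param_ranges"))
  tg <- .axis_grid(ranges$t_range, ranges$n_grid)
  pg <- .axis_grid(ranges$p_range, ranges$n_grid)
  dg <- .axis_grid(ranges$d_range, ranges$n_grid)
  eb <- ranges$E_bracket

  rows <- vector("list", length(tg) * length(pg) * length(dg))
  att_lo <- Inf
  att_hi <- -Inf
  i <- 0L
  for (d in dg) {
    # one frozen basis per diameter: worst case is thinnest wall, lowest E
    pr0 <- shell_problem(E = eb[1], t = min(tg), d = d, p = max(pg), nu = nu, a = a)
    basis <- .shell_basis_adaptive(pr0)
    for (t in tg) {
      for (p in pg) {
        kfun <- local({
          t_ <- t; p_ <- p
          function(E) .shell_k_value(basis, E, t_, p_, nu)
        })
        res <- invert_modulus(k_target,
          t = t, p = p, d = d, E_bracket = eb,
          nu = nu, a = a, kfun = kfun
        )
        att_lo <- min(att_lo, res$k_lo)
        att_hi <- max(att_hi, res$k_hi)
        i <- i + 1L
        if (res$status == "ok") {
          rows[[i]] <- tibble(
            t_um = t, p_mpa = p, d_um = d,
            E_mpa = res$E_mpa, k_model = res$k_model
          )
        } else {
          # near miss at a bracket edge still counts as "similar stiffness"
          if (abs(res$k_lo - k_target) <= tolerance * k_target) {
            rows[[i]] <- tibble(
              t_um = t, p_mpa = p, d_um = d,
              E_mpa = eb[1], k_model = res$k_lo
            )
          } else if (abs(res$k_hi - k_target) <= tolerance * k_target) {
            rows[[i]] <- tibble(
              t_um = t, p_mpa = p, d_um = d,
              E_mpa = eb[2], k_model = res$k_hi
            )
          }
        }
      }
    }
  }
  table <- dplyr::bind_rows(rows)
  out <- structure(
    list(
      table = table,
      E_min = if (nrow(table)) min(table$E_mpa) else NA_real_,
      E_max = if (nrow(table)) max(table$E_mpa) else NA_real_,
      k_target = k_target, tolerance = tolerance, ranges = ranges,
      n_grid_points = i, n_compatible = nrow(table),
      attainable_k = c(lo = att_lo, hi = att_hi)
    ),
    class = "compatible_set"
  )
  if (nrow(table) == 0) {
    inform(sprintf(
      "empty compatible set: target %.3g N/m outside attainable range [%.3g, %.3g] N/m everywhere",
      k_target, att_lo, att_hi
    ))
  }
  out
}

#' @export
print.compatible_set <- function(x, ...) {
  cat(sprintf(
    "Compatible set for k_target = %.3g N/m (tolerance %.0f%%)\n",
    x$k_target, 100 * x$tolerance
  ))
  cat(sprintf(
    "  %d / %d grid points compatible; E in [%.3g, %.3g] MPa (spread %.1fx)\n",
    x$n_compatible, x$n_grid_points, x$E_min, x$E_max,
    if (x$n_compatible) x$E_max / x$E_min else NA_real_
  ))
  invisible(x)
}

#' Modulus-range report for measured cohort statistics
#'
#' Runs [compatible_set()] at the pooled loading mean and median of a group
#' and summarises the implied modulus ranges and per-parameter sensitivities.
#' Only the loading stiffness is inverted (the unloading branch carries
#' viscoelastic history). The report's central caveat: many parameter
#' combinations reproduce the same apparent stiffness, so attributing a
#' single modulus value to the wall is unsupported -- only a range is.
#'
#' @param stats A cohort-statistics tibble from [cohort_statistics()].
#' @param ranges A [param_ranges()].
#' @param group Group to report on (default `"growing"`).
#' @param tolerance Relative stiffness-matching tolerance.
#' @param ... Passed to [compatible_set()].
#' @return An object of class `modulus_report`: list with `at_mean` and
#'   `at_median` compatible sets, `sensitivity` (per-parameter modulus ranges
#'   at the mean), and `caveat`.
#' @export
stiffness_to_modulus_report <- function(stats, ranges = param_ranges(),
                                        group = "growing", tolerance = 0.10,
                                        ...) {
  row <- stats[stats$group == group & stats$phase == "load", ]
  if (nrow(row) != 1) abort("stats must contain one loading row for the group")
  cs_mean <- compatible_set(row$mean_nm, tolerance = tolerance, ranges = ranges, ...)
  cs_median <- compatible_set(row$median_nm, tolerance = tolerance, ranges = ranges, ...)
  sens <- if (cs_mean$n_compatible > 0) {
    purrr::map_dfr(c(t_um = "t_um", p_mpa = "p_mpa", d_um = "d_um"), function(col) {
      cs_mean$table |>
        dplyr::group_by(.data[[col]]) |>
        dplyr::summarise(
          E_min = min(.data$E_mpa), E_max = max(.data$E_mpa),
          .groups = "drop"
        ) |>
        dplyr::summarise(
          within_axis_spread = max(.data$E_max) / min(.data$E_min),
          .groups = "drop"
        )
    }, .id = "parameter")
  } else {
    tibble(parameter = character(), within_axis_spread = numeric())
  }
  structure(
    list(
      group = group, at_mean = cs_mean, at_median = cs_median,
      sensitivity = sens,
      caveat = paste(
        "Multiple (E, t, p, d) combinations reproduce the same apparent",
        "stiffness: a single-value modulus attribution is unsupported;",
        "only the reported range is."
      )
    ),
    class = "modulus_report"
  )
}

#' @export
print.modulus_report <- function(x, ...) {
  cat(sprintf("Modulus report, group '%s'\n", x$group))
  cat("at the pooled loading mean:\n  ")
  print(x$at_mean)
  cat("at the pooled loading median:\n  ")
  print(x$at_median)
  cat(sprintf("Caveat: %s\n", x$caveat))
  invisible(x)
}
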