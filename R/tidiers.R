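#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a permutation group comparison
#'
#' @param x A `cfm_group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return One-row tibble with `phase`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `estimate` (difference of means, N/m), `p.value`, `method`.
#' @export
tidy.cfm_group_comparison <- function(x, ...) {
  tibble(
    phase = x$phase,
    group_a = unname(x$groups["a"]), group_b = unname(x$groups["b"]),
    n_a = unname(x$n["a"]), n_b = unname(x$n["b"]),
    estimate = x$estimate, p.value = x$p.value, method = x$method
  )
}

#' @rdname tidy.cfm_group_comparison
#' @export
glance.cfm_group_comparison <- function(x, ...) {
  tibble(estimate = x$estimate, p.value = x$p.value, n_perm = x$n_perm)
}

#' Tidy a compatible set
#'
#' `tidy()` returns the full table of compatible parameter combinations;
#' `glance()` the one-row summary (modulus range and spread).
#'
#' @param x A `compatible_set` from [compatible_set()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.compatible_set <- function(x, ...) x$table

#' @rdname tidy.compatible_set
#' @export
glance.compatible_set <- function(x, ...) {
  tibble(
    k_target = x$k_target, tolerance = x$tolerance,
    n_grid_points = x$n_grid_points, n_compatible = x$n_compatible,
    E_min = x$E_min, E_max = x$E_max,
    E_spread = if (x$n_compatible > 0) x$E_max / x$E_min else NA_real_,
    attainable_k_lo = unname(x$attainable_k["lo"]),
    attainable_k_hi = unname(x$attainable_k["hi"])
  )
}

#' Tidy an apex profile
#'
#' @param x An `apex_profile` from [apex_profile()].
#' @param ... Unused.
#' @return `tidy()`: the binned table; `glance()`: one row with the Spearman
#'   trend statistic.
#' @export
tidy.apex_profile <- function(x, ...) as_tibble(x)

#' @rdname tidy.apex_profile
#' @export
glance.apex_profile <- function(x, ...) {
  tibble(
    rho = attr(x, "rho"), p.value = attr(x, "p.value"),
    phase = attr(x, "phase"), n_bins = nrow(x)
  )
}
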