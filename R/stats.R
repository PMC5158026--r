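#' Cohort stiffness statistics
#'
#' Per-group, per-phase mean, median and SD of the apparent stiffness, pooled
#' over indentations (not over per-tube averages), matching the reporting
#' convention "n tubes, m indentations" with a single pooled distribution.
#'
#' @param records A stiffness-record tibble from [process_cohort()].
#' @param group Optional grouping column name (default `"group"` when
#'   present, otherwise a single pooled group).
#' @return A tibble with columns `group`, `phase`, `n_tubes`,
#'   `m_indentations`, `mean_nm`, `median_nm`, `sd_nm`.
#' @export
cohort_statistics <- function(records, group = NULL) {
  stopifnot(is.data.frame(records))
  group <- group %||% (if ("group" %in% names(records)) "group" else NULL)
  rec <- records
  if (is.null(group)) {
    rec$group <- "all"
    group <- "group"
  }
  long <- tidyr::pivot_longer(
    dplyr::select(rec, dplyr::all_of(c(group, "tube_id", "k_load", "k_unload"))),
    c("k_load", "k_unload"),
    names_to = "phase", names_prefix = "k_", values_to = "k"
  )
  out <- long |>
    dplyr::group_by(.data[[group]], .data$phase) |>
    dplyr::summarise(
      n_tubes = dplyr::n_distinct(.data$tube_id),
      m_indentations = dplyr::n(),
      mean_nm = mean(.data$k),
      median_nm = median(.data$k),
      sd_nm = sd(.data$k),
      .groups = "drop"
    ) |>
    dplyr::rename(group = 1)
  if (any(out$m_indentations < 2)) {
    abort("cohort statistics need at least 2 records per group")
  }
  out
}

#' Permutation comparison of two groups
#'
#' Two-sided permutation test for the difference in mean apparent stiffness,
#' shuffling group labels at the indentation level. Stiffness distributions
#' are right-skewed (mean > median), so a label-permutation test is used
#' rather than a t test. For small samples all label assignments are
#' enumerated exactly; otherwise `n_perm` random permutations are drawn and
#' the p-value uses the add-one correction `(b + 1) / (n_perm + 1)`.
#'
#' @param records Stiffness-record tibble containing both groups.
#' @param a,b The two group labels to compare (values of `group_col`).
#' @param group_col Grouping column (default `"group"`).
#' @param phase `"load"` or `"unload"`.
#' @param n_perm Number of random permutations (>= 999) when not exhaustive.
#' @param seed Integer seed for the random permutations.
#' @param exact `"auto"` (enumerate when feasible), `"yes"` or `"no"`.
#' @return An object of class `cfm_group_comparison` with the observed
#'   difference of means (`a - b`), the p-value and test metadata. Use
#'   [generics::tidy()] for a tibble.
#' @export
compare_groups <- function(records, a, b, group_col = "group",
                           phase = c("load", "unload"), n_perm = 9999,
                           seed = 1, exact = c("auto", "yes", "no")) {
  phase <- match.arg(phase)
  exact <- match.arg(exact)
  if (n_perm < 999) abort("n_perm must be >= 999")
  col <- paste0("k_", phase)
  xa <- records[[col]][records[[group_col]] == a]
  xb <- records[[col]][records[[group_col]] == b]
  if (length(xa) == 0 || length(xb) == 0) abort("both groups must be non-empty")
  pooled <- c(xa, xb)
  na <- length(xa)
  n <- length(pooled)
  tobs <- mean(xa) - mean(xb)
  eps <- 1e-12 * (abs(tobs) + 1)

  do_exact <- exact == "yes" ||
    (exact == "auto" && choose(n, na) <= 5e4)
  if (do_exact) {
    idx <- utils::combn(n, na)
    tperm <- apply(idx, 2, function(i) mean(pooled[i]) - mean(pooled[-i]))
    p <- mean(abs(tperm) >= abs(tobs) - eps)
    method <- sprintf("exact permutation (%d splits)", ncol(idx))
    n_used <- ncol(idx)
  } else {
    tperm <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        sh <- sample.int(n, na)
        mean(pooled[sh]) - mean(pooled[-sh])
      }, numeric(1))
    })
    p <- (sum(abs(tperm) >= abs(tobs) - eps) + 1) / (n_perm + 1)
    method <- sprintf("random permutation (%d shuffles, add-one)", n_perm)
    n_used <- n_perm
  }
  structure(
    list(
      estimate = tobs, p.value = p, phase = phase,
      groups = c(a = a, b = b), n = c(a = na, b = length(xb)),
      method = method, n_perm = n_used
    ),
    class = "cfm_group_comparison"
  )
}

#' @export
print.cfm_group_comparison <- function(x, ...) {
  cat(sprintf(
    "Group comparison (%sing stiffness): %s (n=%d) vs %s (n=%d)\n",
    x$phase, x$groups["a"], x$n["a"], x$groups["b"], x$n["b"]
  ))
  cat(sprintf("  difference of means: %.4g N/m\n", x$estimate))
  cat(sprintf("  two-sided p = %.4g  [%s]\n", x$p.value, x$method))
  invisible(x)
}

#' Stiffness profile along the apex
#'
#' Bins stiffness records by distance from the tube tip and reports per-bin
#' means, together with a monotone-trend statistic (Spearman rank correlation
#' of bin means vs bin centres). On the apical dome the contact-angle
#' projection attenuates the measured stiffness, so growing tubes show a
#' rising profile towards the shank.
#'
#' @param records Stiffness-record tibble with `distance_from_tip_um`.
#' @param bin_width Bin width, um.
#' @param phase `"unload"` (the published profile) or `"load"`.
#' @return A tibble (`bin_center_um`, `mean_nm`, `sd_nm`, `n`) of class
#'   `apex_profile`, with attributes `rho` (Spearman), `p.value` and `phase`.
#'   Errors when all records fall in one bin.
#' @export
apex_profile <- function(records, bin_width = 2, phase = c("unload", "load")) {
  phase <- match.arg(phase)
  if (!"distance_from_tip_um" %in% names(records) ||
    all(is.na(records$distance_from_tip_um))) {
    abort("records must carry distance_from_tip_um")
  }
  col <- paste0("k_", phase)
  bins <- floor(records$distance_from_tip_um / bin_width)
  tab <- tibble(bin = bins, k = records[[col]]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      mean_nm = mean(.data$k), sd_nm = sd(.data$k), n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(bin_center_um = (.data$bin + 0.5) * bin_width) |>
    dplyr::arrange(.data$bin_center_um) |>
    dplyr::select("bin_center_um", "mean_nm", "sd_nm", "n")
  if (nrow(tab) < 2) abort("all records fall in a single distance bin")
  ct <- suppressWarnings(
    cor.test(tab$bin_center_um, tab$mean_nm, method = "spearman")
  )
  structure(tab,
    class = c("apex_profile", class(tab)),
    rho = unname(ct$estimate), p.value = ct$p.value, phase = phase
  )
}
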