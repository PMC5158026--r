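#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_errorbar
#'   geom_histogram labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a raw force-displacement recording
#'
#' @param object A `raw_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.raw_curve <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$z_um, y = .data$force_uN)) +
    geom_line(colour = "grey30") +
    labs(
      x = "stage displacement z (µm)", y = "force (µN)",
      title = "Raw CFM recording"
    ) +
    theme_minimal()
}

#' Plot a processed force-indentation curve
#'
#' @param object A `processed_curve` from [cancel_sensor()].
#' @param ... Unused.
#' @return A ggplot (colour = phase).
#' @export
autoplot.processed_curve <- function(object, ...) {
  ggplot(
    as_tibble(object),
    aes(x = .data$delta_um, y = .data$force_uN, colour = .data$phase)
  ) +
    geom_line() +
    labs(
      x = "indentation δ (µm)", y = "force (µN)",
      title = "True force-indentation curve", colour = "phase"
    ) +
    theme_minimal()
}

#' Plot an apex stiffness profile
#'
#' @param object An `apex_profile`.
#' @param ... Unused.
#' @return A ggplot of binned mean stiffness vs distance from the tip.
#' @export
autoplot.apex_profile <- function(object, ...) {
  tab <- as_tibble(object)
  ggplot(tab, aes(x = .data$bin_center_um, y = .data$mean_nm)) +
    geom_errorbar(
      aes(
        ymin = .data$mean_nm - .data$sd_nm,
        ymax = .data$mean_nm + .data$sd_nm
      ),
      width = 0.3, colour = "grey60"
    ) +
    geom_point() +
    geom_line(linetype = 2) +
    labs(
      x = "distance from tip (µm)",
      y = sprintf("apparent stiffness, %sing (N/m)", attr(object, "phase")),
      title = sprintf("Apex profile (Spearman rho = %.2f)", attr(object, "rho"))
    ) +
    theme_minimal()
}

#' Plot a compatible set
#'
#' Compatible moduli against each scanned parameter; the vertical spread at
#' fixed parameter value visualises how ill-determined the modulus is.
#'
#' @param object A `compatible_set`.
#' @param ... Unused.
#' @return A ggplot faceted by parameter.
#' @export
autoplot.compatible_set <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$table,
    c("t_um", "p_mpa", "d_um"),
    names_to = "parameter", values_to = "value"
  )
  ggplot(long, aes(x = .data$value, y = .data$E_mpa)) +
    geom_point(alpha = 0.4) +
    facet_wrap(~parameter, scales = "free_x") +
    ggplot2::scale_y_log10() +
    labs(
      x = "parameter value", y = "compatible E (MPa)",
      title = sprintf(
        "Moduli compatible with k = %.3g N/m (spread %.0fx)",
        object$k_target, object$E_max / object$E_min
      )
    ) +
    theme_minimal()
}

#' Histogram of apparent stiffness by group and phase
#'
#' @param records Stiffness records from [process_cohort()].
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_stiffness_distribution <- function(records, bins = 30) {
  long <- tidyr::pivot_longer(
    records, c("k_load", "k_unload"),
    names_to = "phase", names_prefix = "k_", values_to = "k_nm"
  )
  ggplot(long, aes(x = .data$k_nm, fill = .data$group)) +
    geom_histogram(bins = bins, position = "identity", alpha = 0.6) +
    facet_wrap(~phase) +
    labs(x = "apparent stiffness (N/m)", y = "indentations", fill = "group") +
    theme_minimal()
}
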