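#' Pollen-grain geometry
#'
#' A pollen grain is approximated by a prolate ellipsoid with a major and a
#' minor diameter. The minor diameter is the relevant dimension for channel
#' retention because a grain is free to rotate in the reservoir.
#'
#' @param major_diameter Major (long-axis) diameter, um.
#' @param minor_diameter Minor (short-axis) diameter, um.
#' @return An object of class `grain_spec`.
#' @examples
#' grain_spec(128.5, 98.3) # lily
#' @export
grain_spec <- function(major_diameter, minor_diameter) {
  stopifnot(is.numeric(major_diameter), is.numeric(minor_diameter))
  if (!(minor_diameter > 0)) abort("grain minor diameter must be > 0")
  if (major_diameter < minor_diameter) {
    abort("grain major diameter must be >= minor diameter")
  }
  structure(
    list(major_diameter_um = major_diameter, minor_diameter_um = minor_diameter),
    class = "grain_spec"
  )
}

#' Guidance-microchannel geometry
#'
#' @param width Channel width, um.
#' @param height Channel height, um.
#' @param length_min,length_max Shortest and longest channel length, mm.
#'   Optional; only used for reporting.
#' @return An object of class `channel_spec`.
#' @examples
#' channel_spec(25, 30, length_min = 2, length_max = 3.4) # lily design
#' @export
channel_spec <- function(width, height, length_min = NA_real_, length_max = NA_real_) {
  if (!(width > 0 && height > 0)) abort("channel width and height must be > 0")
  if (!is.na(length_min) && !is.na(length_max) && length_min > length_max) {
    abort("length_min must be <= length_max")
  }
  structure(
    list(
      width_um = width, height_um = height,
      length_min_mm = length_min, length_max_mm = length_max
    ),
    class = "channel_spec"
  )
}

#' Lab-on-a-chip layout
#'
#' A chip consists of identical unit cells, each holding a grain reservoir
#' from which a fan of guidance microchannels emerges.
#'
#' @param n_unit_cells Number of unit cells on the chip.
#' @param channels_per_cell Number of guidance channels per unit cell. May be
#'   `NA` when unknown (capacity is then undefined).
#' @param chamber_depth Depth of the grain reservoir, um.
#' @param channel A [channel_spec()].
#' @param footprint Chip footprint, mm (length-2 numeric), optional.
#' @return An object of class `chip_layout`.
#' @export
chip_layout <- function(n_unit_cells, channels_per_cell = NA_integer_,
                        chamber_depth = NA_real_, channel = NULL,
                        footprint = NULL) {
  if (!(n_unit_cells >= 1)) abort("n_unit_cells must be >= 1")
  if (!is.na(channels_per_cell) && channels_per_cell < 1) {
    abort("channels_per_cell must be >= 1 (or NA if unknown)")
  }
  structure(
    list(
      n_unit_cells = as.integer(n_unit_cells),
      channels_per_cell = as.integer(channels_per_cell),
      chamber_depth_um = chamber_depth,
      channel = channel,
      footprint_mm = footprint
    ),
    class = "chip_layout"
  )
}

#' Species presets
#'
#' Published geometry for the two species the chip was designed around:
#' grain ellipsoid diameters, tube diameter distribution, and chip layout.
#' The number of channels per unit cell of the Arabidopsis variant was never
#' reported, so its capacity is undefined unless supplied explicitly.
#'
#' @param species `"lily"` or `"arabidopsis"`.
#' @return A list with elements `label`, `tube_diameter_mean_um`,
#'   `tube_diameter_sd_um`, `grain` ([grain_spec()]) and `layout`
#'   ([chip_layout()]).
#' @examples
#' species_preset("lily")$tube_diameter_mean_um
#' @export
species_preset <- function(species = c("lily", "arabidopsis")) {
  species <- match.arg(species)
  switch(species,
    lily = list(
      label = "lily",
      tube_diameter_mean_um = 17.4,
      tube_diameter_sd_um = 2.5,
      grain = grain_spec(128.5, 98.3),
      layout = chip_layout(
        n_unit_cells = 9, channels_per_cell = 44, chamber_depth = 118.5,
        channel = channel_spec(25, 30, length_min = 2, length_max = 3.4),
        footprint = c(26, 10)
      )
    ),
    arabidopsis = list(
      label = "arabidopsis",
      tube_diameter_mean_um = 4.9,
      tube_diameter_sd_um = 0.7,
      grain = grain_spec(27.0, 19.9),
      layout = chip_layout(n_unit_cells = 40)
    )
  )
}

#' Theoretical guidance capacity of a chip
#'
#' Maximum number of tubes that can be guided simultaneously: unit cells
#' times channels per cell (e.g. 9 x 44 = 396 for the lily chip).
#'
#' @param layout A [chip_layout()].
#' @return Integer count.
#' @examples
#' layout_capacity(species_preset("lily")$layout)
#' @export
layout_capacity <- function(layout) {
  stopifnot(inherits(layout, "chip_layout"))
  if (is.na(layout$channels_per_cell)) {
    abort("capacity undefined: channels_per_cell is unknown for this layout")
  }
  layout$n_unit_cells * layout$channels_per_cell
}

#' Expected number of guided tubes per chip
#'
#' Unit cells times the mean number of tubes guided per cell, matching the
#' reported arithmetic (9 x 12 = 108 lily tubes, 6 x 40 = 240 Arabidopsis
#' tubes per device).
#'
#' @param layout A [chip_layout()].
#' @param mean_guided_per_cell Average number of guided tubes per unit cell;
#'   must not exceed the number of channels per cell (when known).
#' @return Count (numeric; integer-valued when the input is).
#' @examples
#' expected_guided(species_preset("lily")$layout, 12)
#' expected_guided(species_preset("arabidopsis")$layout, 6)
#' @export
expected_guided <- function(layout, mean_guided_per_cell) {
  stopifnot(inherits(layout, "chip_layout"))
  if (mean_guided_per_cell < 0) abort("mean_guided_per_cell must be >= 0")
  if (!is.na(layout$channels_per_cell) &&
    mean_guided_per_cell > layout$channels_per_cell) {
    abort("mean_guided_per_cell exceeds channels_per_cell: physically impossible")
  }
  res <- layout$n_unit_cells * mean_guided_per_cell
  if (isTRUE(all.equal(res, round(res)))) res <- as.integer(round(res))
  res
}

#' Geometric compatibility of grains, tubes and channels
#'
#' Checks the three conditions the channel cross-section must satisfy:
#' the grain must be retained in the reservoir (its minor diameter exceeds
#' the limiting channel dimension, using the minor axis because grains can
#' rotate), the tube must fit through the channel without constriction, and
#' the reservoir depth must force a grain monolayer. All comparisons are
#' strict inequalities (conservative).
#'
#' @param grain A [grain_spec()].
#' @param tube_diameter Tube diameter, um.
#' @param channel A [channel_spec()].
#' @param chamber_depth Grain reservoir depth, um.
#' @return A one-row tibble with logical flags `grain_retained`, `tube_fits`,
#'   `grain_monolayer`, the limiting channel dimension and the inputs.
#' @examples
#' lily <- species_preset("lily")
#' layout_compatibility(lily$grain, 17.4, lily$layout$channel, 118.5)
#' @export
layout_compatibility <- function(grain, tube_diameter, channel, chamber_depth) {
  stopifnot(inherits(grain, "grain_spec"), inherits(channel, "channel_spec"))
  if (!(tube_diameter > 0 && chamber_depth > 0)) {
    abort("tube_diameter and chamber_depth must be > 0")
  }
  lim <- min(channel$width_um, channel$height_um)
  tibble(
    grain_minor_um = grain$minor_diameter_um,
    tube_diameter_um = tube_diameter,
    channel_limit_um = lim,
    chamber_depth_um = chamber_depth,
    grain_retained = grain$minor_diameter_um > lim,
    tube_fits = tube_diameter < lim,
    grain_monolayer = chamber_depth < 2 * grain$minor_diameter_um
  )
}
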