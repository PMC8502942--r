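#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

pixel_tibble <- function(values, pitch, value_name) {
  ny <- nrow(values); nx <- ncol(values)
  out <- tibble::tibble(
    row = rep(seq_len(ny), times = nx),
    col = rep(seq_len(nx), each = ny),
    value = as.vector(values)
  )
  out$x_mm <- (out$col - 0.5) * pitch
  out$y_mm <- (out$row - 0.5) * pitch
  names(out)[names(out) == "value"] <- value_name
  out[, c("row", "col", "x_mm", "y_mm", value_name)]
}

#' Tidy pixel-level views of raster objects
#'
#' Each raster-like object tidies to one row per pixel with 1-based `row` /
#' `col` indices and physical pixel-center coordinates `x_mm` / `y_mm`
#' (origin top-left, y downward).
#'
#' @param x A `tissue_map`, `power_raster`, `absorbance_map` or `label_map`.
#' @param ... Unused.
#' @return A tibble with one row per pixel; the value column is `alpha`
#'   (mm^-1), `power`, or `label` as appropriate.
#' @name tidy-rasters
NULL

#' @rdname tidy-rasters
#' @export
tidy.tissue_map <- function(x, ...) pixel_tibble(x$alpha, x$pitch_mm, "alpha")

#' @rdname tidy-rasters
#' @export
tidy.power_raster <- function(x, ...) {
  out <- pixel_tibble(x$power, x$pitch_mm, "power")
  out$replicate_index <- x$replicate_index
  out
}

#' @rdname tidy-rasters
#' @export
tidy.absorbance_map <- function(x, ...) {
  pixel_tibble(x$alpha, x$pitch_mm, "alpha")
}

#' @rdname tidy-rasters
#' @export
tidy.label_map <- function(x, ...) {
  out <- pixel_tibble(x$labels, x$pitch_mm, "label")
  out$label <- factor(out$label, levels = label_levels)
  out
}

#' One-row summary of an absorbance map
#'
#' @param x An `absorbance_map`.
#' @param ... Unused.
#' @return One-row tibble with grid shape, pitch, thickness, frequency,
#'   alpha range, skin-correction state and replicates averaged.
#' @export
glance.absorbance_map <- function(x, ...) {
  tibble::tibble(
    n_rows = nrow(x$alpha), n_cols = ncol(x$alpha),
    pitch_mm = x$pitch_mm, thickness_mm = x$thickness_mm,
    frequency_ghz = x$frequency_ghz,
    alpha_min = min(x$alpha), alpha_max = max(x$alpha),
    skin_corrected = x$skin_corrected,
    n_replicates_averaged = x$n_replicates_averaged
  )
}

#' Calibration constants behind a volume estimate
#'
#' @param x A `volume_estimate` from [estimate_volume()].
#' @param ... Unused.
#' @return One-row tibble: `alpha_ref`, `v_cell`, `v_effective`, `sigma`, and
#'   the implied `v_per_delta_alpha = v_effective / alpha_ref` (mm^3 per
#'   mm^-1).
#' @export
glance.volume_estimate <- function(x, ...) {
  cal <- attr(x, "calibration")
  tibble::tibble(
    alpha_ref = cal$alpha_ref, v_cell = cal$v_cell,
    v_effective = cal$v_effective,
    sigma = cal$alpha_ref * cal$v_cell,
    v_per_delta_alpha = cal$v_effective / cal$alpha_ref
  )
}

#' @export
tidy.volume_estimate <- function(x, ...) tibble::as_tibble(x)

#' Plot an absorbance map with the clamped blue-to-red scale
#'
#' @param object An `absorbance_map`.
#' @param bands A [class_bands()] supplying the color-scale endpoints; alpha
#'   outside `[background_low, cancer_high]` is clamped for display only.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.absorbance_map <- function(object, bands = class_bands(), ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$alpha)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = blue_red_palette(256L),
      limits = c(bands$background_low, bands$cancer_high),
      oob = scales::squish,
      name = expression(alpha ~ (mm^-1))
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a label map
#'
#' @param object A `label_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.label_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(below_range = "grey85", background = "#2166AC",
                 cancer = "#B2182B", saturated = "#67001F"),
      drop = FALSE, name = "class") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot cohort absorption spectra with SEM ribbons
#'
#' @param object An `absorption_spectrum` tibble, or several row-bound
#'   together.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.absorption_spectrum <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency_ghz, .data$alpha_mean,
                                   colour = .data$tissue,
                                   fill = .data$tissue)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$alpha_mean - .data$alpha_sd,
                                      ymax = .data$alpha_mean + .data$alpha_sd),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "frequency (GHz)",
                  y = expression(alpha ~ (mm^-1))) +
    ggplot2::theme_minimal()
}
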