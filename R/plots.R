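# ggplot2 visualizations for images, EPIs, dictionaries and results.

#' @importFrom rlang .data
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

image_df <- function(mat) {
  tibble::tibble(
    row = rep(seq_len(nrow(mat)), times = ncol(mat)),
    col = rep(seq_len(ncol(mat)), each = nrow(mat)),
    value = as.vector(mat))
}

raster_theme <- function() {
  ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' Plot a raw light-field image
#'
#' @param object An `lfm_raw` (or any matrix).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lfm_raw
#' @export
autoplot.lfm_raw <- function(object, ...) {
  ggplot2::ggplot(image_df(unclass(object)),
                  ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "sensor column (px)", y = "sensor row (px)") +
    raster_theme()
}

#' Plot an epipolar-plane image
#'
#' @param object An `lfm_epi`.
#' @param ... Unused.
#' @return A ggplot; the angular axis runs vertically, the spatial axis
#'   horizontally, so depth appears as the tilt of the epipolar line.
#' @method autoplot lfm_epi
#' @export
autoplot.lfm_epi <- function(object, ...) {
  ggplot2::ggplot(image_df(unclass(object)),
                  ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(x = "spatial sample (lenslet)", y = "angular sample (pixel)",
                  title = paste(attr(object, "orientation"), "EPI")) +
    raster_theme()
}

#' Plot the atoms of an EPI dictionary
#'
#' @param object An `lfm_dictionary`.
#' @param ... Unused.
#' @return A ggplot facetted by atom depth, showing the increasing tilt of
#'   the epipolar line with depth.
#' @method autoplot lfm_dictionary
#' @export
autoplot.lfm_dictionary <- function(object, ...) {
  dfs <- lapply(seq_len(n_atoms(object)), function(m) {
    df <- image_df(object$atoms[m, , ])
    df$depth <- sprintf("%g um", object$depths[m])
    df
  })
  df <- dplyr::bind_rows(dfs)
  df$depth <- factor(df$depth, levels = unique(df$depth))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "amplitude") +
    ggplot2::facet_wrap(~depth) +
    ggplot2::labs(x = "spatial sample", y = "angular sample") +
    raster_theme()
}

#' Plot a localization result
#'
#' @param object An `lfm_localization`.
#' @param truth Optional truth table (`x_um`, `y_um`, `z_um`) overlaid as
#'   open circles.
#' @param ... Unused.
#' @return A ggplot of the lateral positions, coloured by depth.
#' @method autoplot lfm_localization
#' @export
autoplot.lfm_localization <- function(object, truth = NULL, ...) {
  p <- ggplot2::ggplot(object$sources,
                       ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                    colour = .data$z_um)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_viridis_c(name = "depth (um)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_point(data = tibble::as_tibble(truth),
                                 ggplot2::aes(x = .data$x_um, y = .data$y_um),
                                 inherit.aes = FALSE, shape = 1, size = 5)
  }
  p
}

#' Plot an angle-detection contrast curve
#'
#' @param calib An `lfm_calibration` from [calibrate_lightfield()] (must carry
#'   a contrast curve), or the attribute of [detect_rotation_angle()].
#' @return A ggplot of contrast against candidate angle for both search
#'   passes.
#' @export
plot_contrast_curve <- function(calib) {
  curve <- if (inherits(calib, "lfm_calibration")) calib$contrast_curve else calib
  if (is.null(curve)) stop("no contrast curve available", call. = FALSE)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$angle, y = .data$contrast,
                                      colour = .data$pass)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "candidate rotation angle (deg)", y = "intensity contrast") +
    ggplot2::theme_minimal()
}

#' Plot the depth-slope relation of a dictionary
#'
#' @param dict An `lfm_dictionary`.
#' @return A ggplot of the fitted epipolar-line slope of each atom against its
#'   depth.
#' @export
plot_depth_slope <- function(dict) {
  df <- tibble::tibble(
    depth_um = dict$depths,
    slope = vapply(seq_len(n_atoms(dict)), function(m) epi_slope(dict$atoms[m, , ]),
                   numeric(1)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_um, y = .data$slope)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "atom depth (um)", y = "epipolar-line slope (samples/sample)") +
    ggplot2::theme_minimal()
}
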