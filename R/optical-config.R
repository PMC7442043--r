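#' Optical configuration of a microlens-array light-field microscope
#'
#' Bundles every physical constant of the instrument needed by the forward
#' model, the calibration synthesis and the decoding geometry.  Lengths are in
#' micrometres throughout.
#'
#' @param wavelength Emission wavelength lambda (um).
#' @param magnification Objective-side magnification M (dimensionless).
#' @param numerical_aperture Objective NA (dimensionless, must not exceed
#'   `medium_refractive_index`).
#' @param lenslet_pitch MLA pitch d at the sensor plane (um).
#' @param mla_focal_length Focal length of the lenslets f_ML (um).
#' @param pixels_per_lenslet Integer vector `c(N_i, N_j)`, sensor pixels behind
#'   each lenslet along rows and columns; a scalar is recycled.
#' @param sensor_pixel_pitch Sensor pixel size (um).  Defaults to
#'   `lenslet_pitch / N_i` (the pitch is an integer number of pixels after
#'   calibration).
#' @param medium_refractive_index Refractive index of the immersion/sample
#'   medium (dimensionless).
#' @param lenslet_count Integer vector `c(K, L)`, number of lenslets along rows
#'   and columns of the simulated sensor; a scalar is recycled.
#' @param oversample Integer oversampling factor of the field grid relative to
#'   sensor pixels during wave propagation; intensities are integrated (binned)
#'   back to sensor pixels.
#' @param axial_range Largest |depth| (um) accepted by the forward model.
#'
#' @return An object of class `lfm_config` (a named list).
#'
#' @details The default values describe a 25x / NA 1.0 water-immersion
#'   epifluorescence microscope with an f/10 MLA of 125 um pitch placed at the
#'   native image plane and 19 x 19 sensor pixels behind each lenslet; the
#'   emission wavelength defaults to 0.52 um (green fluorophores).
#'
#' @examples
#' cfg <- optical_config(lenslet_count = 5)
#' cfg$sensor_pixel_pitch
#' @export
optical_config <- function(wavelength = 0.52,
                           magnification = 25,
                           numerical_aperture = 1.0,
                           lenslet_pitch = 125,
                           mla_focal_length = 1250,
                           pixels_per_lenslet = c(19, 19),
                           sensor_pixel_pitch = NULL,
                           medium_refractive_index = 1.33,
                           lenslet_count = c(15, 15),
                           oversample = 4,
                           axial_range = 60) {
  pixels_per_lenslet <- as.integer(rep(pixels_per_lenslet, length.out = 2))
  lenslet_count <- as.integer(rep(lenslet_count, length.out = 2))
  if (is.null(sensor_pixel_pitch)) {
    sensor_pixel_pitch <- lenslet_pitch / pixels_per_lenslet[1]
  }
  cfg <- structure(list(
    wavelength = wavelength,
    magnification = magnification,
    numerical_aperture = numerical_aperture,
    lenslet_pitch = lenslet_pitch,
    mla_focal_length = mla_focal_length,
    pixels_per_lenslet = pixels_per_lenslet,
    sensor_pixel_pitch = sensor_pixel_pitch,
    medium_refractive_index = medium_refractive_index,
    lenslet_count = lenslet_count,
    oversample = as.integer(oversample),
    axial_range = axial_range
  ), class = "lfm_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  num <- c("wavelength", "magnification", "numerical_aperture", "lenslet_pitch",
           "mla_focal_length", "sensor_pixel_pitch", "medium_refractive_index")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("optical_config: `", f, "` must be a single positive number", call. = FALSE)
    }
  }
  if (any(cfg$pixels_per_lenslet < 1L) || any(cfg$lenslet_count < 1L)) {
    stop("optical_config: pixel and lenslet counts must be positive integers", call. = FALSE)
  }
  if (cfg$numerical_aperture > cfg$medium_refractive_index) {
    stop("optical_config: numerical aperture cannot exceed the medium refractive index",
         call. = FALSE)
  }
  if (abs(cfg$pixels_per_lenslet[1] * cfg$sensor_pixel_pitch - cfg$lenslet_pitch) >
      cfg$sensor_pixel_pitch) {
    stop("optical_config: N_i * sensor_pixel_pitch must equal the lenslet pitch ",
         "to within one pixel", call. = FALSE)
  }
  if (cfg$oversample < 1L) stop("optical_config: oversample must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Desk-scale preset configuration
#'
#' The full-frame instrument geometry is expensive to simulate; this preset
#' keeps the per-lenslet geometry of [optical_config()] (19 x 19 pixels,
#' 125 um pitch, 25x, NA 1.0) but restricts the simulated sensor to a
#' 15 x 15 lenslet patch with 2x field oversampling so that end-to-end
#' simulations, dictionary builds and localization runs complete in minutes.
#'
#' @param ... Overrides passed on to [optical_config()].
#' @return An `lfm_config`.
#' @export
desk_config <- function(...) {
  args <- list(...)
  defaults <- list(lenslet_count = c(15, 15), oversample = 2)
  do.call(optical_config, utils::modifyList(defaults, args))
}

#' Read / write an optical configuration file
#'
#' Configurations are stored as YAML or JSON with keys exactly matching the
#' arguments of [optical_config()]; unknown keys are rejected.
#'
#' @param path File path; format chosen from the extension (`.yaml`, `.yml`,
#'   `.json`).
#' @return `read_optical_config()` returns an `lfm_config`;
#'   `write_optical_config()` returns `path` invisibly.
#' @export
read_optical_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(optical_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown optical configuration keys: ", paste(bad, collapse = ", "))
  do.call(optical_config, vals)
}

#' @rdname read_optical_config
#' @param cfg An `lfm_config`.
#' @export
write_optical_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "lfm_config"))
  vals <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' @export
print.lfm_config <- function(x, ...) {
  cat("<lfm_config>\n")
  cat(sprintf("  objective: %gx / NA %g (n = %g), lambda = %g um\n",
              x$magnification, x$numerical_aperture, x$medium_refractive_index,
              x$wavelength))
  cat(sprintf("  MLA: pitch %g um, f_ML %g um, %d x %d lenslets, %d x %d px each\n",
              x$lenslet_pitch, x$mla_focal_length, x$lenslet_count[1],
              x$lenslet_count[2], x$pixels_per_lenslet[1], x$pixels_per_lenslet[2]))
  cat(sprintf("  sensor: %d x %d px of %.4g um, field oversample %dx\n",
              sensor_dim(x)[1], sensor_dim(x)[2], x$sensor_pixel_pitch, x$oversample))
  invisible(x)
}

# sensor image size in pixels (rows, cols)
sensor_dim <- function(cfg) cfg$lenslet_count * cfg$pixels_per_lenslet

# physical coordinates of sensor pixel centres (um), origin on the optical axis
sensor_coords <- function(cfg) {
  n <- sensor_dim(cfg)
  px <- cfg$sensor_pixel_pitch
  list(y = ((seq_len(n[1])) - (n[1] + 1) / 2) * px,
       x = ((seq_len(n[2])) - (n[2] + 1) / 2) * px)
}

#' Field grid used during wave propagation
#'
#' The complex field is sampled on a grid `oversample` times finer than the
#' sensor pixels, covering exactly the sensor extent, with the optical axis at
#' the grid centre.
#'
#' @param cfg An `lfm_config`.
#' @return A list with components `y`, `x` (coordinate vectors, um) and
#'   `spacing` (um).
#' @export
field_grid <- function(cfg) {
  n <- sensor_dim(cfg) * cfg$oversample
  step <- cfg$sensor_pixel_pitch / cfg$oversample
  list(y = (seq_len(n[1]) - (n[1] + 1) / 2) * step,
       x = (seq_len(n[2]) - (n[2] + 1) / 2) * step,
       spacing = step)
}

config_hash <- function(cfg) {
  cache_key(cfg$wavelength, cfg$magnification, cfg$numerical_aperture,
            cfg$lenslet_pitch, cfg$mla_focal_length, cfg$pixels_per_lenslet,
            cfg$sensor_pixel_pitch, cfg$medium_refractive_index,
            cfg$lenslet_count, cfg$oversample)
}
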