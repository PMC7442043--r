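# Ground-truthed synthetic light-field generation (clean, rotated, noisy,
# scattering-like) and the localization evaluation harness.  Everything is a
# pure function of (inputs, configuration, seed).

# run code under a fixed seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Synthetic lenslet-grid image
#'
#' Analytic image of a bright-disc grid as produced by an out-of-focus
#' light-field exposure: one smooth disc per lenslet, evaluated directly on
#' (optionally rotated) sensor coordinates.  Because the pattern is evaluated
#' analytically there is no interpolation, which makes it an independent
#' fixture for the calibration detectors.
#'
#' @param n Image size in pixels, `c(rows, cols)`; a scalar is recycled.
#' @param pitch Lenslet pitch in pixels.
#' @param angle Grid rotation in degrees.
#' @param disc_radius Bright-disc radius in pixels.
#' @param softness Edge softness of the disc profile (pixels).
#' @param dark_fraction Fraction of lenslets dimmed to `dark_level` (for
#'   robustness fixtures); selected deterministically from `seed`.
#' @param dark_level Relative intensity of dimmed lenslets.
#' @param seed Seed used when `dark_fraction > 0`.
#' @return A matrix with attribute `centers`: the true disc centres as an
#'   `lfm_center_map`-style list (`row`, `col` matrices) for the unrotated
#'   grid cells that fit fully inside the image.
#' @export
lenslet_grid_image <- function(n = 285, pitch = 19, angle = 0, disc_radius = NULL,
                               softness = 1, dark_fraction = 0, dark_level = 0.15,
                               seed = 1) {
  n <- rep(as.integer(n), length.out = 2)
  if (is.null(disc_radius)) disc_radius <- 0.35 * pitch
  th <- angle * pi / 180
  cy <- (n[1] + 1) / 2; cx <- (n[2] + 1) / 2
  r <- matrix(seq_len(n[1]) - cy, n[1], n[2])
  c <- matrix(seq_len(n[2]) - cx, n[1], n[2], byrow = TRUE)
  # grid-aligned coordinates; convention matches rotate_bilinear(), i.e.
  # lenslet_grid_image(angle = a) ~ rotate_bilinear(lenslet_grid_image(0), a)
  u <- cos(th) * r - sin(th) * c
  v <- sin(th) * r + cos(th) * c
  # distance to the nearest lattice node of pitch p
  du <- u - pitch * round(u / pitch)
  dv <- v - pitch * round(v / pitch)
  rad <- sqrt(du^2 + dv^2)
  img <- 1 / (1 + exp((rad - disc_radius) / softness))
  ku <- round(u / pitch); kv <- round(v / pitch)
  if (dark_fraction > 0) {
    cells <- unique(data.frame(ku = as.vector(ku), kv = as.vector(kv)))
    ndark <- round(nrow(cells) * dark_fraction)
    dark <- with_local_seed(seed, cells[sample.int(nrow(cells), ndark), , drop = FALSE])
    key <- paste(ku, kv)
    img[key %in% paste(dark$ku, dark$kv)] <- img[key %in% paste(dark$ku, dark$kv)] * dark_level
  }
  if (angle == 0) {
    kk <- sort(unique(as.vector(ku))); ll <- sort(unique(as.vector(kv)))
    rows_c <- kk * pitch + cy; cols_c <- ll * pitch + cx
    keep_k <- rows_c - pitch / 2 >= 0.5 & rows_c + pitch / 2 <= n[1] + 0.5
    keep_l <- cols_c - pitch / 2 >= 0.5 & cols_c + pitch / 2 <= n[2] + 0.5
    attr(img, "centers") <- list(row = matrix(rows_c[keep_k], sum(keep_k), sum(keep_l)),
                                 col = matrix(cols_c[keep_l], sum(keep_k), sum(keep_l),
                                              byrow = TRUE))
  }
  img
}

# smooth strictly positive 1D profile for the rank-one background model
smooth_profile <- function(n, center_frac, width_frac) {
  x <- seq_len(n) / n
  0.4 + exp(-(x - center_frac)^2 / (2 * width_frac^2))
}

#' Generate a ground-truthed synthetic raw light-field
#'
#' Renders the listed sources with the wave-optics forward model, then applies
#' the requested corruptions in order: grid rotation, depth-dependent Gaussian
#' blur of the foreground (a scattering surrogate), a smooth rank-one
#' background, and additive Gaussian read noise.  With all corruption
#' parameters at zero the output equals [render_lightfield()] exactly.
#'
#' @param sources A data frame with columns `x`, `y`, `z` (um) and optional
#'   `intensity` (default 1) and `diameter` (um; default 10, use 0 for an
#'   ideal point source).
#' @param cfg An [optical_config()].
#' @param rotation Applied grid rotation (degrees).
#' @param noise_sd Gaussian read-noise standard deviation, as a fraction of
#'   the clean image maximum.
#' @param background_level Peak background intensity as a fraction of the
#'   clean image maximum, in `[0, 1)`; the background is the outer product of
#'   two smooth 1D profiles (rank one by construction).
#' @param blur_sd Gaussian blur sigma (pixels) applied to the foreground per
#'   unit depth (um); 0 disables the scattering surrogate.
#' @param grid_step Ball discretization step (um).
#' @param wrap_shift Passed to [render_lightfield()]; fixtures default to the
#'   periodic lateral boundary so off-axis sources reuse the on-axis PSF
#'   cache.
#' @param seed Integer seed; fixes the noise realization byte-for-byte.
#' @return A list of class `lfm_fixture`: `image` (`lfm_raw`), `truth`
#'   (tibble `source_id`, `x_um`, `y_um`, `z_um`, `intensity`), `clean`
#'   (uncorrupted image), `spec` (the generation parameters).
#' @export
make_fixture <- function(sources, cfg = desk_config(), rotation = 0, noise_sd = 0,
                         background_level = 0, blur_sd = 0, grid_step = 1,
                         wrap_shift = TRUE, seed = 1) {
  stopifnot(is.data.frame(sources), all(c("x", "y", "z") %in% names(sources)))
  if (!nrow(sources)) stop("make_fixture: no sources", call. = FALSE)
  if (background_level < 0 || background_level >= 1) {
    stop("make_fixture: background_level must be in [0, 1)", call. = FALSE)
  }
  intensity <- sources$intensity %||% rep(1, nrow(sources))
  diameter <- sources$diameter %||% rep(10, nrow(sources))
  img <- matrix(0, sensor_dim(cfg)[1], sensor_dim(cfg)[2])
  for (s in seq_len(nrow(sources))) {
    vol <- if (diameter[s] > 0) {
      discretize_ball(c(sources$x[s], sources$y[s], sources$z[s]), diameter[s], grid_step)
    } else {
      point_volume(c(sources$x[s], sources$y[s], sources$z[s]))
    }
    img <- img + intensity[s] * unclass(render_lightfield(vol, cfg, wrap_shift = wrap_shift))
  }
  clean <- img
  if (blur_sd > 0) {
    sigma <- blur_sd * mean(abs(sources$z))
    if (sigma > 0.3) {
      img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
    }
  }
  if (rotation != 0) img <- rotate_bilinear(img, rotation)
  if (background_level > 0) {
    bg <- outer(smooth_profile(nrow(img), 0.45, 0.35),
                smooth_profile(ncol(img), 0.6, 0.4))
    img <- img + background_level * max(clean) * bg / max(bg)
  }
  if (noise_sd > 0) {
    img <- img + with_local_seed(seed, matrix(
      stats::rnorm(length(img), sd = noise_sd * max(clean)), nrow(img)))
  }
  truth <- tibble::tibble(
    source_id = seq_len(nrow(sources)),
    x_um = sources$x, y_um = sources$y, z_um = sources$z,
    intensity = intensity)
  structure(list(image = as_lfm_raw(img, cfg), truth = truth,
                 clean = as_lfm_raw(clean, cfg),
                 spec = list(rotation = rotation, noise_sd = noise_sd,
                             background_level = background_level,
                             blur_sd = blur_sd, grid_step = grid_step,
                             seed = seed)),
            class = "lfm_fixture")
}

#' Evaluate localization against ground truth
#'
#' Matches predicted to true sources greedily by 3D nearest neighbour, then
#' reports per-source axial and lateral errors, per-axis and aggregate RMSE,
#' and the depth-accuracy fraction (|z error| within half a dictionary step).
#'
#' @param predicted An `lfm_localization` or a data frame with `x_um`, `y_um`,
#'   `z_um`.
#' @param truth A data frame with `x_um`, `y_um`, `z_um` (e.g. the `truth`
#'   element of a [make_fixture()] result).
#' @param depth_step Dictionary depth spacing (um) used for the depth-accuracy
#'   criterion.
#' @return A list of class `lfm_eval`: `matches` (tibble with predicted/true
#'   pairs and per-axis errors), `rmse` (named vector `x`, `y`, `z`,
#'   `lateral`, `overall` in um), `depth_accuracy` (fraction), `unmatched`
#'   (count of unmatched sources on either side).
#' @export
evaluate_localization <- function(predicted, truth, depth_step = 4) {
  pred <- if (inherits(predicted, "lfm_localization")) predicted$sources else
    tibble::as_tibble(predicted)
  stopifnot(all(c("x_um", "y_um", "z_um") %in% names(pred)),
            all(c("x_um", "y_um", "z_um") %in% names(truth)))
  np <- nrow(pred); nt <- nrow(truth)
  if (np != nt) {
    warning("evaluate_localization: ", np, " predicted vs ", nt,
            " true sources; extras reported as unmatched", call. = FALSE)
  }
  d2 <- outer(seq_len(np), seq_len(nt), function(i, j) {
    (pred$x_um[i] - truth$x_um[j])^2 + (pred$y_um[i] - truth$y_um[j])^2 +
      (pred$z_um[i] - truth$z_um[j])^2
  })
  pairs <- list()
  free_p <- seq_len(np); free_t <- seq_len(nt)
  while (length(free_p) && length(free_t)) {
    sub <- d2[free_p, free_t, drop = FALSE]
    ij <- arrayInd(which.min(sub), dim(sub))
    pairs[[length(pairs) + 1]] <- c(free_p[ij[1]], free_t[ij[2]])
    free_p <- free_p[-ij[1]]; free_t <- free_t[-ij[2]]
  }
  m <- do.call(rbind, pairs)
  matches <- tibble::tibble(
    predicted = m[, 1], true = m[, 2],
    x_error_um = pred$x_um[m[, 1]] - truth$x_um[m[, 2]],
    y_error_um = pred$y_um[m[, 1]] - truth$y_um[m[, 2]],
    z_error_um = pred$z_um[m[, 1]] - truth$z_um[m[, 2]])
  matches$lateral_error_um <- sqrt(matches$x_error_um^2 + matches$y_error_um^2)
  matches$axial_error_um <- abs(matches$z_error_um)
  rmse <- c(x = sqrt(mean(matches$x_error_um^2)),
            y = sqrt(mean(matches$y_error_um^2)),
            z = sqrt(mean(matches$z_error_um^2)),
            lateral = sqrt(mean(matches$lateral_error_um^2)))
  rmse["overall"] <- sqrt(mean(matches$x_error_um^2 + matches$y_error_um^2 +
                                 matches$z_error_um^2))
  structure(list(matches = matches, rmse = rmse,
                 depth_accuracy = mean(matches$axial_error_um <= depth_step / 2),
                 unmatched = (np - nrow(matches)) + (nt - nrow(matches))),
            class = "lfm_eval")
}

#' @export
print.lfm_eval <- function(x, ...) {
  cat(sprintf(
    "<lfm_eval> %d matched source(s); RMSE x %.3g, y %.3g, z %.3g um; depth accuracy %.0f%%\n",
    nrow(x$matches), x$rmse["x"], x$rmse["y"], x$rmse["z"], 100 * x$depth_accuracy))
  if (x$unmatched > 0) cat("  unmatched sources:", x$unmatched, "\n")
  invisible(x)
}
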