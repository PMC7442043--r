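# Automatic MLA calibration from a raw (out-of-focus) light-field image:
# rotation-angle detection by an intensity-contrast criterion, lenslet-pitch
# detection in the frequency domain, and lenslet-centre detection by
# convolution with disc-shaped kernels.

#' Rotate an image by bilinear interpolation
#'
#' Rotates about the image centre; samples falling outside the source image are
#' filled by edge replication, which keeps the column-sum statistic used for
#' angle detection free of artificial dark borders.
#'
#' @param image Numeric matrix.
#' @param angle Rotation angle in degrees (counter-clockwise).
#' @return The rotated matrix, same size as the input.
#' @export
rotate_bilinear <- function(image, angle) {
  if (angle == 0) return(image)
  n <- dim(image)
  th <- angle * pi / 180
  cy <- (n[1] + 1) / 2; cx <- (n[2] + 1) / 2
  r <- matrix(seq_len(n[1]) - cy, n[1], n[2])
  c <- matrix(seq_len(n[2]) - cx, n[1], n[2], byrow = TRUE)
  # inverse mapping: sample source at the point that rotates onto (r, c)
  sr <- cos(th) * r - sin(th) * c + cy
  sc <- sin(th) * r + cos(th) * c + cx
  sr <- pmin(pmax(sr, 1), n[1])
  sc <- pmin(pmax(sc, 1), n[2])
  r0 <- pmin(floor(sr), n[1] - 1); c0 <- pmin(floor(sc), n[2] - 1)
  wr <- sr - r0; wc <- sc - c0
  idx <- function(rr, cc) image[cbind(as.vector(rr), as.vector(cc))]
  out <- (1 - wr) * (1 - wc) * idx(r0, c0) + (1 - wr) * wc * idx(r0, c0 + 1) +
    wr * (1 - wc) * idx(r0 + 1, c0) + wr * wc * idx(r0 + 1, c0 + 1)
  matrix(out, n[1], n[2])
}

# Butterworth high-pass of a 1D signal; zero-phase (forward-backward).
# Order 3; cutoff defaults to half the lenslet frequency (0.5/pitch cycles/px).
highpass_profile <- function(x, pitch = 19) {
  wc <- min(max((0.5 / pitch) / 0.5, 1e-4), 0.99)  # normalized to Nyquist
  bf <- signal::butter(3, wc, type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

#' Intensity contrast of a light-field image at a candidate rotation angle
#'
#' The image is rotated by `angle`, summed along columns, high-pass filtered
#' (Butterworth, order 3, cutoff at half the lenslet frequency) to remove the
#' DC component and slow envelope, and the contrast `max - min` of the filtered
#' profile is returned.  A perfectly axis-aligned lenslet grid maximizes this
#' contrast because bright centres and dark borders each sum coherently.
#'
#' @param image Numeric matrix, a raw light-field image.
#' @param angle Candidate rotation (degrees).
#' @param pitch Approximate lenslet pitch in pixels (sets the filter cutoff).
#' @return A single non-negative number.
#' @export
intensity_contrast <- function(image, angle, pitch = 19) {
  if (all(image == 0)) stop("intensity_contrast: all-zero image", call. = FALSE)
  prof <- colSums(rotate_bilinear(image, angle))
  prof <- prof - mean(prof)  # drop DC before filtering to avoid edge transients
  f <- highpass_profile(prof, pitch)
  max(f) - min(f)
}

#' Coarse-to-fine detection of the MLA rotation angle
#'
#' Scans `[-coarse_range, coarse_range]` in steps of `coarse_step`, takes the
#' contrast-maximizing angle `a`, then refines over `[a - 1, a + 1]` degrees in
#' steps of `coarse_step / 10`.  The returned angle is the rotation *of the
#' image*; rotating the image by its negative aligns the grid with the sensor
#' axes.
#'
#' @inheritParams intensity_contrast
#' @param coarse_range Half-width of the coarse search (degrees).
#' @param coarse_step Coarse increment (degrees).
#' @return The detected angle (degrees).  The contrast curves of both passes
#'   are attached as attribute `contrast_curve`, a tibble with columns
#'   `angle`, `contrast`, `pass`.
#' @export
detect_rotation_angle <- function(image, coarse_range = 5, coarse_step = 0.1,
                                  pitch = 19) {
  scan <- function(angles, pass) {
    tibble::tibble(
      angle = angles,
      # contrast at probe angle a is evaluated by rotating the image by -a
      contrast = vapply(angles, function(a) intensity_contrast(image, -a, pitch),
                        numeric(1)),
      pass = pass)
  }
  coarse <- scan(seq(-coarse_range, coarse_range, by = coarse_step), "coarse")
  if (diff(range(coarse$contrast)) <= 1e-12 * max(abs(coarse$contrast), 1)) {
    stop("detect_rotation_angle: flat contrast curve, no lenslet grid structure detected",
         call. = FALSE)
  }
  a0 <- coarse$angle[which.max(coarse$contrast)]
  fine <- scan(seq(a0 - 1, a0 + 1, by = coarse_step / 10), "fine")
  out <- fine$angle[which.max(fine$contrast)]
  attr(out, "contrast_curve") <- dplyr::bind_rows(coarse, fine)
  out
}

#' Detect the lenslet pitch from a rotation-corrected image
#'
#' Columns of the calibrated image are summed into an approximately periodic
#' 1D profile whose period is the lenslet pitch.  The dominant non-DC peak of
#' its discrete Fourier spectrum gives the lenslet frequency; the peak location
#' is refined by parabolic interpolation of the log-magnitude, and the pitch is
#' its reciprocal.
#'
#' @param image Numeric matrix with the rotation already corrected.
#' @param max_period Longest period (pixels) considered a lenslet pitch;
#'   spectral bins below the corresponding frequency belong to the scene
#'   envelope (the blobs of out-of-focus sources) and are excluded.  Defaults
#'   to one eighth of the image width, i.e. at least 8 lenslet periods.
#' @return Pitch in pixels (real-valued).
#' @export
detect_pitch <- function(image, max_period = NULL) {
  prof <- colSums(image)
  prof <- prof - mean(prof)
  n <- length(prof)
  if (is.null(max_period)) max_period <- n / 8
  mag <- Mod(stats::fft(prof))[seq_len(floor(n / 2) + 1)]  # DC .. Nyquist
  band <- seq_len(max(1, ceiling(n / max_period)))          # DC + envelope band
  mag[band] <- 0
  peak <- which.max(mag)
  if (all(mag == 0) || peak == length(mag)) {
    stop("detect_pitch: no usable spectral peak below Nyquist; pitch unresolved",
         call. = FALSE)
  }
  if (mag[peak] < 3 * stats::median(mag[mag > 0])) {
    stop("detect_pitch: no distinct spectral peak; image lacks periodic structure",
         call. = FALSE)
  }
  # refine on a 16x zero-padded spectrum: the denser frequency grid resolves
  # the peak to ~p^2/(16 n) pixels, then a parabola interpolates between bins
  pad <- 16L
  magp <- Mod(stats::fft(c(prof, numeric((pad - 1L) * n))))[seq_len(floor(pad * n / 2) + 1)]
  lo <- (peak - 2L) * pad; hi <- peak * pad   # 0-based padded bins around the peak
  kp <- lo + which.max(magp[(lo + 1L):(hi + 1L)]) - 1L
  shift <- parabolic_offset(magp, kp + 1L)
  freq <- (kp + shift) / (pad * n)
  1 / freq
}

# sub-pixel refinement: quadratic fit through a peak sample and its two
# neighbours along one axis; returns an offset in (-0.5, 0.5)
parabolic_offset <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(0)
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (v[i - 1] - v[i + 1]) / denom
  max(min(off, 0.5), -0.5)
}

# disc kernel of a given pixel diameter; multi-disc tiles n x n discs at the
# pitch so that neighbourhood structure contributes to the match
disc_kernel <- function(pitch, n_discs = 1L) {
  rad <- pitch / 2
  m <- ceiling(pitch)
  if (m %% 2 == 0) m <- m + 1L
  cc <- (m + 1) / 2
  one <- outer((seq_len(m) - cc)^2, (seq_len(m) - cc)^2, "+") <= rad^2
  one <- matrix(as.numeric(one), m, m)
  if (n_discs <= 1L) return(one)
  span <- round(pitch * (n_discs - 1))
  sz <- m + span
  if (sz %% 2 == 0) sz <- sz + 1L
  ker <- matrix(0, sz, sz)
  ctr <- (sz + 1) / 2
  for (a in seq_len(n_discs)) for (b in seq_len(n_discs)) {
    oy <- round((a - (n_discs + 1) / 2) * pitch)
    ox <- round((b - (n_discs + 1) / 2) * pitch)
    ys <- ctr + oy + (seq_len(m) - cc)
    xs <- ctr + ox + (seq_len(m) - cc)
    ok <- ys >= 1 & ys <= sz
    okx <- xs >= 1 & xs <= sz
    ker[ys[ok], xs[okx]] <- ker[ys[ok], xs[okx]] + one[ok, okx]
  }
  ker
}

#' Detect lenslet centres
#'
#' Implements disc-kernel centre detection: the image is binarized (Otsu's
#' threshold by default), convolved with a disc-shaped kernel whose diameter
#' equals the lenslet pitch (or a 3 x 3 multi-disc kernel for robustness to
#' locally poor image quality), and centres are found by marching a window of
#' one pitch from the global maximum of the convolved image, snapping each
#' predicted centre to the local maximum within `pitch / 4`.  Sub-pixel
#' positions come from the centroid of the single-disc response plateau
#' (which stays centred even for edge lenslets).  Finally the row and column
#' coordinates are averaged along each grid row and column - weighted by the
#' single-disc response, with cells that strayed more than `pitch / 4` from
#' the rigid-grid prediction (e.g. dark lenslets locking onto a neighbour)
#' carrying no weight - which regularizes the centre map onto a rigid grid.
#'
#' @param image Rotation-corrected light-field image (matrix).
#' @param pitch Lenslet pitch in pixels.
#' @param threshold Binarization threshold on the `[0, 1]`-rescaled image;
#'   `NULL` (default) uses Otsu's method.
#' @param kernel `"multi"` (default) for the 3 x 3 multi-disc kernel or
#'   `"single"` for one disc.
#' @param n_discs Number of discs per side of the multi-disc kernel.
#' @param grid_dim Optional `c(K, L)` expected lenslet grid; inferred from the
#'   image size and pitch when `NULL`.
#' @return A list of class `lfm_center_map`: `row` and `col` are `K x L`
#'   matrices of centre coordinates (pixels, real-valued).
#' @export
detect_centers <- function(image, pitch, threshold = NULL, kernel = c("multi", "single"),
                           n_discs = 3L, grid_dim = NULL) {
  kernel <- match.arg(kernel)
  n <- dim(image)
  if (is.null(grid_dim)) grid_dim <- pmax(floor(n / pitch), 1L)
  K <- grid_dim[1]; L <- grid_dim[2]
  img01 <- (image - min(image)) / max(max(image) - min(image), .Machine$double.eps)
  if (is.null(threshold)) threshold <- EBImage::otsu(EBImage::Image(img01))
  bin <- matrix(as.numeric(img01 > threshold), n[1], n[2])
  # marching response: multi-disc kernel (or single); localization response:
  # always the single disc, whose aligned-overlap term is an even function of
  # the offset, so its response plateau stays centred even for edge lenslets
  conv1 <- as.matrix(EBImage::filter2(EBImage::Image(bin),
                                      disc_kernel(pitch, 1L), boundary = 0))
  conv <- if (kernel == "multi") {
    km <- disc_kernel(pitch, as.integer(n_discs))
    as.matrix(EBImage::filter2(EBImage::Image(bin), km / sum(km), boundary = 0))
  } else conv1

  # anchor the grid on the global maximum of the marching response
  anchor <- arrayInd(which.max(conv), n)
  a_k <- round((anchor[1] - (n[1] + 1) / 2) / pitch + (K + 1) / 2)
  a_l <- round((anchor[2] - (n[2] + 1) / 2) / pitch + (L + 1) / 2)
  a_k <- min(max(a_k, 1L), K); a_l <- min(max(a_l, 1L), L)

  snap <- pitch / 4
  reach <- max(1L, round(pitch / 2) - 1L)
  rows <- matrix(NA_real_, K, L); cols <- matrix(NA_real_, K, L)
  weight <- matrix(0, K, L)
  for (k in seq_len(K)) for (l in seq_len(L)) {
    pr <- anchor[1] + (k - a_k) * pitch
    pc <- anchor[2] + (l - a_l) * pitch
    ys <- max(1, round(pr - snap)):min(n[1], round(pr + snap))
    xs <- max(1, round(pc - snap)):min(n[2], round(pc + snap))
    if (!length(ys) || !length(xs)) next
    # integer position: marching-response maximum within the snap window
    win <- conv[ys, xs, drop = FALSE]
    best <- which(win >= max(win) * (1 - 1e-9), arr.ind = TRUE)
    ctr <- (dim(win) + 1) / 2
    best <- best[which.min((best[, 1] - ctr[1])^2 + (best[, 2] - ctr[2])^2), ]
    r0 <- ys[best[1]]; c0 <- xs[best[2]]
    # sub-pixel position: centroid of the single-disc response plateau
    ys2 <- max(1, r0 - reach):min(n[1], r0 + reach)
    xs2 <- max(1, c0 - reach):min(n[2], c0 + reach)
    win1 <- conv1[ys2, xs2, drop = FALSE]
    plat <- which(win1 >= max(win1) * (1 - 1e-9), arr.ind = TRUE)
    rows[k, l] <- ys2[1] + mean(plat[, 1]) - 1
    cols[k, l] <- xs2[1] + mean(plat[, 2]) - 1
    # a cell whose own disc is dark locks onto a neighbour: only trust the
    # estimate when it stays within the snap radius of the grid prediction
    if (abs(rows[k, l] - pr) <= snap && abs(cols[k, l] - pc) <= snap) {
      weight[k, l] <- max(win1)
    }
  }
  if (anyNA(rows)) {
    miss <- which(is.na(rows), arr.ind = TRUE)
    stop("detect_centers: no centre found for lenslet cells ",
         paste(sprintf("(%d,%d)", miss[, 1], miss[, 2]), collapse = " "), call. = FALSE)
  }
  # average along each grid row / column to give the final rigid grid;
  # lenslets with a weak single-disc response (e.g. dark or vignetted cells)
  # carry no weight so they cannot drag the averages
  ok <- weight >= 0.5 * stats::median(weight)
  if (any(rowSums(ok) == 0) || any(colSums(ok) == 0)) {
    stop("detect_centers: an entire lenslet row or column is too dark to locate",
         call. = FALSE)
  }
  w <- weight * ok
  row_final <- matrix(rowSums(rows * w) / rowSums(w), K, L)
  col_final <- matrix(colSums(cols * w) / colSums(w), K, L, byrow = TRUE)
  structure(list(row = row_final, col = col_final, pitch = pitch,
                 threshold = as.numeric(threshold), kernel = kernel,
                 cell_row = rows, cell_col = cols, cell_weight = weight),
            class = "lfm_center_map")
}

#' Calibrate a raw light-field image
#'
#' Runs the full calibration chain: rotation-angle detection, rotation
#' correction, pitch detection and centre detection.
#'
#' @param image Raw light-field image (matrix or `lfm_raw`).
#' @param coarse_range,coarse_step Passed to [detect_rotation_angle()].
#' @param pitch_hint Approximate pitch in pixels for the contrast filter.
#' @param ... Passed to [detect_centers()].
#' @return An object of class `lfm_calibration` with fields `rotation_angle`
#'   (degrees), `pitch` (pixels), `centers` (an `lfm_center_map`) and
#'   `corrected` (the rotation-corrected image).
#' @export
calibrate_lightfield <- function(image, coarse_range = 5, coarse_step = 0.1,
                                 pitch_hint = 19, ...) {
  image <- unclass(image)
  angle <- detect_rotation_angle(image, coarse_range, coarse_step, pitch = pitch_hint)
  curve <- attr(angle, "contrast_curve")
  corrected <- rotate_bilinear(image, -as.numeric(angle))
  pitch <- detect_pitch(corrected)
  centers <- detect_centers(corrected, pitch, ...)
  structure(list(rotation_angle = as.numeric(angle), pitch = pitch,
                 centers = centers, corrected = corrected,
                 contrast_curve = curve),
            class = "lfm_calibration")
}

#' Exact calibration of a simulated light-field
#'
#' Simulated images from [render_lightfield()] have a known geometry: zero
#' rotation, pitch `N_i` pixels, and lenslet centres on the exact pixel grid.
#' This constructor produces the corresponding `lfm_calibration` without
#' running any detection, for use when decoding simulator output.
#'
#' @param cfg An [optical_config()].
#' @return An `lfm_calibration`.
#' @export
calibration_from_config <- function(cfg) {
  K <- cfg$lenslet_count[1]; L <- cfg$lenslet_count[2]
  Ni <- cfg$pixels_per_lenslet[1]; Nj <- cfg$pixels_per_lenslet[2]
  rows <- matrix((seq_len(K) - 1) * Ni + (Ni + 1) / 2, K, L)
  cols <- matrix((seq_len(L) - 1) * Nj + (Nj + 1) / 2, K, L, byrow = TRUE)
  structure(list(
    rotation_angle = 0,
    pitch = Ni,
    centers = structure(list(row = rows, col = cols, pitch = Ni,
                             threshold = NA_real_, kernel = "exact"),
                        class = "lfm_center_map"),
    corrected = NULL, contrast_curve = NULL), class = "lfm_calibration")
}

#' @export
print.lfm_calibration <- function(x, ...) {
  cat(sprintf("<lfm_calibration> angle %.3f deg, pitch %.3f px, %d x %d centres\n",
              x$rotation_angle, x$pitch, nrow(x$centers$row), ncol(x$centers$row)))
  invisible(x)
}

#' Read / write calibration results as JSON
#'
#' @param calib An `lfm_calibration`.
#' @param path Output path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns an `lfm_calibration` (without the corrected
#'   image, which is not persisted).
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "lfm_calibration"))
  jsonlite::write_json(list(
    rotation_angle = calib$rotation_angle,
    pitch = calib$pitch,
    center_rows = calib$centers$row,
    center_cols = calib$centers$col
  ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- as.matrix(v$center_rows); cols <- as.matrix(v$center_cols)
  structure(list(
    rotation_angle = v$rotation_angle, pitch = v$pitch,
    centers = structure(list(row = rows, col = cols, pitch = v$pitch,
                             threshold = NA_real_, kernel = "file"),
                        class = "lfm_center_map"),
    corrected = NULL, contrast_curve = NULL), class = "lfm_calibration")
}
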