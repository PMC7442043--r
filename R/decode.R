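# Decode a calibrated raw light-field into the two-plane-parameterized 4D form
# I4D(i, j, k, l), with sub-aperture and epipolar-plane-image (EPI) views, and
# the SVD rank-one background purification used for scattering tissue.

#' Decode a raw light-field image into 4D form
#'
#' For each lenslet `(k, l)` the `N_i x N_j` pixel window centred (rounded to
#' the nearest pixel) on its calibrated centre becomes the micro-image
#' `I4D(, , k, l)`; window pixels falling outside the sensor are zero-filled
#' and the affected lenslets flagged as vignetted.  Axis semantics: `(i, j)`
#' index the pixel within the micro-image (the angular/viewing direction),
#' `(k, l)` index the lenslet (the spatial sample).
#'
#' @param raw Raw light-field image (matrix or `lfm_raw`).
#' @param calib An `lfm_calibration` (e.g. from [calibrate_lightfield()] or
#'   [calibration_from_config()]); its rotation must already be corrected in
#'   `raw` when nonzero.
#' @param pixels_per_lenslet Window size `c(N_i, N_j)`; a scalar is recycled.
#'   Defaults to the rounded calibrated pitch.
#' @return A 4D array of class `lfm_lightfield4d` with dimensions
#'   `(N_i, N_j, K, L)` and attributes `calibration` and `vignetted` (logical
#'   `K x L`).
#' @export
decode_4d <- function(raw, calib, pixels_per_lenslet = NULL) {
  stopifnot(inherits(calib, "lfm_calibration"))
  raw <- unclass(raw)
  if (is.null(pixels_per_lenslet)) pixels_per_lenslet <- round(calib$pitch)
  npx <- as.integer(rep(pixels_per_lenslet, length.out = 2))
  # windows snap to integer pixels, so tolerate sub-half-pixel pitch estimates
  if (calib$pitch < max(npx) - 0.5) {
    stop("decode_4d: micro-image windows (", max(npx),
         " px) overlap at pitch ", signif(calib$pitch, 5), " px", call. = FALSE)
  }
  K <- nrow(calib$centers$row); L <- ncol(calib$centers$row)
  offs_i <- seq_len(npx[1]) - floor(npx[1] / 2) - 1L
  offs_j <- seq_len(npx[2]) - floor(npx[2] / 2) - 1L
  lf <- array(0, dim = c(npx[1], npx[2], K, L))
  vig <- matrix(FALSE, K, L)
  n <- dim(raw)
  for (k in seq_len(K)) for (l in seq_len(L)) {
    rr <- round(calib$centers$row[k, l]) + offs_i
    cc <- round(calib$centers$col[k, l]) + offs_j
    ok_r <- rr >= 1 & rr <= n[1]
    ok_c <- cc >= 1 & cc <= n[2]
    if (!all(ok_r) || !all(ok_c)) vig[k, l] <- TRUE
    if (any(ok_r) && any(ok_c)) {
      lf[which(ok_r), which(ok_c), k, l] <- raw[rr[ok_r], cc[ok_c]]
    }
  }
  structure(lf, calibration = calib, vignetted = vig,
            class = c("lfm_lightfield4d", "array"))
}

#' Sub-aperture image
#'
#' The `K x L` slice `I4D(i, j, , )`: one viewing direction, composed of the
#' pixels sharing relative position `(i, j)` behind every lenslet.
#'
#' @param lf An `lfm_lightfield4d`.
#' @param i,j Angular indices.
#' @return A `K x L` matrix.
#' @export
subaperture <- function(lf, i, j) {
  d <- dim(lf)
  if (i < 1 || i > d[1] || j < 1 || j > d[2]) {
    stop("subaperture: angular index out of range", call. = FALSE)
  }
  lf[i, j, , ]
}

#' Central sub-aperture view
#'
#' @param lf An `lfm_lightfield4d`.
#' @return The `K x L` central view `I4D(ceiling(N_i/2), ceiling(N_j/2), , )`.
#' @export
central_subaperture <- function(lf) {
  d <- dim(lf)
  subaperture(lf, ceiling(d[1] / 2), ceiling(d[2] / 2))
}

#' Re-tile a 4D light-field into its raw sensor layout
#'
#' Inverse of [decode_4d()] for non-vignetted data: micro-images are placed
#' back on the lenslet grid, giving a `K N_i x L N_j` image.
#'
#' @param lf An `lfm_lightfield4d`.
#' @return A matrix.
#' @export
tile_microimages <- function(lf) {
  d <- dim(lf)
  out <- matrix(0, d[1] * d[3], d[2] * d[4])
  for (k in seq_len(d[3])) for (l in seq_len(d[4])) {
    out[(k - 1) * d[1] + seq_len(d[1]), (l - 1) * d[2] + seq_len(d[2])] <- lf[, , k, l]
  }
  out
}

#' Extract an epipolar-plane image
#'
#' A horizontal EPI fixes `(j, l)` and spans `(i, k)`; a vertical EPI fixes
#' `(i, k)` and spans `(j, l)`.  Axis 1 of the result is angular, axis 2
#' spatial, so a point source traces a tilted epipolar line whose slope grows
#' with depth.
#'
#' @param lf An `lfm_lightfield4d`.
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param fixed_a For horizontal EPIs the fixed angular index `j`; for
#'   vertical, the fixed angular index `i`.  Defaults to the central view.
#' @param fixed_b For horizontal EPIs the fixed lenslet index `l`; for
#'   vertical, the fixed lenslet index `k`.  Defaults to the central lenslet.
#' @return A matrix of class `lfm_epi` with attributes `orientation`, `fixed`
#'   and (when available from the source light-field) `calibration`.
#' @export
extract_epi <- function(lf, orientation = c("horizontal", "vertical"),
                        fixed_a = NULL, fixed_b = NULL) {
  orientation <- match.arg(orientation)
  d <- dim(lf)
  if (orientation == "horizontal") {
    fixed_a <- fixed_a %||% ceiling(d[2] / 2)
    fixed_b <- fixed_b %||% ceiling(d[4] / 2)
    if (fixed_a < 1 || fixed_a > d[2] || fixed_b < 1 || fixed_b > d[4]) {
      stop("extract_epi: fixed index out of range", call. = FALSE)
    }
    epi <- lf[, fixed_a, , fixed_b]
  } else {
    fixed_a <- fixed_a %||% ceiling(d[1] / 2)
    fixed_b <- fixed_b %||% ceiling(d[3] / 2)
    if (fixed_a < 1 || fixed_a > d[1] || fixed_b < 1 || fixed_b > d[3]) {
      stop("extract_epi: fixed index out of range", call. = FALSE)
    }
    epi <- lf[fixed_a, , fixed_b, ]
  }
  structure(epi, orientation = orientation, fixed = c(fixed_a, fixed_b),
            class = c("lfm_epi", "matrix"))
}

#' @export
print.lfm_epi <- function(x, ...) {
  cat(sprintf("<lfm_epi> %s, %d angular x %d spatial samples, fixed (%d, %d)\n",
              attr(x, "orientation"), nrow(x), ncol(x),
              attr(x, "fixed")[1], attr(x, "fixed")[2]))
  invisible(x)
}

#' Extract the EPI pair through the brightest spatial position
#'
#' Finds the brightest lenslet `(k0, l0)` of the central sub-aperture view and
#' returns the horizontal EPI through `(j = central, l = l0)` and the vertical
#' EPI through `(i = central, k = k0)`, the pair used for localization.
#'
#' @param lf An `lfm_lightfield4d`.
#' @return A list with elements `horizontal` and `vertical` (both `lfm_epi`).
#' @export
extract_localization_epis <- function(lf) {
  d <- dim(lf)
  ctr <- central_subaperture(lf)
  pk <- arrayInd(which.max(ctr), dim(ctr))
  list(
    horizontal = extract_epi(lf, "horizontal", ceiling(d[2] / 2), pk[2]),
    vertical = extract_epi(lf, "vertical", ceiling(d[1] / 2), pk[1])
  )
}

#' Rank-one SVD background removal
#'
#' Scattering tissue adds a diffuse background that is nearly identical across
#' viewing directions.  All sub-aperture images are vectorized into the
#' columns of a matrix `A`; its leading singular triplet gives the rank-one
#' background `B = u_max sigma_max v_max^T`, and the foreground is `A - B`
#' reshaped back to images.
#'
#' @param subapertures A 3D array `(K, L, n_views)` of sub-aperture images, or
#'   an `lfm_lightfield4d` (all `N_i N_j` views are used).
#' @return A list with `foreground` (same shape as the input stack) and
#'   `background` (class `lfm_background`: `sigma_max`, `u_max`, `v_max`, and
#'   the `K x L` background image of the first view).
#' @export
remove_background <- function(subapertures) {
  if (inherits(subapertures, "lfm_lightfield4d")) {
    d <- dim(subapertures)
    stack <- aperm(subapertures, c(3, 4, 1, 2))
    dim(stack) <- c(d[3], d[4], d[1] * d[2])
    subapertures <- stack
  }
  d <- dim(subapertures)
  if (length(d) != 3 || d[3] < 2) {
    stop("remove_background: need a stack of at least 2 sub-aperture images",
         call. = FALSE)
  }
  A <- matrix(subapertures, nrow = d[1] * d[2], ncol = d[3])
  if (all(A == 0)) stop("remove_background: all-zero input", call. = FALSE)
  sv <- svd(A, nu = 1, nv = 1)
  B <- sv$u[, 1, drop = FALSE] %*% (sv$d[1] * t(sv$v[, 1, drop = FALSE]))
  fg <- A - B
  model <- structure(list(sigma_max = sv$d[1], u_max = sv$u[, 1], v_max = sv$v[, 1],
                          image = matrix(B[, 1], d[1], d[2])),
                     class = "lfm_background")
  list(foreground = array(fg, dim = d), background = model)
}

#' Purify a scattering-corrupted 4D light-field
#'
#' Applies [remove_background()] across all sub-aperture views and returns a
#' light-field with the rank-one background subtracted (values may be signed).
#'
#' @param lf An `lfm_lightfield4d`.
#' @return A list with `lightfield` (purified `lfm_lightfield4d`) and
#'   `background` (`lfm_background`).
#' @export
purify_lightfield <- function(lf) {
  d <- dim(lf)
  res <- remove_background(lf)
  fg <- res$foreground
  dim(fg) <- c(d[3], d[4], d[1], d[2])
  out <- aperm(fg, c(3, 4, 1, 2))
  out <- structure(out, calibration = attr(lf, "calibration"),
                   vignetted = attr(lf, "vignetted"),
                   class = c("lfm_lightfield4d", "array"))
  list(lightfield = out, background = res$background)
}

#' Max-projection profiles of an EPI
#'
#' The per-row maxima (projection onto the vertical/angular axis) and
#' per-column maxima (projection onto the horizontal/spatial axis) of an EPI,
#' a cheap diagnostic that suppresses diffuse background.
#'
#' @param epi An `lfm_epi` or plain matrix.
#' @return A list with numeric vectors `row_profile` and `col_profile`.
#' @export
max_projection_epi <- function(epi) {
  stopifnot(length(dim(epi)) == 2, all(dim(epi) > 0))
  list(row_profile = apply(epi, 1, max), col_profile = apply(epi, 2, max))
}
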