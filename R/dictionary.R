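# Depth-aware EPI dictionary: simulate a 10 um ball at a sweep of depths,
# decode each rendered light-field, extract the central EPI, crop to a common
# atom window and normalize to unit l2 norm.  Atom index -> depth is a lookup.

#' Transverse sampling step of the localization grid
#'
#' The lateral quantization of light-field localization in object space:
#' `d / M` um at the native resolution limit (one lenslet), or the
#' super-resolved discretization `d / (M N_i)` um (one sensor pixel) reachable
#' by deconvolution-style methods.
#'
#' @param cfg An [optical_config()].
#' @param super_resolved Logical; return the per-pixel step instead of the
#'   per-lenslet step.
#' @return Step in object-space um.
#' @examples
#' transverse_sampling(optical_config())                        # 5 um
#' transverse_sampling(optical_config(), super_resolved = TRUE) # ~0.26 um
#' @export
transverse_sampling <- function(cfg, super_resolved = FALSE) {
  validate_config(cfg)
  if (super_resolved) {
    cfg$lenslet_pitch / (cfg$magnification * cfg$pixels_per_lenslet[1])
  } else {
    cfg$lenslet_pitch / cfg$magnification
  }
}

#' Build a depth-aware EPI dictionary
#'
#' For every depth `z` in `depths`, renders the light-field of a ball-shaped
#' volume (default 10 um diameter) centred on the optical axis at depth `z`,
#' decodes it to 4D, extracts the central EPI, crops it to a common atom
#' window and normalizes the atom to unit l2 norm.  The epipolar line of each
#' atom tilts more the deeper the source, which is what makes atom identity
#' carry depth information.
#'
#' @param cfg An [optical_config()].
#' @param depths Strictly increasing depths (um), e.g. `seq(0, 48, by = 4)`.
#' @param diameter Ball diameter (um).
#' @param grid_step Ball discretization step (um).
#' @param orientation `"horizontal"` or `"vertical"` atoms (for a centred
#'   simulated ball the two are identical).
#' @param atom_halfwidth Optional half-width (spatial samples) of the atom
#'   window; `NULL` selects the tight bounding box of the epipolar line at the
#'   deepest depth plus a 2-sample margin.
#' @return An object of class `lfm_dictionary`: list with `atoms` (3D array,
#'   `M_atoms x n_angular x n_spatial`), `depths`, `orientation`, `config`,
#'   `diameter`, `grid_step`.
#' @export
build_dictionary <- function(cfg, depths = seq(0, 48, by = 4), diameter = 10,
                             grid_step = 1,
                             orientation = c("horizontal", "vertical"),
                             atom_halfwidth = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(length(depths) >= 1)
  if (is.unsorted(depths, strictly = TRUE)) {
    stop("build_dictionary: depths must be strictly increasing", call. = FALSE)
  }
  calib <- calibration_from_config(cfg)
  epis <- lapply(depths, function(z) {
    vol <- discretize_ball(c(0, 0, z), diameter, grid_step)
    raw <- render_lightfield(vol, cfg)
    lf <- decode_4d(raw, calib, cfg$pixels_per_lenslet)
    extract_epi(lf, orientation)
  })
  ns <- ncol(epis[[length(epis)]])
  ctr <- ceiling(ns / 2)
  if (is.null(atom_halfwidth)) {
    deep <- epis[[length(epis)]]
    occupied <- which(apply(deep, 2, max) > 1e-3 * max(deep))
    bb <- max(abs(occupied - ctr))
    atom_halfwidth <- min(bb + 2L, ctr - 1L)
  }
  win <- (ctr - atom_halfwidth):(ctr + atom_halfwidth)
  atoms <- array(0, dim = c(length(depths), nrow(epis[[1]]), length(win)))
  for (m in seq_along(depths)) {
    a <- unclass(epis[[m]])[, win, drop = FALSE]
    nrm <- sqrt(sum(a^2))
    if (nrm <= 0) {
      stop("build_dictionary: atom at depth ", depths[m], " um has zero energy",
           call. = FALSE)
    }
    atoms[m, , ] <- a / nrm
  }
  structure(list(atoms = atoms, depths = as.numeric(depths),
                 orientation = orientation, config = cfg,
                 diameter = diameter, grid_step = grid_step,
                 atom_halfwidth = atom_halfwidth),
            class = "lfm_dictionary")
}

#' Depth associated with a dictionary atom
#'
#' @param dict An `lfm_dictionary`.
#' @param m Atom index (1-based).
#' @return Depth in um.
#' @export
depth_lookup <- function(dict, m) {
  stopifnot(inherits(dict, "lfm_dictionary"))
  if (any(m < 1 | m > length(dict$depths))) {
    stop("depth_lookup: atom index out of range", call. = FALSE)
  }
  dict$depths[m]
}

#' Number of atoms in a dictionary
#' @param dict An `lfm_dictionary`.
#' @return Integer.
#' @export
n_atoms <- function(dict) length(dict$depths)

#' Fitted slope of an EPI's epipolar line
#'
#' Intensity-weighted least-squares fit of the spatial position of the line
#' against the angular index: for each angular row the intensity-weighted
#' centroid of the (non-negative) row profile is taken, and a line is fitted
#' through the centroids weighted by row energy.  The slope is in spatial
#' samples per angular sample and grows with source depth.
#'
#' @param epi An `lfm_epi`, dictionary atom slice, or plain matrix.
#' @return Slope (spatial samples / angular sample).
#' @export
epi_slope <- function(epi) {
  e <- pmax(unclass(epi), 0)
  ang <- seq_len(nrow(e))
  w <- rowSums(e)
  keep <- w > 1e-6 * max(w)
  cen <- as.numeric(e %*% seq_len(ncol(e))) / pmax(w, .Machine$double.xmin)
  fit <- stats::lm(cen[keep] ~ ang[keep], weights = w[keep])
  unname(stats::coef(fit)[2])
}

#' @export
print.lfm_dictionary <- function(x, ...) {
  cat(sprintf("<lfm_dictionary> %d %s atoms of %d x %d, depths %g..%g um, ball %g um\n",
              n_atoms(x), x$orientation, dim(x$atoms)[2], dim(x$atoms)[3],
              min(x$depths), max(x$depths), x$diameter))
  invisible(x)
}

#' Read / write a dictionary container
#'
#' The dictionary is persisted as an RDS file alongside a small JSON sidecar
#' (same path with extension `.json`) carrying the generation parameters for
#' provenance.
#'
#' @param dict An `lfm_dictionary`.
#' @param path Output path (`.rds`).
#' @return `write_dictionary()` returns `path` invisibly; `read_dictionary()`
#'   returns the `lfm_dictionary`.
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "lfm_dictionary"))
  saveRDS(dict, path)
  meta <- list(depths = dict$depths, orientation = dict$orientation,
               diameter = dict$diameter, grid_step = dict$grid_step,
               config = unclass(dict$config))
  jsonlite::write_json(meta, paste0(sub("\\.rds$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  dict <- readRDS(path)
  stopifnot(inherits(dict, "lfm_dictionary"))
  dict
}
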