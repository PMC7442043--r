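# Convolutional sparse coding on EPIs, solved by ADMM in the Fourier domain.
# The quadratic subproblem is diagonal-plus-rank-one per frequency bin and is
# solved in closed form with the Sherman-Morrison identity; the l1 subproblem
# is elementwise soft-thresholding; the third step updates the scaled duals.
# Atom selection over coefficient-map energies gives depths via the dictionary
# lookup; map peaks give lateral positions; horizontal and vertical estimates
# are fused by reliability-weighted averaging.

#' Soft-thresholding (shrinkage) operator
#'
#' `S_lambda(x) = sign(x) * max(|x| - lambda, 0)`, applied elementwise; the
#' proximal operator of the l1 norm.
#'
#' @param x Numeric vector, matrix or array.
#' @param lambda Threshold, a single non-negative number.
#' @return Same shape as `x`.
#' @examples
#' soft_threshold(c(-1.2, 0.3, 1.2), 0.5)
#' @export
soft_threshold <- function(x, lambda) {
  stopifnot(length(lambda) == 1, lambda >= 0)
  sign(x) * pmax(abs(x) - lambda, 0)
}

# extract coefficient map m as a matrix (guarding against dimension drop)
map_slice <- function(maps, m) {
  matrix(maps[m, , ], dim(maps)[2], dim(maps)[3])
}

# embed an atom into an N-sized map with its centre wrapped to index (1, 1),
# so that coefficient peaks address atom centres directly
embed_atom <- function(atom, n) {
  a <- dim(atom)
  if (any(a > n)) stop("csc: atom larger than the observation", call. = FALSE)
  out <- matrix(0, n[1], n[2])
  ctr <- ceiling((a + 1) / 2)
  rr <- ((seq_len(a[1]) - ctr[1]) %% n[1]) + 1L
  cc <- ((seq_len(a[2]) - ctr[2]) %% n[2]) + 1L
  out[rr, cc] <- atom
  out
}

# cross-correlation peak magnitude of Y with each atom (used for the
# scale-free default of beta; also the LASSO null threshold)
atom_correlations <- function(Y, atoms_hat, n) {
  Yhat <- stats::fft(Y)
  vapply(seq_len(dim(atoms_hat)[1]), function(m) {
    cc <- Re(stats::fft(Conj(atoms_hat[m, , ]) * Yhat, inverse = TRUE)) / prod(n)
    max(abs(cc))
  }, numeric(1))
}

#' Solve the convolutional sparse coding problem on an EPI
#'
#' Minimizes `1/2 ||Y - sum_m d_m * z_m||_2^2 + beta sum_m ||z_m||_1` over the
#' coefficient maps `z_m` (one per dictionary atom, each the size of `Y`,
#' circular convolution) by ADMM in the Fourier domain.  The Z-update is
#' solved independently per frequency bin via the Sherman-Morrison identity;
#' the T-update is [soft_threshold()]; the dual update follows.  The solver is
#' deterministic (zero initialization, no randomness).
#'
#' @param Y Observation: an `lfm_epi` or numeric matrix (vectors are treated
#'   as 1-row matrices).
#' @param dict An `lfm_dictionary`, or a list of numeric matrices (the atoms).
#' @param beta Sparsity weight; `"auto"` (default) uses
#'   `0.05 * max_m ||corr(Y, d_m)||_inf`, which is invariant to rescaling `Y`.
#' @param mu ADMM penalty; defaults to `10 * beta`.
#' @param max_iter Maximum iterations.
#' @param tol Stop when the relative primal residual `||Z - T|| / ||Z||` falls
#'   below this.
#' @param pad Zero-padding (angular, spatial) added around `Y` before solving,
#'   to suppress circular wrap-around; `NULL` pads by the atom size.  Padded
#'   coefficients are masked out of source selection downstream.
#' @return An object of class `lfm_csc` with elements `maps` (array
#'   `M x nrow x ncol` over the padded grid), `T`, `duals`, `objective`,
#'   `primal_residual`, `dual_residual` (per-iteration traces), `iterations`,
#'   `beta`, `mu`, `pad`, `valid` (logical mask of unpadded positions) and
#'   `dims`.
#' @export
csc_admm <- function(Y, dict, beta = "auto", mu = NULL, max_iter = 200,
                     tol = 1e-4, pad = NULL) {
  atoms <- if (inherits(dict, "lfm_dictionary")) {
    lapply(seq_len(n_atoms(dict)), function(m) dict$atoms[m, , ])
  } else if (is.list(dict)) {
    # plain vectors are 1D atoms: orient them along the observation rows
    lapply(dict, function(a) if (is.null(dim(a))) matrix(a, nrow = 1) else a)
  } else stop("csc_admm: dict must be an lfm_dictionary or list of matrices")
  Y <- unclass(Y)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  if (!all(is.finite(Y))) stop("csc_admm: observation contains non-finite values")
  M <- length(atoms)
  asz <- vapply(atoms, dim, integer(2))
  if (is.null(pad)) pad <- c(max(asz[1, ]), max(asz[2, ]))
  pad <- rep(as.integer(pad), length.out = 2)
  pad <- pmin(pad, dim(Y) * 2L)  # no need to pad beyond wrap reach
  if (nrow(Y) == 1) pad[1] <- 0L
  n <- dim(Y) + 2L * pad
  Yp <- matrix(0, n[1], n[2])
  Yp[pad[1] + seq_len(nrow(Y)), pad[2] + seq_len(ncol(Y))] <- Y
  valid <- matrix(FALSE, n[1], n[2])
  valid[pad[1] + seq_len(nrow(Y)), pad[2] + seq_len(ncol(Y))] <- TRUE

  Dhat <- array(0i, dim = c(M, n[1], n[2]))
  for (m in seq_len(M)) Dhat[m, , ] <- stats::fft(embed_atom(atoms[[m]], n))
  corr_max <- max(atom_correlations(Yp, Dhat, n))
  if (identical(beta, "auto")) beta <- 0.05 * corr_max
  stopifnot(is.numeric(beta), beta >= 0)
  # the shrinkage threshold beta/mu must live on the scale of the coefficients
  # (the atom correlations), not on an absolute scale; with unit-norm atoms
  # the quadratic term has O(1) curvature, so this mu also conditions well
  if (is.null(mu)) {
    mu <- if (corr_max > 0) 10 * max(beta, .Machine$double.eps) / corr_max else 1
  }

  Yhat <- stats::fft(Yp)
  DtY <- array(0i, dim = dim(Dhat))
  for (m in seq_len(M)) DtY[m, , ] <- Conj(Dhat[m, , ]) * Yhat
  denom <- matrix(0, n[1], n[2])
  for (m in seq_len(M)) denom <- denom + Mod(Dhat[m, , ])^2

  Z <- array(0, dim = c(M, n[1], n[2]))
  Tm <- Z; G <- Z
  obj <- pr <- dr <- numeric(0)
  npx <- prod(n)
  iter_done <- 0L
  for (it in seq_len(max_iter)) {
    # Z-update: per-bin Sherman-Morrison solve of (d* d^T + mu I) z = b
    B <- array(0i, dim = dim(Dhat))
    sumDB <- matrix(0i, n[1], n[2])
    for (m in seq_len(M)) {
      B[m, , ] <- DtY[m, , ] - stats::fft(G[m, , ]) + mu * stats::fft(Tm[m, , ])
      sumDB <- sumDB + Dhat[m, , ] * B[m, , ]
    }
    corr <- sumDB / (mu + denom)
    recon_hat <- matrix(0i, n[1], n[2])
    for (m in seq_len(M)) {
      zh <- (B[m, , ] - Conj(Dhat[m, , ]) * corr) / mu
      Z[m, , ] <- Re(stats::fft(zh, inverse = TRUE)) / npx
      recon_hat <- recon_hat + Dhat[m, , ] * zh
    }
    if (!all(is.finite(Z))) {
      stop("csc_admm: solver diverged (non-finite values at iteration ", it, ")",
           call. = FALSE)
    }
    Tprev <- Tm
    Tm <- soft_threshold(Z + G / mu, beta / mu)
    G <- G + mu * (Z - Tm)
    recon <- Re(stats::fft(recon_hat, inverse = TRUE)) / npx
    obj <- c(obj, 0.5 * sum((Yp - recon)^2) + beta * sum(abs(Tm)))
    pr <- c(pr, sqrt(sum((Z - Tm)^2)) / max(sqrt(sum(Z^2)), .Machine$double.eps))
    dr <- c(dr, mu * sqrt(sum((Tm - Tprev)^2)) / max(sqrt(sum(G^2)), .Machine$double.eps))
    iter_done <- it
    if (pr[it] < tol) break
  }
  structure(list(maps = Z, T = Tm, duals = G, objective = obj,
                 primal_residual = pr, dual_residual = dr,
                 iterations = iter_done, beta = beta, mu = mu, pad = pad,
                 valid = valid, dims = dim(Y)),
            class = "lfm_csc")
}

#' @export
print.lfm_csc <- function(x, ...) {
  cat(sprintf("<lfm_csc> %d maps of %d x %d, %d iterations, objective %.4g\n",
              dim(x$maps)[1], dim(x$maps)[2], dim(x$maps)[3], x$iterations,
              utils::tail(x$objective, 1)))
  invisible(x)
}

#' Select source atoms from coefficient-map energies
#'
#' Computes the energy `e_m = ||z_m||_2^2` of every coefficient map (over the
#' valid, unpadded region) and picks the `S` most energetic maps, suppressing
#' atoms whose depth lies within one dictionary step of an already selected
#' atom so that one physical source cannot claim two adjacent atoms.  The peak
#' of each selected map gives the spatial offset of its source.
#'
#' @param fit An `lfm_csc` from [csc_admm()].
#' @param S Number of sources to select (`>= 1`).
#' @param depths Atom depth lookup (one per map), used for the adjacency
#'   suppression; `NULL` disables suppression.
#' @return A tibble with one row per selected source: `atom`, `depth_um` (NA
#'   when `depths` is `NULL`), `energy`, `peak_angular`, `peak_spatial`
#'   (indices on the unpadded grid), `peak_value`.
#' @export
select_sources <- function(fit, S, depths = NULL) {
  stopifnot(inherits(fit, "lfm_csc"), S >= 1)
  M <- dim(fit$maps)[1]
  if (S > M) stop("select_sources: S exceeds the number of atoms", call. = FALSE)
  e <- vapply(seq_len(M), function(m) sum(fit$maps[m, , ][fit$valid]^2), numeric(1))
  if (sum(e > 0) < S) {
    stop("select_sources: fewer than S nonzero coefficient maps", call. = FALSE)
  }
  step <- if (!is.null(depths) && length(depths) > 1) stats::median(diff(depths)) else NULL
  chosen <- integer(0)
  for (m in order(e, decreasing = TRUE)) {
    if (e[m] <= 0) break
    if (!is.null(step) && length(chosen) &&
        any(abs(depths[chosen] - depths[m]) <= step + 1e-9)) next
    chosen <- c(chosen, m)
    if (length(chosen) == S) break
  }
  if (length(chosen) < S) {
    stop("select_sources: could not select ", S,
         " sources after depth-adjacency suppression", call. = FALSE)
  }
  rows <- lapply(chosen, function(m) {
    map <- map_slice(fit$maps, m)
    map[!fit$valid] <- 0
    pk <- arrayInd(which.max(abs(map)), dim(map))
    tibble::tibble(atom = m,
                   depth_um = if (is.null(depths)) NA_real_ else depths[m],
                   energy = e[m],
                   peak_angular = pk[1] - fit$pad[1],
                   peak_spatial = pk[2] - fit$pad[2],
                   peak_value = map[pk])
  })
  dplyr::bind_rows(rows)
}

#' Reliability weight of a coefficient matrix
#'
#' The fraction of total coefficient energy captured by the selected maps,
#' `w = ||Z_{,Omega}||_F^2 / ||Z||_F^2`, in `[0, 1]`.  Large weights indicate
#' that the selected atoms dominate the representation, i.e. a trustworthy
#' EPI.
#'
#' @param fit An `lfm_csc`, or a 3D array of coefficient maps.
#' @param omega Indices of the selected maps.
#' @return A single number in `[0, 1]`.
#' @export
compute_weight <- function(fit, omega) {
  maps <- if (inherits(fit, "lfm_csc")) fit$maps else fit
  stopifnot(length(dim(maps)) == 3)
  if (any(omega < 1 | omega > dim(maps)[1])) {
    stop("compute_weight: omega out of range", call. = FALSE)
  }
  total <- sum(maps^2)
  if (total <= 0) stop("compute_weight: zero total coefficient energy", call. = FALSE)
  sum(maps[omega, , , drop = FALSE]^2) / total
}

#' Fuse horizontal and vertical position estimates
#'
#' Reliability-weighted average of the two per-EPI 3D estimates,
#' `p = (w_h p_h + w_v p_v) / (w_h + w_v)`.  The weights are renormalized to
#' sum to one so the fusion is a convex combination of the two positions.
#'
#' @param p_h,p_v Numeric length-3 vectors or n x 3 matrices (matched rows).
#' @param w_h,w_v Non-negative reliability weights.
#' @return Same shape as `p_h`.
#' @export
fuse_locations <- function(p_h, p_v, w_h, w_v) {
  if (w_h + w_v <= 0) stop("fuse_locations: weights sum to zero", call. = FALSE)
  (w_h * p_h + w_v * p_v) / (w_h + w_v)
}

# map a spatial EPI index to an object-space lateral coordinate (um);
# the 4-f image is inverted, hence the sign flip
spatial_index_to_um <- function(idx, n_spatial, cfg) {
  -(idx - ceiling(n_spatial / 2)) * transverse_sampling(cfg)
}

#' Localize sources from an EPI pair
#'
#' Runs [csc_admm()] on the horizontal and vertical EPIs against the
#' depth-aware dictionary, selects the `S` most energetic atoms per EPI
#' ([select_sources()]), converts map peaks to object-space lateral
#' coordinates and atoms to depths, computes the per-EPI reliability weights
#' and fuses the two estimates ([fuse_locations()]).
#'
#' @param epi_h,epi_v Horizontal and vertical `lfm_epi` (from
#'   [extract_localization_epis()] or [extract_epi()]).
#' @param dict An `lfm_dictionary` built with the same optical configuration.
#' @param S Number of sources.
#' @param beta,mu,max_iter,tol Passed to [csc_admm()].
#' @return An object of class `lfm_localization`: list with `sources` (tibble
#'   with `source_id`, `x_um`, `y_um`, `z_um`, `w_h`, `w_v`, `atom_h`,
#'   `atom_v`), `omega_h`, `omega_v`, `fit_h`, `fit_v`, `config`.
#' @export
localize <- function(epi_h, epi_v, dict, S = 1, beta = "auto", mu = NULL,
                     max_iter = 200, tol = 1e-4) {
  stopifnot(inherits(dict, "lfm_dictionary"))
  cfg <- dict$config
  fit_h <- csc_admm(epi_h, dict, beta = beta, mu = mu, max_iter = max_iter, tol = tol)
  fit_v <- csc_admm(epi_v, dict, beta = beta, mu = mu, max_iter = max_iter, tol = tol)
  sel_h <- select_sources(fit_h, S, dict$depths)
  sel_v <- select_sources(fit_v, S, dict$depths)
  w_h <- compute_weight(fit_h, sel_h$atom)
  w_v <- compute_weight(fit_v, sel_v$atom)

  # the horizontal EPI (i-k space) fixes (j, l): its peak moves along lenslet
  # rows k -> the y coordinate; the fixed l gives x.  Vice versa for vertical.
  fx_h <- attr(epi_h, "fixed"); fx_v <- attr(epi_v, "fixed")
  K <- ncol(epi_h); L <- ncol(epi_v)
  p_h <- cbind(
    x = spatial_index_to_um(rep(fx_h[2], S), L, cfg),
    y = spatial_index_to_um(sel_h$peak_spatial, K, cfg),
    z = sel_h$depth_um)
  p_v <- cbind(
    x = spatial_index_to_um(sel_v$peak_spatial, L, cfg),
    y = spatial_index_to_um(rep(fx_v[2], S), K, cfg),
    z = sel_v$depth_um)

  # greedy nearest-depth pairing of the S horizontal and S vertical sources,
  # ties broken by lateral proximity
  pairing <- integer(S)
  left <- seq_len(S)
  for (s in order(sel_h$energy, decreasing = TRUE)) {
    dz <- abs(p_v[left, 3] - p_h[s, 3])
    dl <- sqrt((p_v[left, 1] - p_h[s, 1])^2 + (p_v[left, 2] - p_h[s, 2])^2)
    best <- left[order(dz, dl)][1]
    pairing[s] <- best
    left <- setdiff(left, best)
  }
  fused <- fuse_locations(p_h, p_v[pairing, , drop = FALSE], w_h, w_v)
  sources <- tibble::tibble(
    source_id = seq_len(S),
    x_um = unname(fused[, 1]), y_um = unname(fused[, 2]), z_um = unname(fused[, 3]),
    w_h = w_h, w_v = w_v,
    atom_h = sel_h$atom, atom_v = sel_v$atom[pairing])
  structure(list(sources = sources, omega_h = sel_h$atom, omega_v = sel_v$atom,
                 selection_h = sel_h, selection_v = sel_v,
                 fit_h = fit_h, fit_v = fit_v, config = cfg,
                 depths = dict$depths),
            class = "lfm_localization")
}

#' Localize directly from a decoded light-field
#'
#' Convenience wrapper: extracts the localization EPI pair
#' ([extract_localization_epis()]) and calls [localize()].
#'
#' @param lf An `lfm_lightfield4d`.
#' @inheritParams localize
#' @return An `lfm_localization`.
#' @export
localize_lightfield <- function(lf, dict, S = 1, ...) {
  epis <- extract_localization_epis(lf)
  localize(epis$horizontal, epis$vertical, dict, S = S, ...)
}

#' Estimate the source count from map energies
#'
#' Optional heuristic when `S` is unknown: sorts the per-map energies and
#' returns the position of the largest relative drop.
#'
#' @param fit An `lfm_csc`.
#' @return Estimated number of sources (integer `>= 1`).
#' @export
estimate_source_count <- function(fit) {
  stopifnot(inherits(fit, "lfm_csc"))
  M <- dim(fit$maps)[1]
  e <- sort(vapply(seq_len(M), function(m) sum(fit$maps[m, , ][fit$valid]^2),
                   numeric(1)), decreasing = TRUE)
  e <- e[e > 0]
  if (length(e) <= 1) return(length(e))
  drops <- e[-length(e)] / pmax(e[-1], .Machine$double.xmin)
  which.max(drops)
}

#' @export
print.lfm_localization <- function(x, ...) {
  cat(sprintf("<lfm_localization> %d source(s), w_h = %.3f, w_v = %.3f\n",
              nrow(x$sources), x$sources$w_h[1], x$sources$w_v[1]))
  print(x$sources)
  invisible(x)
}
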