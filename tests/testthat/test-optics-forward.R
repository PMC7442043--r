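# Wave-optics forward model: Debye wavefront, MLA mask, Fresnel propagation,
# PSF and volume rendering.

small_cfg <- function(...) desk_config(lenslet_count = 5, ...)

test_that("optical configuration validates its physical invariants", {
  cfg <- optical_config()
  expect_s3_class(cfg, "lfm_config")
  expect_equal(cfg$sensor_pixel_pitch * cfg$pixels_per_lenslet[1], cfg$lenslet_pitch)
  expect_error(optical_config(numerical_aperture = 1.4, medium_refractive_index = 1.33),
               "refractive index")
  expect_error(optical_config(wavelength = -1), "positive")
  expect_error(optical_config(sensor_pixel_pitch = 3), "one pixel")
})

test_that("optical configuration round-trips through YAML and JSON", {
  cfg <- desk_config(wavelength = 0.51)
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_optical_config(cfg, path)
    back <- read_optical_config(path)
    expect_equal(unclass(back), unclass(cfg))
  }
})

test_that("MLA mask is phase-only, pitch-periodic, and centred per lenslet", {
  cfg <- small_cfg()
  grid <- field_grid(cfg)
  mask <- mla_mask(cfg, grid)$values
  expect_true(all(abs(Mod(mask) - 1) < 1e-12))
  # periodicity: shift by one lenslet pitch (N_i * oversample samples)
  sh <- cfg$pixels_per_lenslet[1] * cfg$oversample
  inner <- (sh + 1):(nrow(mask) - sh)
  expect_equal(mask[inner, inner], mask[inner + sh, inner + sh], tolerance = 1e-12)
  # phase vanishes at lenslet centres: the four samples around each centre
  # have equal phase magnitude |pi (dy^2+dx^2) / (lambda f)| with dy = dx
  ctr_idx <- which.min(abs(grid$y))  # nearest sample to the optical axis
  expected <- exp(-1i * pi * 2 * grid$y[ctr_idx]^2 /
                    (cfg$wavelength * cfg$mla_focal_length))
  expect_equal(mask[ctr_idx, ctr_idx], expected, tolerance = 1e-12)
})

test_that("Fresnel propagation conserves energy and is the identity at z = 0", {
  cfg <- small_cfg()
  grid <- field_grid(cfg)
  u <- debye_wavefront(c(0, 0, 4), cfg, grid)
  expect_identical(fresnel_propagate(u, 0, cfg)$values, u$values)
  prop <- fresnel_propagate(u, cfg$mla_focal_length, cfg)
  expect_equal(field_energy(prop), field_energy(u), tolerance = 1e-10)
})

test_that("propagated Gaussian beam matches the analytic waist formula", {
  lambda <- 0.52
  cfg <- optical_config(wavelength = lambda, lenslet_count = 1)
  n <- 256; spacing <- 1
  x <- (seq_len(n) - (n + 1) / 2) * spacing
  w0 <- 15
  u <- lfm_field(exp(-outer(x^2, x^2, "+") / w0^2) + 0i, spacing)
  z <- 400
  v <- fresnel_propagate(u, z, cfg)
  I <- Mod(v$values)^2
  r2 <- sum(outer(x^2, x^2, "+") * I) / sum(I)   # <r^2> = w^2/2 for |U|^2 ~ e^{-2r^2/w^2}
  w_num <- sqrt(2 * r2)
  zr <- pi * w0^2 / lambda
  w_ref <- w0 * sqrt(1 + (z / zr)^2)
  expect_equal(w_num, w_ref, tolerance = 0.01)
})

test_that("Debye wavefront is radially symmetric on axis and shifts with the source", {
  cfg <- small_cfg()
  grid <- field_grid(cfg)
  u0 <- debye_wavefront(c(0, 0, 0), cfg, grid)$values
  expect_equal(Mod(u0), Mod(u0[nrow(u0):1, ]), tolerance = 1e-12)
  expect_equal(Mod(u0), t(Mod(u0)), tolerance = 1e-12)
  # a lateral source shift of one lenslet pitch / M moves the image field by
  # exactly -1 pitch (N_i * oversample samples) on the grid
  delta <- cfg$lenslet_pitch / cfg$magnification
  u1 <- debye_wavefront(c(delta, 0, 0), cfg, grid)$values
  sh <- cfg$pixels_per_lenslet[2] * cfg$oversample
  keep <- 1:(ncol(u0) - sh)
  expect_equal(u1[, keep], u0[, keep + sh], tolerance = 1e-9)
})

test_that("in-focus central lobe matches the Airy radius at moderate NA", {
  cfg <- optical_config(numerical_aperture = 0.3, medium_refractive_index = 1.0,
                        lenslet_count = 3, oversample = 2)
  grid <- field_grid(cfg)
  u <- debye_wavefront(c(0, 0, 0), cfg, grid)$values
  ctr <- which.min(abs(grid$y))
  profile <- Mod(u[ctr, ctr:ncol(u)])
  first_min <- which(diff(profile) > 0)[1]  # first upturn = first dark ring
  r_num <- (first_min - 1) * grid$spacing   # image-plane um
  r_airy <- 0.61 * cfg$wavelength * cfg$magnification / cfg$numerical_aperture
  expect_lt(abs(r_num - r_airy), grid$spacing)
})

test_that("grid and axial-range preconditions raise errors", {
  cfg <- desk_config(lenslet_count = 3, oversample = 1)
  # NA 1.0 at 1x oversampling: object-plane spacing 0.263 um > lambda/(2 NA)
  expect_error(debye_wavefront(c(0, 0, 0), cfg), "too coarse")
  cfg2 <- small_cfg()
  expect_error(debye_wavefront(c(0, 0, 99), cfg2), "axial range")
})

test_that("PSF is non-negative, symmetric on axis, and spreads with depth", {
  cfg <- test_cfg()
  p0 <- lfm_psf(c(0, 0, 0), cfg)
  expect_true(all(p0 >= 0))
  expect_equal(p0, p0[nrow(p0):1, ], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(p0, t(p0), tolerance = 1e-12, ignore_attr = TRUE)
  rms_radius <- function(img) {
    n <- dim(img)
    y <- seq_len(n[1]) - (n[1] + 1) / 2
    x <- seq_len(n[2]) - (n[2] + 1) / 2
    sqrt(sum(outer(y^2, x^2, "+") * img) / sum(img))
  }
  radii <- vapply(seq(0, 48, by = 8),
                  function(z) rms_radius(lfm_psf(c(0, 0, z), cfg)), numeric(1))
  expect_true(all(diff(radii) > 0))
})

test_that("PSF obeys lateral equivariance at one lenslet pitch", {
  cfg <- test_cfg()
  delta <- cfg$lenslet_pitch / cfg$magnification
  h0 <- lfm_psf(c(0, 0, 8), cfg)
  h1 <- lfm_psf(c(delta, 0, 8), cfg)
  sh <- cfg$pixels_per_lenslet[2]  # image moves by -M delta = -1 pitch
  keep <- 1:(ncol(h0) - sh)
  # columns agree up to the lenslet-grid resampling / boundary truncation
  expect_lt(max(abs(h1[, keep] - h0[, keep + sh])), 1e-4 * max(h0))
})

test_that("ball discretization matches a brute-force lattice count", {
  ball <- discretize_ball(c(0, 0, 0), diameter = 10, grid_step = 1)
  count <- 0
  for (x in -5:5) for (y in -5:5) for (z in -5:5) {
    if (x^2 + y^2 + z^2 <= 25) count <- count + 1
  }
  expect_equal(nrow(ball$points), count)
  expect_true(all(rowSums(ball$points^2) <= 25 + 1e-12))
  expect_equal(sum(ball$intensity), 1)
  # degenerate ball collapses to its centre
  tiny <- discretize_ball(c(1, 2, 3), diameter = 0.5, grid_step = 1)
  expect_equal(tiny$points, matrix(c(1, 2, 3), 1))
  expect_error(discretize_ball(c(0, 0, 0), diameter = 10, grid_step = 4),
               "diameter / 4")
})

test_that("rendering is exactly linear in the emitter intensities", {
  cfg <- test_cfg()
  p1 <- c(0, 0, 8); p2 <- c(5, -5, 16)
  single <- render_lightfield(point_volume(p1), cfg)
  expect_equal(unclass(single), unclass(lfm_psf(p1, cfg)), ignore_attr = TRUE)
  v1 <- point_volume(p1, 2)
  v2 <- point_volume(p2, 3)
  both <- point_volume(rbind(p1, p2), c(2, 3))
  expect_equal(unclass(render_lightfield(both, cfg)),
               unclass(render_lightfield(v1, cfg)) + unclass(render_lightfield(v2, cfg)),
               tolerance = 1e-14, ignore_attr = TRUE)
  scaled <- point_volume(p1, 2 * 3.7)
  expect_equal(unclass(render_lightfield(scaled, cfg)),
               3.7 * unclass(render_lightfield(v1, cfg)),
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_error(render_lightfield(point_volume(p1, 0), cfg), "empty")
})

test_that("wrap-shifted rendering equals open-boundary rendering away from the border", {
  cfg <- test_cfg()
  vol <- point_volume(c(5, 0, 8))  # one lenslet pitch off axis
  open <- unclass(render_lightfield(vol, cfg))
  wrapped <- unclass(render_lightfield(vol, cfg, wrap_shift = TRUE))
  inner <- 39:247  # two lenslets in from each border
  expect_lt(max(abs(wrapped[inner, inner] - open[inner, inner])), 1e-4 * max(open))
})
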