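# 4D decoding, sub-aperture and EPI views, background purification.

test_that("decoding conserves intensity and round-trips micro-image tiling", {
  lf <- test_ball_lf(16)
  cfg <- test_cfg()
  raw <- render_lightfield(discretize_ball(c(0, 0, 16), 10, test_ball_step()), cfg)
  expect_equal(sum(lf), sum(raw))
  expect_equal(tile_microimages(lf), unclass(raw), ignore_attr = TRUE)
  expect_equal(dim(lf), c(19, 19, 15, 15))
  expect_error(decode_4d(raw, structure(list(pitch = 10,
    centers = attr(lf, "calibration")$centers), class = "lfm_calibration"), 19),
    "overlap")
})

test_that("sub-aperture slices match the 4D array and sum consistently", {
  lf <- test_ball_lf(16)
  sa <- subaperture(lf, 4, 7)
  expect_equal(sa, lf[4, 7, , ])
  expect_error(subaperture(lf, 0, 7), "out of range")
  total <- 0
  for (i in seq_len(dim(lf)[1])) for (j in seq_len(dim(lf)[2])) {
    total <- total + sum(subaperture(lf, i, j))
  }
  expect_equal(total, sum(lf))
  # central view of an in-focus bead peaks at the bead's lenslet
  lf0 <- test_ball_lf(0)
  ctr <- central_subaperture(lf0)
  expect_equal(as.vector(arrayInd(which.max(ctr), dim(ctr))), c(8, 8))
})

test_that("EPI extraction follows the fixed-index conventions", {
  lf <- test_ball_lf(16)
  eh <- extract_epi(lf, "horizontal", 10, 8)
  expect_equal(unclass(eh), lf[, 10, , 8], ignore_attr = TRUE)
  expect_equal(dim(eh), c(19, 15))
  ev <- extract_epi(lf, "vertical", 10, 8)
  expect_equal(unclass(ev), lf[10, , 8, ], ignore_attr = TRUE)
  expect_error(extract_epi(lf, "horizontal", 99, 1), "out of range")
})

test_that("epipolar line is vertical in focus and tilts more with depth", {
  s0 <- abs(epi_slope(extract_epi(test_ball_lf(0), "horizontal")))
  s8 <- abs(epi_slope(extract_epi(test_ball_lf(8), "horizontal")))
  s20 <- abs(epi_slope(extract_epi(test_ball_lf(20), "horizontal")))
  expect_lt(s0, 0.05)
  expect_gt(s20, s8)
})

test_that("lateral shifts move the epipolar line without changing its slope", {
  cfg <- test_cfg()
  pitch_obj <- transverse_sampling(cfg)
  fx0 <- make_fixture(data.frame(x = 0, y = 0, z = 16), cfg,
                      grid_step = test_ball_step())
  fx1 <- make_fixture(data.frame(x = 0, y = pitch_obj, z = 16), cfg,
                      grid_step = test_ball_step())
  lf0 <- decode_fixture(fx0); lf1 <- decode_fixture(fx1)
  e0 <- extract_epi(lf0, "horizontal", 10, 8)
  e1 <- extract_epi(lf1, "horizontal", 10, 8)
  # shifting the source by +1 lenslet pitch moves the (inverted) line by -1
  # spatial sample; slope is unchanged
  expect_equal(unclass(e1)[, 1:14], unclass(e0)[, 2:15], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(epi_slope(e1), epi_slope(e0), tolerance = 0.05)
})

test_that("rank-one background removal separates foreground exactly and orthogonally", {
  set.seed(7)
  u <- abs(rnorm(100)); v <- abs(rnorm(64))
  stack <- array(outer(u, v), dim = c(10, 10, 64))
  res <- remove_background(stack)
  expect_lt(max(abs(res$foreground)), 1e-10 * max(stack))
  expect_equal(res$background$sigma_max, sqrt(sum(u^2) * sum(v^2)))
  # background + a bright localized spot: the spot's own intensity is restored
  # within 5%.  The spot sits in a dim region of the background (small
  # singular-vector components), which is the separable regime; a spot
  # constant across views would itself be rank one and be absorbed.
  spot <- array(0, dim = c(10, 10, 64))
  px <- arrayInd(which.min(u), c(10, 10))
  vw <- which.min(v)
  spot[px[1], px[2], vw] <- 0.5 * max(u) * max(v)
  res2 <- remove_background(stack + spot)
  expect_lt(abs(res2$foreground[px[1], px[2], vw] - spot[px[1], px[2], vw]) /
              spot[px[1], px[2], vw], 0.05)
  # Pythagoras and orthogonality of the SVD split
  A <- matrix(stack + spot, nrow = 100)
  B <- res2$background$u_max %*% (res2$background$sigma_max * t(res2$background$v_max))
  FG <- matrix(res2$foreground, nrow = 100)
  expect_equal(sum(A^2), sum(B^2) + sum(FG^2))
  expect_lt(abs(sum(FG * B)), 1e-8 * sum(A^2))
  expect_error(remove_background(array(0, dim = c(4, 4, 3))), "all-zero")
  expect_error(remove_background(array(1, dim = c(4, 4, 1))), "at least 2")
})

test_that("light-field purification subtracts the shared background per view", {
  lf <- test_ball_lf(12)
  base <- unclass(lf)
  bg <- array(0, dim = dim(base))
  prof <- outer(exp(-((1:15 - 8)^2) / 60), exp(-((1:15 - 7)^2) / 80))
  for (i in 1:19) for (j in 1:19) bg[i, j, , ] <- 0.3 * max(base) * prof
  corrupted <- structure(base + bg, calibration = attr(lf, "calibration"),
                         vignetted = attr(lf, "vignetted"),
                         class = c("lfm_lightfield4d", "array"))
  out <- purify_lightfield(corrupted)
  expect_s3_class(out$lightfield, "lfm_lightfield4d")
  # purification brings the field closer to the clean signal than the
  # corrupted input was
  rel_pure <- sqrt(sum((unclass(out$lightfield) - base)^2) / sum(base^2))
  rel_corrupt <- sqrt(sum((unclass(corrupted) - base)^2) / sum(base^2))
  expect_lt(rel_pure, 0.5 * rel_corrupt)
  peak_true <- arrayInd(which.max(central_subaperture(lf)), c(15, 15))
  peak_pure <- arrayInd(which.max(central_subaperture(out$lightfield)), c(15, 15))
  expect_equal(peak_pure, peak_true)
})

test_that("max-projection profiles pick per-row and per-column maxima", {
  epi <- matrix(0, 5, 7)
  epi[2, 3] <- 4; epi[5, 6] <- 2
  mp <- max_projection_epi(epi)
  expect_equal(mp$row_profile, c(0, 4, 0, 0, 2))
  expect_equal(mp$col_profile, c(0, 0, 4, 0, 0, 2, 0))
  const <- max_projection_epi(matrix(3, 4, 4))
  expect_equal(const$row_profile, rep(3, 4))
  expect_equal(const$col_profile, rep(3, 4))
  # adding a strictly dimmer pixel changes nothing
  epi2 <- epi; epi2[3, 3] <- 1
  expect_equal(max_projection_epi(epi2)$col_profile, mp$col_profile)
})

test_that("raw images round-trip through 32-bit float TIFF", {
  cfg <- desk_config(lenslet_count = 3)
  img <- render_lightfield(point_volume(c(0, 0, 8)), cfg)
  path <- withr::local_tempfile(fileext = ".tif")
  write_lightfield_tiff(img, path)
  back <- read_lightfield_tiff(path)
  expect_equal(unclass(back), unclass(img), tolerance = 1e-6, ignore_attr = TRUE)
})
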