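# Shared heavy fixtures, built lazily and at most once per test session.
# The desk-scale preset (15 x 15 lenslets, 19 x 19 px, 2x oversampling) with a
# 10 um ball discretized at 2 um is used for all end-to-end experiments.

.shared <- new.env(parent = emptyenv())

shared <- function(name, build) {
  if (is.null(.shared[[name]])) .shared[[name]] <- build()
  .shared[[name]]
}

test_cfg <- function() shared("cfg", function() desk_config())

test_ball_step <- function() 2

test_depths <- function() seq(0, 48, by = 4)

test_dictionary <- function() shared("dict", function() {
  build_dictionary(test_cfg(), depths = test_depths(), grid_step = test_ball_step())
})

test_vertical_dictionary <- function() shared("dict_v", function() {
  build_dictionary(test_cfg(), depths = test_depths(), grid_step = test_ball_step(),
                   orientation = "vertical")
})

# a decoded light-field of a centred ball at the given depth (cached)
test_ball_lf <- function(z) shared(paste0("lf", z), function() {
  cfg <- test_cfg()
  raw <- render_lightfield(discretize_ball(c(0, 0, z), 10, test_ball_step()), cfg)
  decode_4d(raw, calibration_from_config(cfg), cfg$pixels_per_lenslet)
})

# the 20 seeded single-bead recovery fixtures: on-grid depths, lateral
# positions uniform on the d/M lenslet grid within +/- 2 lenslets
recovery_fixtures <- function() shared("recovery", function() {
  cfg <- test_cfg()
  pitch_obj <- transverse_sampling(cfg)  # 5 um
  withr::with_seed(20240117, {
    lapply(seq_len(20), function(i) {
      src <- data.frame(
        x = sample(-2:2, 1) * pitch_obj,
        y = sample(-2:2, 1) * pitch_obj,
        z = sample(test_depths(), 1))
      make_fixture(src, cfg, grid_step = test_ball_step(), seed = 1000 + i)
    })
  })
})

decode_fixture <- function(fx) {
  cfg <- test_cfg()
  decode_4d(fx$image, calibration_from_config(cfg), cfg$pixels_per_lenslet)
}

# deep out-of-focus emitter lattice lighting every lenslet uniformly - the
# analogue of the out-of-focus exposure used for calibration.  Point emitters
# on the lenslet-pitch lattice all reuse one cached PSF, so the scene is cheap.
calibration_scene <- function() shared("calib_scene", function() {
  cfg <- test_cfg()
  g <- seq(-35, 35, by = 5)
  src <- expand.grid(x = g, y = g)
  src$z <- 40
  src$diameter <- 0
  unclass(make_fixture(src, cfg)$image)
})
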