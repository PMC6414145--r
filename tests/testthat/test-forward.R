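test_that("instantaneous transit image follows the attenuation law", {
  sp <- small_spec(pixels = 32)
  fwd <- forward_model(alpha = 0.05, beta = 1e-4, i0 = 1e4, k0 = 0)
  beam <- beam_model(10, 10, wedge = TRUE)

  # no phantom: the image is I0 * fluence (open field), wedge ramp along x
  img0 <- render_transit_image(make_slab_phantom(0), beam, 0, fwd, sp)
  g <- grid_coords(32, 32, 0.4)
  expected <- matrix(0, 32, 32)
  for (r in 1:32) for (c in 1:32) {
    x <- g$x[c]; y <- g$y[r]
    if (abs(x) <= 5 && abs(y) <= 5)
      expected[r, c] <- 1e4 * (0.5 + 0.5 * (x / 10 + 0.5))
  }
  expect_equal(img0, expected, ignore_attr = TRUE, tolerance = 1e-12)

  # uniform 10 cm slab, no scatter: ratio to open field is exp(-0.51)
  img10 <- render_transit_image(make_slab_phantom(10), beam, 0, fwd, sp)
  infield <- img0 > 0
  expect_equal(unique(round(img10[infield] / img0[infield], 10)),
               round(exp(-0.51), 10))

  # scatter multiplies the primary by (1 + k0 * A * t)
  fwd_s <- forward_model(alpha = 0.05, beta = 1e-4, i0 = 1e4, k0 = 1.93e-5)
  img10s <- render_transit_image(make_slab_phantom(10), beam, 0, fwd_s, sp)
  expect_equal(img10s[infield] / img10[infield],
               rep(1 + 1.93e-5 * 100 * 10, sum(infield)))
})

test_that("displacement translates the phantom-dependent signal, aperture fixed", {
  sp <- small_spec(pixels = 64, pitch = 0.2)
  fwd <- forward_model(k0 = 0)
  beam <- beam_model(20, 20)  # aperture beyond the shifted comparison zone
  ph <- make_breast_phantom(10, dome_semiaxes = c(3, 3), chest_halfwidth = c(5, 5))
  a <- render_transit_image(ph, beam, 0, fwd, sp)
  b <- render_transit_image(ph, beam, 1.0, fwd, sp)  # +1 cm = 5 px at 0.2 cm
  expect_equal(b[, 6:64], a[, 1:59], tolerance = 1e-12)
})

test_that("static acquisition equals dark level plus the instantaneous render", {
  sp <- small_spec(pixels = 24, n_frames = 4, noise = 0)
  fwd <- forward_model()
  beam <- beam_model(8, 8)
  ph <- make_breast_phantom(12)
  img <- acquire(ph, beam, make_static_trace(5), fwd, sp, start_offset = 0)
  ref <- render_transit_image(ph, beam, 0, fwd, sp)
  expect_false(img$is_dark_corrected)
  expect_equal(img$pixels, ref + 100, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("zero-amplitude motion is bit-identical to the static acquisition", {
  sp <- small_spec(pixels = 24, n_frames = 5, noise = 0.005, seed = 31)
  fwd <- forward_model()
  beam <- beam_model(8, 8)
  ph <- make_breast_phantom(12)
  a <- acquire(ph, beam, make_static_trace(10), fwd, sp)
  b <- acquire(ph, beam, make_sinusoid_trace(0, 12, duration = 10), fwd, sp)
  expect_identical(a$pixels, b$pixels)

  # and acquisition is a pure function of its arguments including seed
  a2 <- acquire(ph, beam, make_static_trace(10), fwd, sp)
  expect_identical(a$pixels, a2$pixels)
  sp2 <- sp; sp2$seed <- 32L
  a3 <- acquire(ph, beam, make_static_trace(10), fwd, sp2)
  expect_false(identical(a$pixels, a3$pixels))
})

test_that("frame averaging converges to the dense-time quadrature", {
  fwd <- forward_model()
  beam <- beam_model(10, 6)
  ph <- make_breast_phantom(12, dome_semiaxes = c(4, 3))
  trace <- make_sinusoid_trace(1.0, 14, duration = 30)
  delivery <- 25.8

  sp60 <- acquisition_spec(n_frames = 60, frame_time = delivery / 60,
                           pixels_x = 48, pixels_y = 48, pixel_pitch = 0.25,
                           noise_scale = 0, dark_level = 0, seed = 1)
  img60 <- acquire(ph, beam, trace, fwd, sp60, start_offset = 0)
  oracle <- acquire_oracle(ph, beam, trace, fwd, sp60, start_offset = 0,
                           n_sub = 3000)
  open_level <- fwd$i0
  expect_lt(max(abs(img60$pixels - oracle)), 0.002 * open_level)

  # and a 6000-frame acquisition is closer still
  sp6k <- sp60; sp6k$n_frames <- 6000L; sp6k$frame_time <- delivery / 6000
  img6k <- acquire(ph, beam, trace, fwd, sp6k, start_offset = 0)
  expect_lt(max(abs(img6k$pixels - oracle)),
            max(abs(img60$pixels - oracle)) + 1e-9)
})

test_that("motion blur widens the attenuation footprint, bounded by the excursion", {
  # phantom edge moving with +/-1.5 cm: the region showing attenuation
  # grows, by at most one amplitude per side (plus discretisation)
  fwd <- forward_model(k0 = 0)
  beam <- beam_model(20, 10)
  ph <- make_breast_phantom(10, dome_semiaxes = c(5, 4),
                            chest_halfwidth = c(6, 7))
  sp <- acquisition_spec(n_frames = 60, frame_time = 0.43, pixels_x = 128,
                         pixels_y = 64, pixel_pitch = 0.2, noise_scale = 0,
                         dark_level = 0, seed = 1)
  stat <- acquire(ph, beam, make_static_trace(30), fwd, sp, start_offset = 0)
  mov <- acquire(ph, beam, make_sinusoid_trace(1.5, 12, duration = 30),
                 fwd, sp, start_offset = 0)
  row <- 32
  footprint <- function(img) {
    p <- img$pixels[row, ]
    p <- p[p > 0]                      # in-field pixels only
    prof <- -log(p / max(p))           # ~thickness
    sum(prof > 0.05 * max(prof)) * sp$pixel_pitch
  }
  widening <- footprint(mov) - footprint(stat)
  expect_gt(widening, 0.4)
  expect_lte(widening, 3.0 + 2 * sp$pixel_pitch)

  # and blurring never deepens the attenuation: the moving image is at
  # least as bright as the static one at the static maximum-thickness pixel
  peak <- which(stat$pixels == min(stat$pixels[stat$pixels > 0]),
                arr.ind = TRUE)[1, ]
  expect_gte(mov$pixels[peak[1], peak[2]], stat$pixels[peak[1], peak[2]])
})

test_that("the calibration series has the designed structure", {
  sp <- small_spec(pixels = 16, n_frames = 2)
  ser <- make_calibration_series(spec = sp, forward = forward_model())
  expect_length(ser$images, 7)
  expect_equal(ser$thicknesses, c(0, 2, 4, 7, 11, 16, 21))
  expect_equal(ser$dark$pixels[1, 1], 100)

  # attenuation is monotone: every slab image is darker than the open field
  means <- vapply(ser$images, function(im) mean(im$pixels), numeric(1))
  expect_true(all(diff(means) < 0))

  expect_error(make_calibration_series(c(0), spec = sp), "underdetermined")
  expect_error(make_calibration_series(c(2, 4, 7), spec = sp), "including 0")
})

test_that("acquisition rejects traces shorter than the delivery", {
  sp <- small_spec(pixels = 8, n_frames = 10)
  expect_error(acquire(make_slab_phantom(1), beam_model(5, 5),
                       make_static_trace(2), forward_model(), sp),
               "shorter")
})
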