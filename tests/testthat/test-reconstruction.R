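test_that("scatter-to-primary ratio matches hand values and validates inputs", {
  # 1.93e-5 * 676 * 21 and 1.93e-5 * 112 * 10, by hand
  expect_equal(spr(21, 676, scatter_model()), 0.2739828)
  expect_equal(spr(10, 112, scatter_model()), 0.0216160)
  expect_equal(spr(0, 676, scatter_model()), 0)
  m <- matrix(c(0, 5, 10, 21), 2)
  expect_equal(spr(m, 100, scatter_model()), 1.93e-5 * 100 * m)
  expect_error(spr(-1, 676), ">= 0")
  expect_error(scatter_model(k0 = -1), ">= 0")
  expect_error(scatter_model(area_treat = 0), "> 0")
})

test_that("quadratic inversion solves the attenuation model", {
  # -ln(I/I0) = 0.51 = 0.05*10 + 1e-4*100 exactly: t = 10
  expect_equal(invert_quadratic(exp(-0.51), 1, 0.05, 1e-4), 10,
               tolerance = 1e-12)
  # consistency over the full thickness range
  tt <- seq(0, 21, by = 0.5)
  I <- exp(-0.05 * tt - 1e-4 * tt^2)
  expect_equal(invert_quadratic(I, 1, 0.05, 1e-4), tt, tolerance = 1e-9)

  # tiny beta agrees with the exact linear limit
  expect_equal(invert_quadratic(exp(-0.5), 1, 0.05, 1e-12),
               invert_quadratic(exp(-0.5), 1, 0.05, 0), tolerance = 1e-6)

  # clamps and invalid pixels
  expect_equal(invert_quadratic(1.2, 1, 0.05, 1e-4), 0)   # I > I0
  expect_true(is.na(invert_quadratic(0, 1, 0.05, 1e-4)))  # no signal
  expect_true(is.na(invert_quadratic(0.5, 1, -0.01, 1e-4)))
  # negative discriminant (unphysical negative beta) yields NA
  expect_true(is.na(invert_quadratic(exp(-1), 1, 0.05, -0.01)))

  # shape preservation
  M <- matrix(exp(-0.05 * c(1, 2, 3, 4)), 2)
  expect_equal(dim(invert_quadratic(M, 1, 0.05, 0)), c(2, 2))
})

test_that("reconstruction fixed point matches a scalar root-finding oracle", {
  # exact calibration, image with treatment-field scatter only: the
  # iterative correction must land on the root of the full forward curve
  cal <- fit_quadratic(direct_series(0.05, 1e-4, pixels = 4))
  k0 <- 1.93e-5; A_t <- 112
  ratio <- 0.55   # not generated from a round thickness
  img <- portal_image(matrix(1e4 * ratio, 4, 4), 0.4, is_dark_corrected = TRUE)
  sc <- scatter_model(k0 = k0, area_calib = 1e-9, area_treat = A_t)
  tm <- reconstruct(img, cal, open_treat = NULL, scatter = sc, tol = 1e-8,
                    max_iter = 50)
  want <- scalar_thickness_oracle(ratio, 0.05, 1e-4, k0, A_t)
  expect_true(tm$converged)
  expect_equal(unique(round(as.vector(tm$t), 6)), round(want, 6))
})

test_that("forward/backward consistency on a uniform slab with both scatters", {
  # calibration series carries calibration-field scatter; the treatment
  # image carries treatment-field scatter; reconstruction must undo the
  # difference and recover the true slab thickness
  sp <- small_spec(pixels = 16)
  fwd <- forward_model()   # k0 on
  cal <- fit_quadratic(make_calibration_series(forward = fwd, spec = sp))
  beam_t <- beam_model(14, 8)
  tr <- make_static_trace(5)
  dark <- portal_image(matrix(100, 16, 16), sp$pixel_pitch)
  img <- dark_correct(acquire(make_slab_phantom(10), beam_t, tr, fwd, sp,
                              start_offset = 0), dark)
  open_t <- dark_correct(acquire(make_slab_phantom(0), beam_t, tr, fwd, sp,
                                 start_offset = 0), dark)
  tm <- reconstruct(img, cal, open_treat = open_t,
                    scatter = scatter_model(area_calib = 676, area_treat = 112))
  infield <- open_t$pixels > 0
  expect_true(tm$converged)
  expect_lte(tm$iterations_run, 5)
  err <- abs(tm$t[infield & tm$valid] - 10)
  expect_lt(sqrt(mean(err^2)), 0.05)
})

test_that("the output factor divides out static fluence modulation", {
  # a wedge multiplies both the treatment image and its open field;
  # with F applied the reconstructed slab is uniform, without it the
  # thickness acquires a spurious gradient
  sp <- small_spec(pixels = 32)
  fwd <- forward_model()
  cal <- fit_quadratic(make_calibration_series(forward = fwd, spec = sp))
  wedge <- beam_model(10, 10, wedge = TRUE)
  tr <- make_static_trace(5)
  dark <- portal_image(matrix(100, 32, 32), sp$pixel_pitch)
  img <- dark_correct(acquire(make_slab_phantom(8), wedge, tr, fwd, sp,
                              start_offset = 0), dark)
  open_t <- dark_correct(acquire(make_slab_phantom(0), wedge, tr, fwd, sp,
                                 start_offset = 0), dark)
  sc <- scatter_model(area_calib = 676, area_treat = 100)
  with_f <- reconstruct(img, cal, open_treat = open_t, scatter = sc)
  no_f <- reconstruct(img, cal, open_treat = NULL, scatter = sc)
  infield <- open_t$pixels > 0
  expect_lt(max(abs(with_f$t[infield & with_f$valid] - 8)), 0.05)
  expect_gt(diff(range(no_f$t[infield & no_f$valid])), 1)
})

test_that("reconstruction is a per-pixel map (transpose equivariance)", {
  cal <- fit_quadratic(direct_series(0.05, 1e-4, pixels = 6))
  px <- matrix(1e4 * exp(-0.05 * seq(0.5, 18, length.out = 36)), 6)
  a <- reconstruct(portal_image(px, 0.4, is_dark_corrected = TRUE), cal)
  b <- reconstruct(portal_image(t(px), 0.4, is_dark_corrected = TRUE), cal)
  expect_equal(b$t, t(a$t))
})

test_that("fixed iteration schedule and non-convergence are reported honestly", {
  cal <- fit_quadratic(direct_series(0.05, 1e-4, pixels = 4))
  img <- portal_image(matrix(1e4 * exp(-0.6), 4, 4), 0.4,
                      is_dark_corrected = TRUE)
  tm5 <- reconstruct(img, cal, fixed_iters = 5)
  expect_identical(tm5$iterations_run, 5L)
  expect_true(tm5$converged)

  # tol = 0 can never be reached: the warning must fire
  expect_warning(reconstruct(img, cal, tol = 0, max_iter = 3),
                 "did not reach")

  # dead pixels come back invalid with zero thickness
  img$pixels[1, 1] <- 0
  tm <- reconstruct(img, cal)
  expect_false(tm$valid[1, 1])
  expect_identical(tm$t[1, 1], 0)

  expect_error(reconstruct(portal_image(matrix(1, 4, 4), 0.4), cal),
               "dark-corrected")
  expect_error(reconstruct(portal_image(matrix(1, 3, 3), 0.4,
                                        is_dark_corrected = TRUE), cal),
               "grids differ")
})
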