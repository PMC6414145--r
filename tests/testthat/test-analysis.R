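test_that("thickness-to-intensity conversion matches the closed form and round-trips", {
  expect_equal(thickness_to_intensity(matrix(10, 1, 1))$dose[1, 1],
               exp(-0.51), tolerance = 1e-12)
  expect_equal(thickness_to_intensity(matrix(0, 1, 1))$dose[1, 1], 1)

  # inversion of the conversion reproduces the thickness to 1e-9
  tt <- matrix(seq(0, 21, length.out = 64), 8)
  d <- thickness_to_intensity(tt)
  back <- invert_quadratic(d$dose, 1, 0.05, 1e-4)
  expect_lt(max(abs(back - tt)), 1e-9)

  expect_error(thickness_to_intensity(matrix(-1, 1, 1)), ">= 0")
})

test_that("dose-difference percentages are exact counts", {
  ref <- matrix(1, 2, 2)
  ev <- matrix(1 + c(0.005, 0.015, 0.025, 0.06), 2)
  roi <- matrix(TRUE, 2, 2)
  s <- dose_diff_summary(ev, ref, roi, thresholds = c(5, 3, 2, 1))
  expect_equal(unname(s$pct_within), c(75, 75, 50, 25))
  expect_equal(s$n_roi, 4)
  expect_equal(s$diff, ev - 1)

  # difference is local-relative: scaling both images changes nothing
  s2 <- dose_diff_summary(7 * ev, 7 * ref, roi)
  expect_equal(s2$pct_within, s$pct_within)

  # identical images are 100% within every threshold
  s3 <- dose_diff_summary(ref, ref, roi, thresholds = c(1, 0.1))
  expect_equal(unname(s3$pct_within), c(100, 100))

  # pixels outside the ROI are excluded; a boundary |diff| == threshold
  # passes (values chosen exactly representable in binary)
  roi2 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
  expect_equal(unname(dose_diff_summary(matrix(1.25, 2, 2), ref, roi2,
                                        thresholds = 25)$pct_within), 100)
  expect_error(dose_diff_summary(ev, matrix(0, 2, 2), roi), "positive")
  expect_error(dose_diff_summary(ev, matrix(1, 3, 3), roi), "grids differ")
})

test_that("gamma of identical images is zero; a uniform offset gives the exact ratio", {
  d <- matrix(runif(64, 0.5, 1), 8)
  roi <- matrix(TRUE, 8, 8)
  g0 <- gamma_2d(d, d, roi, 3, 3, pixel_pitch_cm = 0.1)
  expect_equal(max(g0$gamma), 0)
  expect_equal(g0$pass_rate, 100)

  # uniform reference, evaluated 3% higher at 3%/3mm: the dose term is
  # exactly 1 everywhere and distance cannot help
  ref <- matrix(1, 8, 8)
  g1 <- gamma_2d(matrix(1.03, 8, 8), ref, roi, 3, 3, pixel_pitch_cm = 0.1)
  expect_equal(unique(round(as.vector(g1$gamma), 9)), 1)
  expect_equal(g1$pass_rate, 0)   # pass requires gamma < 1, strictly

  # at 6%/3mm the same offset halves gamma
  g2 <- gamma_2d(matrix(1.03, 8, 8), ref, roi, 6, 3, pixel_pitch_cm = 0.1)
  expect_equal(unique(round(as.vector(g2$gamma), 9)), 0.5)
  expect_equal(g2$pass_rate, 100)
})

test_that("gamma matches the exhaustive fine-grid oracle on a shifted edge", {
  # smooth ramp edge shifted by 2 pixels (2 mm at 0.1 cm pitch)
  nr <- 24; nc <- 24
  edge <- function(shift) {
    x <- outer(rep(1, nr), seq_len(nc)) - shift
    0.2 + 0.8 / (1 + exp(-(x - 12)))
  }
  rf <- edge(0); ev <- edge(2)
  roi <- matrix(FALSE, nr, nc); roi[5:20, 5:20] <- TRUE

  for (crit in list(c(3, 3), c(2, 2), c(1, 1))) {
    g <- gamma_2d(ev, rf, roi, crit[1], crit[2], pixel_pitch_cm = 0.1)
    o <- gamma_oracle(ev, rf, roi, crit[1], crit[2], 0.1, fine = 10)
    expect_lt(max(abs(g$gamma[roi] - o[roi])), 0.05)
  }

  # 3%/3mm passes everywhere (2 mm shift within tolerance); 1%/1mm fails
  # in the edge band
  g33 <- gamma_2d(ev, rf, roi, 3, 3, pixel_pitch_cm = 0.1)
  g11 <- gamma_2d(ev, rf, roi, 1, 1, pixel_pitch_cm = 0.1)
  expect_equal(g33$pass_rate, 100)
  expect_lt(g11$pass_rate, 100)
  expect_gt(sum(g11$gamma[roi] >= 1), 0)
})

test_that("gamma orderings: stricter criteria never pass more pixels", {
  set.seed(7)
  rf <- matrix(0.5 + 0.5 * outer(sin(seq(0, 3, length.out = 20)),
                                 cos(seq(0, 3, length.out = 20))), 20)
  rf <- rf + 0.6
  ev <- rf * (1 + matrix(rnorm(400, 0, 0.02), 20))
  roi <- matrix(TRUE, 20, 20)
  crits <- list(c(5, 5), c(3, 3), c(2, 2), c(1, 1))
  rates <- vapply(crits, function(cr)
    gamma_2d(ev, rf, roi, cr[1], cr[2], pixel_pitch_cm = 0.1)$pass_rate,
    numeric(1))
  expect_true(all(diff(rates) <= 0))

  # gamma passing is at least as permissive as dose-difference alone at
  # the same dose criterion (distance search can only reduce gamma)
  dd <- dose_diff_summary(ev, rf, roi, thresholds = 2)
  g22 <- gamma_2d(ev, rf, roi, 2, 2, pixel_pitch_cm = 0.1)
  expect_gte(g22$pass_rate + 1e-9, unname(dd$pct_within))
})

test_that("gamma rejects an undersampled native-grid search", {
  d <- matrix(1, 8, 8)
  expect_error(gamma_2d(d, d, NULL, 3, 0.5, pixel_pitch_cm = 0.1,
                        interp_factor = 1),
               "interp")
  expect_silent(gamma_2d(d, d, NULL, 3, 1, pixel_pitch_cm = 0.1,
                         interp_factor = 1))
  expect_error(gamma_2d(d, d, NULL, -3, 3, pixel_pitch_cm = 0.1), "positive")
  expect_error(gamma_2d(d, d, NULL, 3, 3), "pixel_pitch")
})

test_that("row and oblique profiles agree with direct indexing", {
  m <- matrix(seq_len(48), 6, 8)
  p <- profile_1d(m, row = 3, pixel_pitch_cm = 0.2)
  expect_equal(p$value, m[3, ])
  expect_equal(diff(p$pos_cm), rep(0.2, 7))

  # oblique profile along a constant row reproduces bilinear samples
  po <- profile_1d(m, from = c(-0.5, 0), to = c(0.5, 0), n = 5,
                   pixel_pitch_cm = 0.2)
  expect_equal(nrow(po), 5)
  expect_equal(po$pos_cm, seq(0, 1, by = 0.25))
  expect_error(profile_1d(m, row = 99), "outside")
  expect_error(profile_1d(m, from = c(-99, 0), to = c(0, 0),
                          pixel_pitch_cm = 0.2), "leaves the grid")
})
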