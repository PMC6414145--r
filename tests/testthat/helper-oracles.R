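# Shared fixtures and independent oracles used across the suite.
# Oracles deliberately avoid the code paths they check: the gamma oracle
# is an exhaustive fine-grid search, the acquisition oracle a dense-time
# quadrature, the inversion oracle a scalar root bracket.

# small, fast acquisition geometry (noiseless by default)
small_spec <- function(pixels = 64, pitch = 0.4, n_frames = 3,
                       noise = 0, seed = 1, frame_time = 0.43) {
  acquisition_spec(n_frames = n_frames, frame_time = frame_time,
                   pixels_x = pixels, pixels_y = pixels, pixel_pitch = pitch,
                   noise_scale = noise, dark_level = 100, seed = seed)
}

# exhaustive local-dose gamma: reference bilinearly upsampled onto a
# grid `fine` times denser, searched with no radius cutoff
gamma_oracle <- function(ev, rf, roi, dose_pct, dist_mm, pitch_cm,
                         fine = 10) {
  nr <- nrow(rf); nc <- ncol(rf)
  pitch_mm <- pitch_cm * 10
  fr <- seq(1, nr, by = 1 / fine)
  fc <- seq(1, nc, by = 1 / fine)
  up <- apply(rf, 2, function(col) approx(seq_len(nr), col, xout = fr)$y)
  up <- t(apply(up, 1, function(row) approx(seq_len(nc), row, xout = fc)$y))
  rpos <- (fr - 1) * pitch_mm
  cpos <- (fc - 1) * pitch_mm
  pos_ok <- up > 0
  frac <- dose_pct / 100
  g <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!roi[r, c]) next
    de <- ev[r, c]
    if (!is.finite(de)) next
    d2 <- outer((rpos - (r - 1) * pitch_mm)^2, (cpos - (c - 1) * pitch_mm)^2, "+")
    dd <- (de - up) / (frac * up)
    g2 <- d2 / dist_mm^2 + dd^2
    g[r, c] <- sqrt(min(g2[pos_ok]))
  }
  g
}

# dense-time quadrature acquisition oracle: average the instantaneous
# render over a fine time grid instead of frame midpoints
acquire_oracle <- function(phantom, beam, trace, forward, spec,
                           start_offset = 0, n_sub = 2000) {
  delivery <- spec$n_frames * spec$frame_time
  ts <- min(trace$times) + start_offset +
    (seq_len(n_sub) - 0.5) * delivery / n_sub
  disp <- trace_displacement(trace, ts)
  acc <- 0
  for (d in disp)
    acc <- acc + render_transit_image(phantom, beam, d, forward, spec,
                                      t_max = Inf)
  acc / n_sub + spec$dark_level
}

# scalar thickness oracle: root of the forward curve for one pixel,
# including the treatment-field scatter factor
scalar_thickness_oracle <- function(I_over_I0, alpha, beta, k0, area_treat) {
  f <- function(t) exp(-alpha * t - beta * t^2) * (1 + k0 * area_treat * t) -
    I_over_I0
  uniroot(f, c(0, 50), tol = 1e-12)$root
}

# noiseless scatter-free calibration series generated directly from the
# attenuation law (not via the package's acquisition path)
direct_series <- function(alpha0, beta0, i0 = 1e4, pixels = 8,
                          thicknesses = c(0, 2, 4, 7, 11, 16, 21)) {
  imgs <- lapply(thicknesses, function(t) {
    p <- matrix(i0 * exp(-alpha0 * t - beta0 * t^2), pixels, pixels)
    portal_image(p, 0.4, is_dark_corrected = TRUE,
                 meta = list(thickness_cm = t))
  })
  list(images = imgs,
       dark = portal_image(matrix(0, pixels, pixels), 0.4),
       field_area = 676)
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
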