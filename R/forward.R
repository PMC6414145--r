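# Forward model and frame-integrated acquisition.  The detector signal
# for an object of water-equivalent thickness t is
#     I = I0 * fluence * exp(-alpha0*t - beta0*t^2) * (1 + k0*A*t),
# i.e. a quadratic-exponent primary plus a first-order multiplicative
# scatter-to-primary term proportional to field area and thickness.
# Acquisition averages this over the frames of the delivery while the
# phantom follows a motion trace, then adds the dark-current offset.

#' Acquisition specification
#'
#' Frame-integrated acquisition parameters of the portal imager.
#' Defaults follow a 100 MU exposure read out as 60 frames of 430 ms,
#' on a 256 x 256 grid with 0.1 cm pixels at the isocentre plane.
#'
#' @param n_frames Number of frames (>= 1).
#' @param frame_time Frame integration time in seconds.
#' @param pixels_x,pixels_y Grid size (columns, rows).
#' @param pixel_pitch Pixel pitch in cm at the isocentre plane.
#' @param noise_scale Relative standard deviation of the per-frame
#'   multiplicative Gaussian noise (0 disables noise).
#' @param dark_level Dark-current offset in counts.
#' @param seed Integer seed for the acquisition noise and start offset.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_frames = 60, frame_time = 0.43,
                             pixels_x = 256, pixels_y = 256,
                             pixel_pitch = 0.1, noise_scale = 0.005,
                             dark_level = 100, seed = 1) {
  if (n_frames < 1) stop("`n_frames` must be >= 1", call. = FALSE)
  if (frame_time <= 0) stop("`frame_time` must be > 0", call. = FALSE)
  if (noise_scale < 0) stop("`noise_scale` must be >= 0", call. = FALSE)
  if (pixel_pitch <= 0) stop("`pixel_pitch` must be > 0", call. = FALSE)
  structure(list(n_frames = as.integer(n_frames), frame_time = frame_time,
                 pixels_x = as.integer(pixels_x),
                 pixels_y = as.integer(pixels_y),
                 pixel_pitch = pixel_pitch, noise_scale = noise_scale,
                 dark_level = dark_level, seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Forward-model coefficients
#'
#' Scalar attenuation and scatter coefficients used to synthesise
#' detector images.  `alpha` and `beta` are the quadratic-exponent
#' attenuation coefficients, `i0` the open-field signal level in counts,
#' and `k0` the scatter-to-primary coefficient (per cm^3, multiplying
#' field area times thickness).
#'
#' @param alpha Linear attenuation coefficient (1/cm), > 0.
#' @param beta Quadratic beam-hardening coefficient (1/cm^2), >= 0.
#' @param i0 Open-field signal (counts), > 0.
#' @param k0 Scatter-to-primary coefficient (1/cm^3), >= 0; 0 disables
#'   scatter in the synthetic images.
#' @return An object of class `forward_model`.
#' @export
forward_model <- function(alpha = 0.05, beta = 1e-4, i0 = 1e4,
                          k0 = 1.93e-5) {
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  if (i0 <= 0) stop("`i0` must be > 0", call. = FALSE)
  if (k0 < 0) stop("`k0` must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, i0 = i0, k0 = k0),
            class = "forward_model")
}

#' Portal image container
#'
#' @param pixels Numeric matrix of detector counts (rows = y, cols = x).
#' @param pixel_pitch Pixel pitch in cm.
#' @param is_dark_corrected Has the dark-current offset been subtracted?
#' @param meta Named list of acquisition provenance.
#' @return An object of class `portal_image`.
#' @export
portal_image <- function(pixels, pixel_pitch, is_dark_corrected = FALSE,
                         meta = list()) {
  stopifnot(is.matrix(pixels))
  if (!all(is.finite(pixels))) stop("pixel values must be finite", call. = FALSE)
  structure(list(pixels = pixels, pixel_pitch = pixel_pitch,
                 is_dark_corrected = isTRUE(is_dark_corrected), meta = meta),
            class = "portal_image")
}

#' @export
print.portal_image <- function(x, ...) {
  cat(sprintf("<portal_image> %d x %d px @ %.3g cm, %s, range [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch,
              if (x$is_dark_corrected) "dark-corrected" else "raw",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Render an instantaneous (single-frame) transit image
#'
#' Samples the phantom thickness at `x - displacement`, applies the
#' quadratic-exponent attenuation and the first-order scatter term, and
#' multiplies by the beam fluence (zero outside the aperture).  No dark
#' offset and no noise: this is the noiseless single-time-point signal.
#'
#' @param phantom A `phantom_model`.
#' @param beam A `beam_model` (its `area` is the scatter field area).
#' @param displacement Phantom displacement along +x in cm.
#' @param forward A `forward_model`.
#' @param spec An `acquisition_spec` (grid geometry only is used).
#' @param t_max Calibrated thickness range ceiling; thickness beyond it
#'   sets an `extrapolated` flag on the result.
#' @return Numeric matrix of detector counts with attribute
#'   `extrapolated` (logical).
#' @export
render_transit_image <- function(phantom, beam, displacement = 0,
                                 forward = forward_model(),
                                 spec = acquisition_spec(), t_max = 21) {
  stopifnot(inherits(phantom, "phantom_model"), inherits(beam, "beam_model"),
            inherits(forward, "forward_model"),
            inherits(spec, "acquisition_spec"))
  stopifnot_scalar(displacement, "displacement")
  nx <- spec$pixels_x; ny <- spec$pixels_y; pitch <- spec$pixel_pitch
  tmap <- sample_thickness(phantom, nx, ny, pitch, displacement)
  g <- grid_coords(nx, ny, pitch)
  X <- matrix(g$x, nrow = ny, ncol = nx, byrow = TRUE)
  Y <- matrix(g$y, nrow = ny, ncol = nx)
  flu <- matrix(beam$fluence_fn(as.vector(X), as.vector(Y)), nrow = ny)
  primary <- forward$i0 * flu * exp(-forward$alpha * tmap - forward$beta * tmap^2)
  img <- primary * (1 + forward$k0 * beam$area * tmap)
  extrap <- any(tmap[flu > 0] > t_max)
  if (extrap)
    warning("phantom thickness exceeds the calibrated range (extrapolation)",
            call. = FALSE)
  attr(img, "extrapolated") <- extrap
  img
}

#' Acquire a frame-integrated portal image
#'
#' Averages the instantaneous transit image over the delivery frames,
#' evaluating the motion trace at each frame midpoint, applies optional
#' per-frame multiplicative Gaussian noise, and adds the dark-current
#' offset.  The delivery starts at `start_offset` seconds into the
#' trace; by default the offset is drawn uniformly from the slack
#' between trace duration and delivery time (an arbitrary point in the
#' respiratory cycle), reproducibly from `spec$seed`.
#'
#' @inheritParams render_transit_image
#' @param trace A `motion_trace` at least as long as the delivery
#'   (`n_frames * frame_time`).
#' @param start_offset Start of the delivery within the trace (s), or
#'   `NULL` to draw it from the seed.
#' @return A raw (not dark-corrected) `portal_image`.
#' @export
acquire <- function(phantom, beam, trace, forward = forward_model(),
                    spec = acquisition_spec(), start_offset = NULL,
                    t_max = 21) {
  stopifnot(inherits(trace, "motion_trace"))
  delivery <- spec$n_frames * spec$frame_time
  if (trace_duration(trace) < delivery - 1e-9)
    stop("motion trace is shorter than the delivery time", call. = FALSE)

  with_seed(spec$seed, {
    if (is.null(start_offset)) {
      slack <- trace_duration(trace) - delivery
      start_offset <- runif(1, 0, max(slack, 0))
    }
    mids <- min(trace$times) + start_offset +
      (seq_len(spec$n_frames) - 0.5) * spec$frame_time
    disp <- trace_displacement(trace, mids)

    ny <- spec$pixels_y; nx <- spec$pixels_x
    acc <- matrix(0, ny, nx)
    cache_d <- NA_real_; cache_img <- NULL
    extrap <- FALSE
    for (k in seq_len(spec$n_frames)) {
      if (!identical(disp[k], cache_d)) {
        cache_img <- render_transit_image(phantom, beam, disp[k], forward,
                                          spec, t_max = t_max)
        extrap <- extrap || attr(cache_img, "extrapolated")
        attr(cache_img, "extrapolated") <- NULL
        cache_d <- disp[k]
      }
      frame <- cache_img
      if (spec$noise_scale > 0)
        frame <- frame * (1 + spec$noise_scale * matrix(rnorm(ny * nx), ny, nx))
      acc <- acc + frame
    }
    img <- acc / spec$n_frames + spec$dark_level
    portal_image(img, spec$pixel_pitch, is_dark_corrected = FALSE,
                 meta = list(field_size = c(beam$field_size_x, beam$field_size_y),
                             field_area = beam$area,
                             motion_kind = trace$kind,
                             start_offset = start_offset,
                             n_frames = spec$n_frames,
                             frame_time = spec$frame_time,
                             seed = spec$seed,
                             extrapolated = extrap))
  })
}

#' Generate a calibration slab series
#'
#' One frame-integrated flood image per slab thickness (the thickness-0
#' member is the open field) plus a dark image, all at the calibration
#' field size.  The default thickness list is the seven-point design
#' `{0, 2, 4, 7, 11, 16, 21}` cm.
#'
#' @param thicknesses Distinct slab thicknesses in cm; must include 0
#'   (the open field) and at least three distinct values.
#' @param beam Calibration `beam_model` (flat flood field).
#' @param forward A `forward_model` (set `k0 = 0` for a scatter-free,
#'   purely quadratic-exponent series).
#' @param spec An `acquisition_spec`; the seed is advanced per image so
#'   noise is independent across slabs yet reproducible.
#' @return A list with `images` (list of `portal_image`, one per
#'   thickness, each carrying `meta$thickness_cm`), `dark` (a
#'   `portal_image` at the dark level), and `thicknesses`.
#' @export
make_calibration_series <- function(thicknesses = c(0, 2, 4, 7, 11, 16, 21),
                                    beam = calibration_beam(),
                                    forward = forward_model(),
                                    spec = acquisition_spec()) {
  thicknesses <- sort(unique(thicknesses))
  if (any(thicknesses < 0)) stop("thicknesses must be >= 0", call. = FALSE)
  if (length(thicknesses) < 3 || !(0 %in% thicknesses))
    stop("need at least 3 distinct thicknesses including 0 (fit underdetermined)",
         call. = FALSE)
  delivery <- spec$n_frames * spec$frame_time
  trace <- make_static_trace(duration = delivery + 1)
  images <- lapply(seq_along(thicknesses), function(i) {
    sp <- spec
    sp$seed <- spec$seed + i   # independent noise per slab image
    img <- acquire(make_slab_phantom(thicknesses[i]), beam, trace,
                   forward, sp, start_offset = 0, t_max = Inf)
    img$meta$thickness_cm <- thicknesses[i]
    img
  })
  dark <- portal_image(matrix(spec$dark_level, spec$pixels_y, spec$pixels_x),
                       spec$pixel_pitch, is_dark_corrected = FALSE,
                       meta = list(kind = "dark"))
  list(images = images, dark = dark, thicknesses = thicknesses,
       field_area = beam$area)
}
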