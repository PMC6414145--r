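# Motion-effect quantification: thickness-to-intensity conversion,
# per-pixel dose-difference statistics over a region of interest, and
# local-dose 2D gamma analysis.  Throughout, the static (or day-one)
# image is the reference and the motion image is the evaluated
# distribution; dose normalisation is local.

#' Convert a thickness map back to a relative intensity (dose) map
#'
#' Applies the quadratic attenuation model with fixed conversion
#' coefficients (`alpha = 0.05`/cm, `beta = 1e-4`/cm^2 by default) so
#' thickness maps from different sessions map onto a common dose
#' surrogate: `dose = I0 * exp(-alpha*t - beta*t^2)`.
#'
#' @param t_map A `thickness_map` or a numeric matrix of thickness (cm).
#' @param alpha_conv,beta_conv Conversion coefficients.
#' @param I0 Open-field intensity scale (default 1, i.e. relative dose).
#' @return An object of class `dose_image`: `dose` (matrix), `valid`,
#'   `alpha_conv`, `beta_conv`, `pixel_pitch` (NA for bare matrices).
#' @export
#' @examples
#' thickness_to_intensity(matrix(10, 1, 1))$dose  # exp(-0.51)
thickness_to_intensity <- function(t_map, alpha_conv = 0.05,
                                   beta_conv = 1e-4, I0 = 1) {
  if (inherits(t_map, "thickness_map")) {
    t <- t_map$t; valid <- t_map$valid; pitch <- t_map$pixel_pitch
  } else {
    t <- as.matrix(t_map); valid <- is.finite(t); pitch <- NA_real_
  }
  if (any(t[valid] < 0)) stop("thickness must be >= 0", call. = FALSE)
  dose <- I0 * exp(-alpha_conv * t - beta_conv * t^2)
  dose[!valid] <- NA_real_
  structure(list(dose = dose, valid = valid, alpha_conv = alpha_conv,
                 beta_conv = beta_conv, I0 = I0, pixel_pitch = pitch),
            class = "dose_image")
}

#' @export
print.dose_image <- function(x, ...) {
  cat(sprintf("<dose_image> %d x %d px, dose in [%.4g, %.4g] (alpha=%g, beta=%g)\n",
              nrow(x$dose), ncol(x$dose),
              min(x$dose, na.rm = TRUE), max(x$dose, na.rm = TRUE),
              x$alpha_conv, x$beta_conv))
  invisible(x)
}

roi_mask_of <- function(roi, dims) {
  m <- if (inherits(roi, "roi_polygon")) roi$filled_mask
       else if (inherits(roi, "field_mask")) roi$mask
       else if (is.matrix(roi) && is.logical(roi)) roi
       else stop("`roi` must be an roi_polygon, field_mask or logical matrix",
                 call. = FALSE)
  if (!identical(dim(m), dims)) stop("ROI grid does not match the images",
                                     call. = FALSE)
  m
}

dose_matrix_of <- function(x) {
  if (inherits(x, "dose_image")) x$dose
  else if (is.matrix(x)) x
  else stop("expected a dose_image or matrix", call. = FALSE)
}

#' Per-pixel dose-difference summary over a region of interest
#'
#' Computes the local relative dose difference
#' `(evaluated - reference) / reference` per pixel and reports the
#' percentage of ROI pixels whose absolute difference is within each
#' threshold.
#'
#' @param evaluated,reference `dose_image`s (or matrices) on one grid;
#'   `reference` must be positive over the ROI.
#' @param roi An `roi_polygon`, `field_mask`, or logical matrix.
#' @param thresholds Percent thresholds (default `c(5, 3, 2, 1)`).
#' @return An object of class `dose_diff_summary`: `thresholds`,
#'   `pct_within` (named numeric, percent), `n_roi`, and `diff` (the
#'   relative-difference matrix, `NA` outside the ROI).
#' @export
dose_diff_summary <- function(evaluated, reference, roi,
                              thresholds = c(5, 3, 2, 1)) {
  ev <- dose_matrix_of(evaluated); rf <- dose_matrix_of(reference)
  if (!identical(dim(ev), dim(rf))) stop("grids differ", call. = FALSE)
  m <- roi_mask_of(roi, dim(ev))
  m <- m & is.finite(ev) & is.finite(rf)
  if (!any(m)) stop("empty region of interest", call. = FALSE)
  if (any(rf[m] <= 0)) stop("reference dose must be positive over the ROI",
                            call. = FALSE)
  rel <- matrix(NA_real_, nrow(ev), ncol(ev))
  rel[m] <- (ev[m] - rf[m]) / rf[m]
  pct <- vapply(thresholds, function(th)
    100 * mean(abs(rel[m]) <= th / 100), numeric(1))
  names(pct) <- paste0(thresholds, "%")
  structure(list(thresholds = thresholds, pct_within = pct,
                 n_roi = sum(m), diff = rel),
            class = "dose_diff_summary")
}

#' @export
print.dose_diff_summary <- function(x, ...) {
  cat("<dose_diff_summary> ", x$n_roi, "ROI px;",
      paste(sprintf("<=%s: %.1f%%", names(x$pct_within), x$pct_within),
            collapse = "  "), "\n")
  invisible(x)
}

#' Local-dose 2D gamma analysis
#'
#' For each ROI pixel `r`, the gamma index is the minimum over search
#' positions `p` of
#' `sqrt(|p - r|^2 / dist_crit^2 + (De(r) - Dr(p))^2 / (dose_crit * Dr(p) / 100)^2)`,
#' with the dose criterion normalised locally to the reference dose at
#' the compared position.  The search covers a disc of radius
#' `search_factor * dist_crit` on a sub-pixel grid obtained by bilinear
#' interpolation of the reference at step `pixel_pitch / interp_factor`.
#' A pixel passes when gamma < 1.
#'
#' @param evaluated,reference `dose_image`s (or matrices) on one grid.
#' @param roi ROI (`roi_polygon`, `field_mask` or logical matrix); `NULL`
#'   evaluates everywhere the dose is finite.
#' @param dose_crit_pct Dose criterion in percent (local).
#' @param dist_crit_mm Distance-to-agreement criterion in mm.
#' @param pixel_pitch_cm Pixel pitch in cm; taken from `evaluated` when
#'   it is a `dose_image` carrying one.
#' @param search_factor Search radius in units of `dist_crit_mm`.
#' @param interp_factor Sub-pixel refinement of the search grid; 1
#'   searches the native grid only and requires
#'   `dist_crit_mm >= 10 * pixel_pitch_cm` (otherwise the search would
#'   undersample the criterion).
#' @return An object of class `gamma_map`: `gamma` (matrix, `NA`
#'   outside the ROI), `pass_rate` (percent of ROI pixels with gamma
#'   < 1), `dose_crit_pct`, `dist_crit_mm`, `n_roi`.
#' @export
gamma_2d <- function(evaluated, reference, roi = NULL, dose_crit_pct,
                     dist_crit_mm, pixel_pitch_cm = NULL,
                     search_factor = 3, interp_factor = 10) {
  ev <- dose_matrix_of(evaluated); rf <- dose_matrix_of(reference)
  if (!identical(dim(ev), dim(rf))) stop("grids differ", call. = FALSE)
  if (is.null(pixel_pitch_cm) && inherits(evaluated, "dose_image"))
    pixel_pitch_cm <- evaluated$pixel_pitch
  if (is.null(pixel_pitch_cm) || !is.finite(pixel_pitch_cm))
    stop("`pixel_pitch_cm` is required", call. = FALSE)
  stopifnot_scalar(dose_crit_pct, "dose_crit_pct")
  stopifnot_scalar(dist_crit_mm, "dist_crit_mm")
  if (dose_crit_pct <= 0 || dist_crit_mm <= 0)
    stop("criteria must be positive", call. = FALSE)
  pitch_mm <- pixel_pitch_cm * 10
  if (interp_factor < 1) stop("`interp_factor` must be >= 1", call. = FALSE)
  if (interp_factor == 1 && dist_crit_mm < pitch_mm)
    stop("distance criterion below the pixel pitch: enable interpolation (interp_factor > 1)",
         call. = FALSE)
  m <- if (is.null(roi)) is.finite(ev) & is.finite(rf)
       else roi_mask_of(roi, dim(ev)) & is.finite(ev) & is.finite(rf)
  if (!any(m)) stop("empty region of interest", call. = FALSE)

  step_mm <- pitch_mm / interp_factor
  g <- gamma2d_cpp(ev, rf, m, pitch_mm, dose_crit_pct / 100,
                   dist_crit_mm, search_factor * dist_crit_mm, step_mm)
  inroi <- m & !is.na(g)
  pass <- 100 * mean(g[inroi] < 1)
  structure(list(gamma = g, pass_rate = pass,
                 dose_crit_pct = dose_crit_pct, dist_crit_mm = dist_crit_mm,
                 n_roi = sum(inroi)),
            class = "gamma_map")
}

#' @export
print.gamma_map <- function(x, ...) {
  cat(sprintf("<gamma_map> %g%%/%g mm: pass rate %.1f%% over %d ROI px (max gamma %.2f)\n",
              x$dose_crit_pct, x$dist_crit_mm, x$pass_rate, x$n_roi,
              max(x$gamma, na.rm = TRUE)))
  invisible(x)
}

#' Extract a 1D profile from a map
#'
#' Either a single image row (nearest-neighbour, the usual horizontal
#' profile through the dome apex) or an arbitrary line between two
#' points in cm, sampled with bilinear interpolation.
#'
#' @param map A `thickness_map`, `dose_image`, `portal_image` or matrix.
#' @param row Row index for a horizontal profile.
#' @param from,to Endpoints `c(x, y)` in cm for an oblique profile.
#' @param n Number of samples for an oblique profile.
#' @param pixel_pitch_cm Pixel pitch in cm (taken from the object when
#'   available).
#' @return A data frame with `pos_cm` (distance along the profile, for
#'   row profiles the x coordinate) and `value`.
#' @export
profile_1d <- function(map, row = NULL, from = NULL, to = NULL, n = 256,
                       pixel_pitch_cm = NULL) {
  m <- if (inherits(map, "thickness_map")) map$t
       else if (inherits(map, "dose_image")) map$dose
       else if (inherits(map, "portal_image")) map$pixels
       else as.matrix(map)
  if (is.null(pixel_pitch_cm))
    pixel_pitch_cm <- if (inherits(map, "thickness_map")) map$pixel_pitch
      else if (inherits(map, "portal_image")) map$pixel_pitch
      else if (inherits(map, "dose_image")) map$pixel_pitch
      else NA_real_
  nr <- nrow(m); nc <- ncol(m)
  if (!is.null(row)) {
    if (row < 1 || row > nr) stop("row outside the grid", call. = FALSE)
    x <- if (is.finite(pixel_pitch_cm))
      grid_coords(nc, nr, pixel_pitch_cm)$x else seq_len(nc)
    return(data.frame(pos_cm = x, value = m[row, ]))
  }
  if (is.null(from) || is.null(to))
    stop("give either `row` or both `from` and `to`", call. = FALSE)
  if (!is.finite(pixel_pitch_cm))
    stop("`pixel_pitch_cm` is required for oblique profiles", call. = FALSE)
  xs <- seq(from[1], to[1], length.out = n)
  ys <- seq(from[2], to[2], length.out = n)
  rr <- coord_to_row(ys, nr, pixel_pitch_cm)
  cc <- coord_to_col(xs, nc, pixel_pitch_cm)
  if (any(rr < 1 | rr > nr | cc < 1 | cc > nc))
    stop("profile line leaves the grid", call. = FALSE)
  v <- bilinear_sample(m, rr, cc)
  d <- sqrt((xs - from[1])^2 + (ys - from[2])^2)
  data.frame(pos_cm = d, value = v)
}
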