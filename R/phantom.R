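# Virtual phantom: an analytic water-equivalent thickness function in
# beam's-eye-view coordinates, standing in for a physical thorax phantom
# with a breast attachment.  An analytic phantom gives exact oracles for
# the forward model and the reconstruction.

# Smooth compact-support bump: cos^2(pi*u/2) on |u| <= 1, 0 outside.
# Bounded gradient, so sampled thickness maps are free of pixel-scale jumps.
cos2_bump <- function(u) {
  v <- numeric(length(u))
  i <- abs(u) < 1
  v[i] <- cos(pi * u[i] / 2)^2
  v
}

#' Construct a breast-shaped virtual phantom
#'
#' Builds an analytic water-equivalent thickness function: a smooth
#' dome (the "breast") superposed on a broad chest-wall mound, both
#' tapering continuously to zero.  The total thickness peaks at exactly
#' `separation_max` at the dome apex, emulating the typical separation
#' of a patient's breast; thickness is zero outside the body extent.
#'
#' @param separation_max Maximum thickness (cm) at the dome apex.  Must
#'   lie in (0, 21], the range spanned by the slab calibration.
#' @param centre Dome apex position `c(x, y)` in cm.
#' @param dome_semiaxes Dome semi-axes `c(a, b)` in cm (support ellipse of
#'   the breast).
#' @param chest_frac Fraction of `separation_max` contributed by the
#'   chest-wall mound at the apex.
#' @param chest_halfwidth Half-widths `c(wx, wy)` in cm of the chest-wall
#'   mound support.
#' @param n_outline Number of vertices of the returned breast outline
#'   polygon.
#' @return An object of class `phantom_model`: a list with
#'   `thickness_fn(x, y)` (vectorised, cm), `breast_outline` (closed
#'   two-column matrix of (x, y) cm), `body_extent`
#'   (`c(xmin, xmax, ymin, ymax)`), and `separation_max`.
#' @export
#' @examples
#' ph <- make_breast_phantom(16)
#' ph$thickness_fn(0, 0)   # apex thickness = 16 cm
make_breast_phantom <- function(separation_max = 16,
                                centre = c(0, 0),
                                dome_semiaxes = c(6, 5),
                                chest_frac = 0.3,
                                chest_halfwidth = c(11, 12),
                                n_outline = 72) {
  stopifnot_scalar(separation_max, "separation_max")
  if (separation_max <= 0 || separation_max > 21)
    stop("`separation_max` must lie in (0, 21] cm, the calibrated thickness range",
         call. = FALSE)
  stopifnot(length(centre) == 2, length(dome_semiaxes) == 2,
            all(dome_semiaxes > 0), chest_frac >= 0, chest_frac < 1,
            all(chest_halfwidth > 0))

  h_chest <- chest_frac * separation_max
  h_dome  <- separation_max - h_chest
  cx <- centre[1]; cy <- centre[2]
  a <- dome_semiaxes[1]; b <- dome_semiaxes[2]
  wx <- chest_halfwidth[1]; wy <- chest_halfwidth[2]

  thickness_fn <- function(x, y) {
    # chest-wall mound (broad, shallow) + breast dome, both centred on the
    # apex so the global maximum is exactly separation_max at `centre`
    chest <- h_chest * cos2_bump((x - cx) / wx) * cos2_bump((y - cy) / wy)
    r <- sqrt(((x - cx) / a)^2 + ((y - cy) / b)^2)
    chest + h_dome * cos2_bump(r)
  }

  th <- seq(0, 2 * pi, length.out = n_outline + 1)
  outline <- cbind(x = cx + a * cos(th), y = cy + b * sin(th))

  structure(list(
    thickness_fn = thickness_fn,
    breast_outline = outline,
    body_extent = c(xmin = cx - wx, xmax = cx + wx,
                    ymin = cy - wy, ymax = cy + wy),
    separation_max = separation_max
  ), class = "phantom_model")
}

#' Construct a uniform-slab phantom
#'
#' A slab of constant water-equivalent thickness covering the whole
#' field of view, as used for the flood calibration series.
#'
#' @param thickness Slab thickness in cm (>= 0).
#' @return A `phantom_model` whose thickness function is constant.
#' @export
make_slab_phantom <- function(thickness) {
  stopifnot_scalar(thickness, "thickness")
  if (thickness < 0) stop("`thickness` must be >= 0", call. = FALSE)
  structure(list(
    thickness_fn = function(x, y) rep(thickness, length(x)),
    breast_outline = NULL,
    body_extent = c(xmin = -Inf, xmax = Inf, ymin = -Inf, ymax = Inf),
    separation_max = thickness
  ), class = "phantom_model")
}

#' Sample a phantom thickness function on an image grid
#'
#' @param phantom A `phantom_model`.
#' @param nx,ny Grid size (columns, rows).
#' @param pitch Pixel pitch in cm.
#' @param displacement Shift of the phantom along +x in cm (the phantom is
#'   sampled at `x - displacement`).
#' @return A `ny` x `nx` matrix of thickness in cm (rows = y, columns = x).
#' @export
sample_thickness <- function(phantom, nx, ny, pitch, displacement = 0) {
  stopifnot(inherits(phantom, "phantom_model"))
  g <- grid_coords(nx, ny, pitch)
  X <- matrix(g$x - displacement, nrow = ny, ncol = nx, byrow = TRUE)
  Y <- matrix(g$y, nrow = ny, ncol = nx)
  matrix(phantom$thickness_fn(as.vector(X), as.vector(Y)), nrow = ny, ncol = nx)
}

#' @export
print.phantom_model <- function(x, ...) {
  cat("<phantom_model>  max thickness:", x$separation_max, "cm\n")
  if (!is.null(x$breast_outline))
    cat("  breast outline:", nrow(x$breast_outline), "vertices\n")
  cat("  body extent (cm):",
      paste(sprintf("%s=%.1f", names(x$body_extent), x$body_extent),
            collapse = ", "), "\n")
  invisible(x)
}
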