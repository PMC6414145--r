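# Beam model: rectangular aperture at the isocentre plane with a
# per-position fluence modifier.  A physical wedge is represented as a
# static multiplicative fluence ramp across the field; the calibration
# flood field is a flat-fluence beam large enough to cover the detector.

#' Construct a beam model
#'
#' @param field_size_x,field_size_y Field size (cm) at the isocentre
#'   plane along x (longitudinal) and y.
#' @param wedge If `TRUE`, apply a wedge-like fluence ramp along x inside
#'   the aperture, from `wedge_range[1]` at the -x edge to
#'   `wedge_range[2]` at the +x edge.  If `FALSE` the in-field fluence
#'   is 1.
#' @param wedge_range Length-2 positive numeric, fluence at the two x
#'   edges of the field.
#' @return An object of class `beam_model` with `field_size_x`,
#'   `field_size_y`, `area` (cm^2, the product of the field sizes), and
#'   `fluence_fn(x, y)` returning the per-position fluence (0 outside the
#'   aperture, strictly positive inside).
#' @export
#' @examples
#' b <- beam_model(14, 8, wedge = TRUE)
#' b$area
beam_model <- function(field_size_x, field_size_y, wedge = FALSE,
                       wedge_range = c(0.5, 1.0)) {
  stopifnot_scalar(field_size_x, "field_size_x")
  stopifnot_scalar(field_size_y, "field_size_y")
  if (field_size_x <= 0 || field_size_y <= 0)
    stop("field sizes must be positive", call. = FALSE)
  stopifnot(length(wedge_range) == 2, all(wedge_range > 0))
  hx <- field_size_x / 2; hy <- field_size_y / 2
  w0 <- wedge_range[1]; w1 <- wedge_range[2]
  fluence_fn <- function(x, y) {
    inside <- abs(x) <= hx & abs(y) <= hy
    f <- numeric(length(x))
    if (wedge) {
      u <- (x / field_size_x) + 0.5   # 0 at -x edge, 1 at +x edge
      f[inside] <- (w0 + (w1 - w0) * u)[inside]
    } else {
      f[inside] <- 1
    }
    f
  }
  structure(list(
    field_size_x = field_size_x,
    field_size_y = field_size_y,
    area = field_size_x * field_size_y,
    wedge = wedge,
    fluence_fn = fluence_fn
  ), class = "beam_model")
}

#' Default calibration flood beam
#'
#' The flat calibration field (26 x 26 cm^2 at the isocentre plane),
#' sized to flood every detector pixel.
#'
#' @return A flat-fluence `beam_model`.
#' @export
calibration_beam <- function() beam_model(26, 26, wedge = FALSE)

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf("<beam_model> %g x %g cm^2 (A = %g cm^2)%s\n",
              x$field_size_x, x$field_size_y, x$area,
              if (x$wedge) ", wedged" else ""))
  invisible(x)
}
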