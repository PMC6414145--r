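# Per-pixel quadratic attenuation calibration.  From a dark-corrected
# slab series the exponent of
#     I(t) = I0 * exp(-alpha*t - beta*t^2)
# is fitted per pixel by linear least squares in the log domain:
#     -ln(I_t / I0) = alpha*t + beta*t^2,
# with I0 taken from the measured open field (no intercept is fitted).

#' Dark-current correction
#'
#' Subtracts the dark/offset image pixelwise, clamping at zero.
#'
#' @param raw A raw `portal_image`.
#' @param dark The dark `portal_image` (same grid).
#' @return A dark-corrected `portal_image`.
#' @export
#' @examples
#' r <- portal_image(matrix(c(100, 50), 1), 0.1)
#' d <- portal_image(matrix(c(10, 60), 1), 0.1)
#' dark_correct(r, d)$pixels
dark_correct <- function(raw, dark) {
  stopifnot(inherits(raw, "portal_image"), inherits(dark, "portal_image"))
  if (raw$is_dark_corrected)
    stop("image is already dark-corrected", call. = FALSE)
  if (!identical(dim(raw$pixels), dim(dark$pixels)))
    stop("raw and dark images have different grid shapes", call. = FALSE)
  out <- raw
  out$pixels <- pmax(raw$pixels - dark$pixels, 0)
  out$is_dark_corrected <- TRUE
  out
}

#' Fit the per-pixel quadratic attenuation model
#'
#' Least-squares fit, per pixel, of `(alpha, beta)` in
#' `-ln(I_t / I0) = alpha*t + beta*t^2` over the slab thicknesses of a
#' calibration series.  The open field (thickness 0) provides `I0`
#' directly and does not enter the regression.  Pixels with any
#' non-positive signal, or with a non-positive fitted `alpha`, are
#' flagged invalid rather than silently used.
#'
#' @param series A calibration series as returned by
#'   [make_calibration_series()], or a list with elements `images`
#'   (list of `portal_image` each carrying `meta$thickness_cm`), `dark`
#'   (a dark `portal_image`, optional if images are already corrected)
#'   and `field_area` (cm^2).
#' @return An object of class `calibration_model` with matrices
#'   `alpha_map` (1/cm), `beta_map` (1/cm^2), `i0_map` (counts),
#'   `valid` (logical), `fit_residual_map` (RMS log-domain residual),
#'   plus `calib_field_area` and `thicknesses`.
#' @export
fit_quadratic <- function(series) {
  stopifnot(is.list(series), !is.null(series$images))
  imgs <- series$images
  th <- vapply(imgs, function(im) im$meta$thickness_cm, numeric(1))
  if (anyNA(th)) stop("every series image needs meta$thickness_cm", call. = FALSE)
  o <- order(th); imgs <- imgs[o]; th <- th[o]
  if (anyDuplicated(th)) stop("slab thicknesses must be distinct", call. = FALSE)
  if (!(0 %in% th)) stop("series must include the open field (t = 0)", call. = FALSE)
  t_pos <- th[th > 0]
  if (length(t_pos) < 2)
    stop("underdetermined fit: need at least two non-zero thicknesses",
         call. = FALSE)

  imgs <- lapply(imgs, function(im) {
    if (im$is_dark_corrected) im else dark_correct(im, series$dark)
  })
  i0 <- imgs[[which(th == 0)]]$pixels
  slabs <- imgs[th > 0]
  ny <- nrow(i0); nx <- ncol(i0)

  valid <- i0 > 0
  for (im in slabs) valid <- valid & (im$pixels > 0)

  # normal equations for y = alpha*t + beta*t^2, shared design across pixels
  S11 <- sum(t_pos^2); S12 <- sum(t_pos^3); S22 <- sum(t_pos^4)
  det <- S11 * S22 - S12^2
  if (abs(det) < .Machine$double.eps * S22^2)
    stop("rank-deficient design in (t, t^2)", call. = FALSE)
  b1 <- matrix(0, ny, nx); b2 <- matrix(0, ny, nx)
  ys <- vector("list", length(t_pos))
  for (j in seq_along(t_pos)) {
    y <- matrix(NA_real_, ny, nx)
    y[valid] <- -log(slabs[[j]]$pixels[valid] / i0[valid])
    ys[[j]] <- y
    b1 <- b1 + t_pos[j] * y
    b2 <- b2 + t_pos[j]^2 * y
  }
  alpha <- (S22 * b1 - S12 * b2) / det
  beta  <- (S11 * b2 - S12 * b1) / det

  res2 <- matrix(0, ny, nx)
  for (j in seq_along(t_pos)) {
    r <- ys[[j]] - alpha * t_pos[j] - beta * t_pos[j]^2
    res2 <- res2 + r^2
  }
  residual <- sqrt(res2 / length(t_pos))

  valid <- valid & is.finite(alpha) & (alpha > 0)
  alpha[!valid] <- NA_real_; beta[!valid] <- NA_real_
  residual[!valid] <- NA_real_

  structure(list(alpha_map = alpha, beta_map = beta, i0_map = i0,
                 valid = valid, fit_residual_map = residual,
                 calib_field_area = series$field_area %||% NA_real_,
                 thicknesses = th),
            class = "calibration_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %d x %d px, slabs {%s} cm, A_calib = %g cm^2\n",
              nrow(x$alpha_map), ncol(x$alpha_map),
              paste(x$thicknesses, collapse = ", "), x$calib_field_area))
  cat(sprintf("  alpha: median %.4g /cm   beta: median %.3g /cm^2   valid: %.1f%%\n",
              median(x$alpha_map, na.rm = TRUE),
              median(x$beta_map, na.rm = TRUE), 100 * mean(x$valid)))
  invisible(x)
}

#' Serialize / load a calibration model
#'
#' The model is written as a directory of 16-bit TIFF maps
#' (`alpha.tiff`, `beta.tiff`, `i0.tiff`, `valid.tiff`) with scale
#' factors and metadata in `meta.json`.
#'
#' @param model A `calibration_model`.
#' @param dir Directory path (created if needed).
#' @return `write_calibration` returns `dir` invisibly;
#'   `read_calibration` returns a `calibration_model`.
#' @export
write_calibration <- function(model, dir) {
  stopifnot(inherits(model, "calibration_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- list(
    alpha = write_map_tiff(model$alpha_map, file.path(dir, "alpha.tiff")),
    beta  = write_map_tiff(model$beta_map, file.path(dir, "beta.tiff")),
    i0    = write_map_tiff(model$i0_map, file.path(dir, "i0.tiff")),
    valid = write_map_tiff(model$valid * 1.0, file.path(dir, "valid.tiff")),
    residual = write_map_tiff(model$fit_residual_map,
                              file.path(dir, "residual.tiff"))
  )
  meta <- list(scales = sc, calib_field_area = model$calib_field_area,
               thicknesses = model$thicknesses)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  rd <- function(name)
    read_map_tiff(file.path(dir, paste0(name, ".tiff")), meta$scales[[name]])
  valid <- rd("valid") > 0.5
  alpha <- rd("alpha"); beta <- rd("beta"); residual <- rd("residual")
  alpha[!valid] <- NA_real_; beta[!valid] <- NA_real_
  residual[!valid] <- NA_real_
  structure(list(alpha_map = alpha, beta_map = beta, i0_map = rd("i0"),
                 valid = valid, fit_residual_map = residual,
                 calib_field_area = meta$calib_field_area,
                 thicknesses = meta$thicknesses),
            class = "calibration_model")
}
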