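# Thickness reconstruction: invert the per-pixel quadratic attenuation
# model inside an iterative correction loop that accounts for the
# difference in field size (open-field output factor F) and in
# scatter-to-primary ratio between the calibration and treatment
# geometries.

#' First-order scatter-to-primary ratio model
#'
#' `SPR = k0 * A * t`: proportional to the field area at the isocentre
#' plane and to the object thickness.
#'
#' @param k0 Scatter coefficient (1/cm^3); the packaged default is
#'   1.93e-5, accounting for system geometry and the electron density of
#'   the water-equivalent calibration plastic.
#' @param area_calib Calibration field area (cm^2).
#' @param area_treat Treatment field area (cm^2).
#' @return An object of class `scatter_model`.
#' @export
scatter_model <- function(k0 = 1.93e-5, area_calib = 676, area_treat = 112) {
  if (k0 < 0) stop("`k0` must be >= 0", call. = FALSE)
  if (area_calib <= 0 || area_treat <= 0)
    stop("field areas must be > 0", call. = FALSE)
  structure(list(k0 = k0, area_calib = area_calib, area_treat = area_treat),
            class = "scatter_model")
}

#' Scatter-to-primary ratio
#'
#' @param t Thickness in cm (scalar, vector or matrix; all >= 0).
#' @param area Field area in cm^2.
#' @param model A `scatter_model` supplying `k0`.
#' @return `k0 * area * t`, same shape as `t`.
#' @export
#' @examples
#' spr(21, 676, scatter_model())   # calibration geometry, thickest slab
spr <- function(t, area, model = scatter_model()) {
  stopifnot(inherits(model, "scatter_model"))
  if (any(t < 0, na.rm = TRUE)) stop("`t` must be >= 0", call. = FALSE)
  model$k0 * area * t
}

#' Invert the quadratic attenuation model for thickness
#'
#' Solves `-ln(I/I0) = alpha*t + beta*t^2` for `t`, taking the root
#' branch `t = (-alpha + sqrt(alpha^2 - 4*beta*ln(I/I0))) / (2*beta)`
#' that is non-negative for attenuated signals.  For `|beta|` below
#' 1e-9 the linear limit `-ln(I/I0)/alpha` is used for numerical
#' stability.  Signals at or above `I0` clamp to `t = 0`; non-positive
#' signals and negative discriminants yield `NA` (invalid pixel).
#'
#' @param I Measured (dark-corrected) signal; scalar, vector or matrix.
#' @param I0 Open-field signal, same shape or scalar.
#' @param alpha,beta Calibration coefficients, same shape or scalar.
#' @param beta_tol Threshold on `|beta|` below which the linear
#'   fallback is used.
#' @return Thickness in cm, same shape as the inputs; `NA` where invalid.
#' @export
#' @examples
#' invert_quadratic(exp(-0.51), 1, 0.05, 1e-4)   # 10 cm
invert_quadratic <- function(I, I0, alpha, beta, beta_tol = 1e-9) {
  shp <- dim(I)
  n <- max(length(I), length(I0), length(alpha), length(beta))
  I <- rep_len(as.vector(I), n); I0 <- rep_len(as.vector(I0), n)
  alpha <- rep_len(as.vector(alpha), n); beta <- rep_len(as.vector(beta), n)

  t <- rep(NA_real_, n)
  ok <- is.finite(I) & is.finite(I0) & is.finite(alpha) &
    I > 0 & I0 > 0 & alpha > 0
  lnr <- rep(NA_real_, n)
  lnr[ok] <- log(I[ok] / I0[ok])
  lnr[ok & lnr > 0] <- 0          # clamp I >= I0 to zero thickness

  lin <- ok & (is.na(beta) | abs(beta) < beta_tol)
  t[lin] <- -lnr[lin] / alpha[lin]

  qd <- ok & !lin
  if (any(qd)) {
    disc <- alpha[qd]^2 - 4 * beta[qd] * lnr[qd]
    tq <- rep(NA_real_, sum(qd))
    pos <- disc >= 0
    tq[pos] <- (-alpha[qd][pos] + sqrt(disc[pos])) / (2 * beta[qd][pos])
    t[qd] <- tq
  }
  t[!is.na(t) & t < 0] <- 0
  if (!is.null(shp)) dim(t) <- shp
  t
}

#' Reconstruct an equivalent-thickness map from a treatment image
#'
#' Converts a dark-corrected treatment-field portal image into a map of
#' equivalent water-equivalent-plastic thickness.  Each iteration (i)
#' inverts the quadratic calibration for a thickness estimate `t_i` and
#' (ii) re-corrects the image intensity for the field-size and scatter
#' difference between calibration and treatment,
#' `I_{i+1} = (I_image / F) * (1 + SPR_ref(t_i)) / (1 + SPR_treat(t_i))`,
#' with `SPR_ref = k0 * A_calib * t_i` and `SPR_treat = k0 * A_treat * t_i`
#' evaluated at the current estimate.  The correction factor is always
#' applied to the original dark-corrected image (compounding it onto the
#' previous iterate would grow the signal without bound), so the loop is
#' a contraction and typically settles within five iterations.  The
#' open-field output factor `F = open_treat / I0` (a per-pixel image
#' ratio, which also carries any static fluence modulation such as a
#' wedge) normalises the treatment image onto the calibration intensity
#' scale and is applied once.  The loop stops when the largest per-pixel
#' thickness change is below `tol` or after `max_iter` iterations.
#'
#' @param image Dark-corrected treatment `portal_image`.
#' @param calib A `calibration_model` on the same grid.
#' @param open_treat Dark-corrected open-field `portal_image` at the
#'   treatment field size (defines `F`); `NULL` means `F` is identically 1.
#' @param scatter A `scatter_model`.
#' @param max_iter Maximum number of iterations.
#' @param tol Convergence tolerance on max |delta t| (cm).
#' @param fixed_iters If non-`NULL`, run exactly this many iterations
#'   (no early stop), mirroring a fixed five-iteration schedule.
#' @param f_apply `"once"` (default) applies the output-factor
#'   normalisation; `"none"` skips it (for images already on the
#'   calibration intensity scale).
#' @return An object of class `thickness_map`: matrices `t` (cm) and
#'   `valid`, plus `iterations_run`, `max_delta_last` (cm), `converged`,
#'   `pixel_pitch`, and `provenance`.
#' @export
reconstruct <- function(image, calib, open_treat = NULL,
                        scatter = scatter_model(), max_iter = 10,
                        tol = 0.01, fixed_iters = NULL,
                        f_apply = c("once", "none")) {
  stopifnot(inherits(image, "portal_image"),
            inherits(calib, "calibration_model"),
            inherits(scatter, "scatter_model"))
  f_apply <- match.arg(f_apply)
  if (!image$is_dark_corrected)
    stop("treatment image must be dark-corrected first", call. = FALSE)
  if (!identical(dim(image$pixels), dim(calib$alpha_map)))
    stop("image and calibration grids differ", call. = FALSE)

  F_map <- NULL
  if (!is.null(open_treat)) {
    stopifnot(inherits(open_treat, "portal_image"))
    if (!open_treat$is_dark_corrected)
      stop("open-field treatment image must be dark-corrected", call. = FALSE)
    F_map <- open_treat$pixels / calib$i0_map
    F_map[!is.finite(F_map) | F_map <= 0] <- NA_real_
  }

  I_base <- image$pixels
  if (!is.null(F_map) && f_apply == "once") I_base <- I_base / F_map
  valid <- calib$valid & image$pixels > 0
  if (!is.null(F_map)) valid <- valid & is.finite(F_map)

  n_corr <- if (is.null(fixed_iters)) max_iter else fixed_iters
  # first thickness estimate from the uncorrected (F-normalised) image
  t_cur <- invert_quadratic(I_base, calib$i0_map, calib$alpha_map,
                            calib$beta_map)
  iterations <- 0L
  max_delta <- NA_real_
  converged <- FALSE
  cmp <- valid & !is.na(t_cur)

  for (i in seq_len(n_corr)) {
    t_est <- t_cur
    t_est[is.na(t_est)] <- 0
    # correction factor at the current estimate, applied to the original
    I_cur <- I_base * (1 + spr(t_est, scatter$area_calib, scatter)) /
                      (1 + spr(t_est, scatter$area_treat, scatter))
    t_new <- invert_quadratic(I_cur, calib$i0_map, calib$alpha_map,
                              calib$beta_map)
    iterations <- i
    max_delta <- max(abs(t_new - t_cur)[cmp & !is.na(t_new)], na.rm = TRUE)
    t_cur <- t_new
    if (is.null(fixed_iters) && max_delta < tol) { converged <- TRUE; break }
  }
  if (!is.null(fixed_iters)) converged <- TRUE
  if (!converged)
    warning(sprintf(
      "thickness reconstruction did not reach tol = %g cm in %d iterations (last max |dt| = %.4g cm)",
      tol, max_iter, max_delta), call. = FALSE)

  t_out <- t_cur
  valid <- valid & !is.na(t_out)
  t_out[!valid] <- 0
  structure(list(t = t_out, valid = valid, iterations_run = iterations,
                 max_delta_last = max_delta, converged = converged,
                 pixel_pitch = image$pixel_pitch,
                 provenance = list(
                   scatter = unclass(scatter),
                   f_apply = f_apply, tol = tol,
                   calib_thicknesses = calib$thicknesses)),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %d x %d px, t in [%.2f, %.2f] cm, %d iterations%s\n",
              nrow(x$t), ncol(x$t), min(x$t[x$valid]), max(x$t[x$valid]),
              x$iterations_run,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}
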