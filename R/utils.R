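# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the
#' previous RNG state afterwards, so generators are pure functions of
#' their arguments (including the seed) and never disturb a caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Pixel-centre coordinates of an image grid
#'
#' Pixel centres in cm at the isocentre plane.  Columns map to x
#' (the longitudinal/motion axis), rows map to y; the grid is centred
#' on the beam axis (0, 0).
#'
#' @param nx,ny Number of columns (x) and rows (y).
#' @param pitch Pixel pitch in cm.
#' @return List with numeric vectors `x` (length `nx`) and `y` (length `ny`).
#' @export
#' @examples
#' grid_coords(4, 4, 0.1)$x
grid_coords <- function(nx, ny, pitch) {
  list(
    x = (seq_len(nx) - (nx + 1) / 2) * pitch,
    y = (seq_len(ny) - (ny + 1) / 2) * pitch
  )
}

# x/y cm -> fractional column/row index (inverse of grid_coords)
coord_to_col <- function(x, nx, pitch) x / pitch + (nx + 1) / 2
coord_to_row <- function(y, ny, pitch) y / pitch + (ny + 1) / 2

# Bilinear sample of matrix `m` at fractional (row, col) positions.
# Out-of-bounds positions return `fill`.
bilinear_sample <- function(m, row, col, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(fill, length(row))
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc &
    is.finite(row) & is.finite(col)
  if (!any(ok)) return(out)
  r <- row[ok]; c <- col[ok]
  r0 <- pmin(pmax(floor(r), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(c), 1L), nc - 1L)
  fr <- r - r0; fc <- c - c0
  v00 <- m[cbind(r0, c0)];     v10 <- m[cbind(r0 + 1L, c0)]
  v01 <- m[cbind(r0, c0 + 1L)]; v11 <- m[cbind(r0 + 1L, c0 + 1L)]
  out[ok] <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
  out
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}
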