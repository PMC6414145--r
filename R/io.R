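# Image I/O: 16-bit grayscale TIFF with a JSON sidecar recording the
# affine counts scale, plus plain CSV grids as a text alternative.

#' Write a numeric map as 16-bit grayscale TIFF
#'
#' Values are affinely mapped to the 16-bit range; the offset and scale
#' needed to recover physical units are returned (and normally stored in
#' a JSON sidecar).  `NA` pixels are stored as 0 and must be recovered
#' through a validity mask.
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @return Invisibly, a list with `offset`, `scale` (value =
#'   offset + scale * stored16), written alongside by callers.
#' @export
write_map_tiff <- function(m, path) {
  stopifnot(is.matrix(m))
  v <- m
  fin <- is.finite(v)
  lo <- if (any(fin)) min(v[fin]) else 0
  hi <- if (any(fin)) max(v[fin]) else 1
  if (hi <= lo) hi <- lo + 1
  scaled <- (v - lo) / (hi - lo)
  scaled[!fin] <- 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(list(offset = lo, scale = hi - lo))
}

#' Read a 16-bit grayscale TIFF written by [write_map_tiff()]
#'
#' @param path TIFF path.
#' @param scale_info List with `offset` and `scale`.
#' @return Numeric matrix in physical units.
#' @export
read_map_tiff <- function(path, scale_info) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  scale_info$offset + scale_info$scale * m
}

#' Write / read a portal image as TIFF plus JSON sidecar
#'
#' The sidecar (`<path>.json`) carries the counts scale and the image
#' metadata so the stored 16-bit grid round-trips to counts.
#'
#' @param image A `portal_image`.
#' @param path TIFF output path.
#' @return `write_portal_tiff` returns `path` invisibly;
#'   `read_portal_tiff` returns a `portal_image`.
#' @export
write_portal_tiff <- function(image, path) {
  stopifnot(inherits(image, "portal_image"))
  sc <- write_map_tiff(image$pixels, path)
  side <- list(offset = sc$offset, scale = sc$scale,
               pixel_pitch = image$pixel_pitch,
               is_dark_corrected = image$is_dark_corrected,
               meta = image$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_portal_tiff
#' @export
read_portal_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- read_map_tiff(path, side)
  portal_image(m, side$pixel_pitch, side$is_dark_corrected,
               meta = as.list(side$meta))
}

#' Write / read a numeric grid as plain CSV (no header)
#'
#' @param m Numeric matrix.
#' @param path CSV path.
#' @return `write_grid_csv` returns `path` invisibly; `read_grid_csv`
#'   returns a numeric matrix.
#' @export
write_grid_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ","))
}
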