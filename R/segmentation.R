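# Radiation-field segmentation: threshold mask, Freeman chain-code
# boundary tracing (Moore neighbourhood), and even-odd polygon fill for
# the operator-style region of interest.

# Freeman 8-direction codes: 0=E, 1=NE, 2=N, 3=NW, 4=W, 5=SW, 6=S, 7=SE
# in image coordinates (x = column increasing right, y = row increasing
# down; "N" is decreasing row).
freeman_dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
freeman_dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)

#' Threshold-based radiation-field mask with chain-code boundary
#'
#' Thresholds the image at `threshold_frac` of a robust maximum (the
#' 99th percentile), keeps the largest connected component
#' (8-connectivity), and traces its outer boundary with a Moore
#' chain-code walk.  Pixels exactly at the threshold are included.
#'
#' @param image A `portal_image`, `thickness_map`, `dose_image`, or a
#'   bare numeric matrix.
#' @param threshold_frac Fraction of the robust maximum (default 0.5).
#' @return An object of class `field_mask`: `mask` (logical matrix),
#'   `boundary` (two-column matrix of boundary pixel (row, col)
#'   indices, in traversal order), `chain` (integer Freeman codes, one
#'   per step, closed), and `threshold_used` (absolute counts).
#' @export
field_mask <- function(image, threshold_frac = 0.5) {
  m <- if (is.matrix(image)) image
       else if (inherits(image, "portal_image")) image$pixels
       else if (inherits(image, "thickness_map")) image$t
       else if (inherits(image, "dose_image")) image$dose
       else stop("unsupported image type", call. = FALSE)
  if (!any(is.finite(m)) || max(m, na.rm = TRUE) <= 0)
    stop("NoFieldDetected: image has no positive signal", call. = FALSE)
  robust_max <- quantile(m[is.finite(m)], 0.99, names = FALSE)
  thr <- threshold_frac * robust_max
  mask <- !is.na(m) & m >= thr
  if (!any(mask))
    stop("NoFieldDetected: threshold mask is empty", call. = FALSE)
  lab <- EBImage::bwlabel(mask * 1)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  mask <- lab == keep

  tr <- trace_boundary(mask)
  structure(list(mask = mask, boundary = tr$pixels, chain = tr$chain,
                 threshold_used = thr),
            class = "field_mask")
}

#' Trace the outer boundary of a binary mask with a Freeman chain code
#'
#' Moore-neighbourhood tracing with Jacob's stopping criterion: the walk
#' ends when the start pixel is re-entered from the starting direction,
#' so the chain is closed (the final step returns to the start pixel).
#'
#' @param mask Logical matrix (a single connected region).
#' @param start Optional `c(row, col)` of a boundary pixel to start
#'   from; default is the topmost-then-leftmost mask pixel.
#' @return List with `pixels` (n x 2 matrix of (row, col), traversal
#'   order, no repeated closing pixel) and `chain` (n Freeman codes;
#'   following them from the first pixel returns to it).
#' @export
trace_boundary <- function(mask, start = NULL) {
  stopifnot(is.matrix(mask))
  mask <- !is.na(mask) & mask
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]

  if (is.null(start)) {
    idx <- which(mask)
    if (!length(idx)) stop("empty mask", call. = FALSE)
    rows <- (idx - 1L) %% nr + 1L; cols <- (idx - 1L) %/% nr + 1L
    o <- order(rows, cols)[1]
    start <- c(rows[o], cols[o])
    enter_dir <- 4L  # came from the west (scan order guarantees west is empty)
  } else {
    if (!inside(start[1], start[2]))
      stop("`start` is not a mask pixel", call. = FALSE)
    # find a background Moore neighbour to define the backtrack direction
    enter_dir <- NA_integer_
    for (d in 0:7) {
      r2 <- start[1] + freeman_dr[d + 1L]; c2 <- start[2] + freeman_dc[d + 1L]
      if (!inside(r2, c2)) { enter_dir <- d; break }
    }
    if (is.na(enter_dir)) stop("`start` is not a boundary pixel", call. = FALSE)
  }

  if (sum(mask) == 1L)
    return(list(pixels = matrix(start, 1, 2,
                                dimnames = list(NULL, c("row", "col"))),
                chain = integer(0)))

  px <- list(); chain <- integer(0)
  cur <- start
  backtrack <- enter_dir  # direction pointing at a known background pixel
  first_move <- NULL
  repeat {
    # scan clockwise starting just past the backtrack direction
    found <- FALSE
    for (k in 1:8) {
      d <- (backtrack - k) %% 8L     # clockwise in screen coordinates
      r2 <- cur[1] + freeman_dr[d + 1L]; c2 <- cur[2] + freeman_dc[d + 1L]
      if (inside(r2, c2)) {
        px[[length(px) + 1L]] <- cur
        chain <- c(chain, d)
        # new backtrack: direction from the new pixel toward the last
        # background pixel scanned before finding this one
        dprev <- (backtrack - (k - 1L)) %% 8L
        br <- cur[1] + freeman_dr[dprev + 1L]
        bc <- cur[2] + freeman_dc[dprev + 1L]
        cur <- c(r2, c2)
        backtrack <- dir_between(cur, c(br, bc))
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel (cannot happen after the n==1 guard)
    if (is.null(first_move)) {
      first_move <- chain[1]
    } else if (all(cur == start) && chain[length(chain)] == first_move &&
               length(px) > 1L) {
      # Jacob's criterion approximation: back at start heading the same way
      break
    }
    if (length(chain) > 4L * (nr * nc)) stop("boundary trace failed to close",
                                             call. = FALSE)
    if (all(cur == start)) break
  }
  pixels <- do.call(rbind, px)
  colnames(pixels) <- c("row", "col")
  # drop duplicate visits while keeping order (thin protrusions aside)
  list(pixels = pixels, chain = chain)
}

# Freeman code of the step from pixel a to an 8-neighbour b
dir_between <- function(a, b) {
  dr <- b[1] - a[1]; dc <- b[2] - a[2]
  which(freeman_dr == dr & freeman_dc == dc)[1] - 1L
}

#' @export
print.field_mask <- function(x, ...) {
  cat(sprintf("<field_mask> area %d px, boundary %d px (chain length %d), threshold %.4g\n",
              sum(x$mask), nrow(x$boundary), length(x$chain),
              x$threshold_used))
  invisible(x)
}

# ---- polygon ROI ----------------------------------------------------------

shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Fill a polygon region of interest on a pixel grid
#'
#' Even-odd fill with pixel-centre inclusion: a pixel belongs to the
#' ROI when its centre is inside the polygon or exactly on its
#' boundary.  Pixel centres sit at integer coordinates, `(0, 0)` being
#' the centre of the top-left pixel (`x` = column, `y` = row).
#'
#' @param vertices Two-column matrix (x, y) of polygon vertices in pixel
#'   coordinates, at least 3; the closing edge is implicit.
#' @param grid_shape `c(n_rows, n_cols)` of the target grid.
#' @return An object of class `roi_polygon`: `vertices` (closed),
#'   `filled_mask` (logical matrix), `degenerate` (logical; `TRUE` when
#'   the polygon area is zero).
#' @export
#' @examples
#' sq <- rbind(c(0, 0), c(0, 3), c(3, 3), c(3, 0))
#' sum(fill_polygon(sq, c(10, 10))$filled_mask)  # 16
fill_polygon <- function(vertices, grid_shape) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3) stop("need at least 3 vertices", call. = FALSE)
  if (all(vertices[1, ] == vertices[nrow(vertices), ]))
    vertices <- vertices[-nrow(vertices), , drop = FALSE]
  n <- nrow(vertices)
  if (n < 3) stop("need at least 3 distinct vertices", call. = FALSE)

  # reject self-intersection between non-adjacent edges
  idx <- cbind(seq_len(n), c(2:n, 1L))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # first and last edges are adjacent
      if (segments_intersect(vertices[idx[i, 1], ], vertices[idx[i, 2], ],
                             vertices[idx[j, 1], ], vertices[idx[j, 2], ]))
        stop("polygon is self-intersecting", call. = FALSE)
    }
  }

  degenerate <- shoelace_area(vertices) < .Machine$double.eps^0.5
  nr <- grid_shape[1]; nc <- grid_shape[2]
  px <- rep(0:(nc - 1), each = nr)   # x = column (0-based), column-major
  py <- rep(0:(nr - 1), times = nc)  # y = row

  crossings <- integer(length(px))
  on_edge <- logical(length(px))
  eps <- 1e-9
  for (i in seq_len(n)) {
    a <- vertices[idx[i, 1], ]; b <- vertices[idx[i, 2], ]
    # even-odd ray cast (ray toward +x), half-open in y to handle vertices
    straddles <- (a[2] > py) != (b[2] > py)
    if (any(straddles)) {
      xi <- a[1] + (py - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
      crossings <- crossings + as.integer(straddles & px < xi)
    }
    # boundary inclusion: point within eps of the segment
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 > 0) {
      tt <- pmin(pmax(((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2, 0), 1)
      dx <- px - (a[1] + tt * ab[1]); dy <- py - (a[2] + tt * ab[2])
      on_edge <- on_edge | (dx * dx + dy * dy < eps)
    } else {
      on_edge <- on_edge | (abs(px - a[1]) < eps & abs(py - a[2]) < eps)
    }
  }
  mask <- matrix((crossings %% 2L == 1L) | on_edge, nr, nc)
  structure(list(vertices = rbind(vertices, vertices[1, ]),
                 filled_mask = mask, degenerate = degenerate),
            class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon> %d vertices, %d px filled%s\n",
              nrow(x$vertices) - 1L, sum(x$filled_mask),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Read ROI vertices from CSV
#'
#' Expects columns `x_px, y_px` in pixel coordinates.
#'
#' @param path CSV path.
#' @return Two-column matrix of vertices.
#' @export
read_roi_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("x_px", "y_px") %in% names(df)))
    stop("ROI CSV must have columns x_px, y_px", call. = FALSE)
  as.matrix(df[, c("x_px", "y_px")])
}
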