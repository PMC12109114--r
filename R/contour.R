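#' Extract outer contours from a binary mask
#'
#' Connected foreground regions are labelled and the ordered outer boundary
#' of each region is traced (holes are ignored, matching external-contour
#' retrieval). Contours are returned sorted by enclosed area (descending),
#' ties broken by topmost-then-leftmost starting pixel, so the result is
#' deterministic. Regions whose boundary has fewer than 3 pixels are
#' dropped (they cannot form a polygon).
#'
#' @param mask a `binary_mask` (0/255 matrix) from [binarize_slice()].
#' @return List of `ct_contour` objects, each with `points` (n x 2 matrix
#'   of 0-based `(row, col)` pixel coordinates, ordered along the closed
#'   boundary), `area_px` (shoelace area of the boundary-pixel-center
#'   polygon) and `centroid_px` (polygon center of mass, `(row, col)`).
#' @export
extract_contours <- function(mask) {
  as_mask_matrix(mask)
  if (!any(mask == 255L)) return(list())
  lab <- EBImage::bwlabel(matrix(as.numeric(mask != 0L), nrow(mask)))
  ocs <- EBImage::ocontour(lab)
  out <- lapply(ocs, function(pts) {
    if (nrow(pts) < 3L) return(NULL)
    new_contour(pts)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) return(list())
  key <- vapply(out, function(ct) {
    tr <- min(ct$points[, 1])
    tc <- min(ct$points[ct$points[, 1] == tr, 2])
    tr * 1e6 + tc
  }, 0)
  area <- vapply(out, `[[`, 0, "area_px")
  out[order(-area, key)]
}

new_contour <- function(points) {
  points <- matrix(as.numeric(points), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  structure(list(points = points,
                 area_px = polygon_area(points),
                 centroid_px = polygon_centroid(points)),
            class = "ct_contour")
}

#' @export
print.ct_contour <- function(x, ...) {
  cat("<ct_contour> ", nrow(x$points), " boundary px, area ",
      format(x$area_px), " px, centroid (",
      paste(format(round(x$centroid_px, 1)), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

# shoelace area of a closed polygon given as ordered vertices
polygon_area <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  i2 <- c(2:n, 1L)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# polygon center of mass (shoelace moments); vertex mean for degenerate area
polygon_centroid <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1L)
  cr <- p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(colMeans(p))
  c(sum((p[, 1] + p[i2, 1]) * cr) / (6 * a),
    sum((p[, 2] + p[i2, 2]) * cr) / (6 * a))
}

# convex hull area of a point set
convex_hull_area <- function(p) {
  h <- grDevices::chull(p[, 1], p[, 2])
  if (length(h) < 3L) return(0)
  polygon_area(p[h, , drop = FALSE])
}

#' Contour solidity (area / convex-hull area)
#'
#' @param contour a `ct_contour` or an n x 2 matrix of ordered polygon
#'   vertices.
#' @return Solidity in `(0, 1]`; exactly 1 for convex polygons. `NaN` when
#'   the hull area is zero.
#' @export
contour_solidity <- function(contour) {
  p <- if (inherits(contour, "ct_contour")) contour$points else contour
  a <- if (inherits(contour, "ct_contour")) contour$area_px else
    polygon_area(p)
  h <- convex_hull_area(p)
  if (h <= 0) return(NaN)
  a / h
}

# even-odd (crossing-number) point-in-polygon test, vectorized over points;
# pts and poly are (row, col) matrices. Points on an edge may fall either
# side; callers that care treat boundary pixels separately.
points_in_polygon <- function(pts, poly) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}
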