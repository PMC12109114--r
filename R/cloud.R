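#' Construct a point cloud
#'
#' An unordered set of 3D points in world millimeter coordinates, tagged
#' with the slicing plane that produced it.
#'
#' @param points n x 3 numeric matrix (columns x, y, z in mm).
#' @param source_plane one of `"axial"`, `"sagittal"`, `"coronal"`,
#'   `"merged"`, or a free-form tag (e.g. `"ground_truth"`).
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, source_plane = "merged") {
  points <- as_point_matrix(points)
  if (nrow(points) > 0L && any(!is.finite(points)))
    stop("point coordinates must be finite")
  structure(list(points = points, source_plane = source_plane),
            class = "point_cloud")
}

as_point_matrix <- function(x) {
  if (inherits(x, "point_cloud")) x <- x$points
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("points must be an n x 3 matrix")
  storage.mode(x) <- "double"
  colnames(x) <- c("x", "y", "z")
  x
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("<point_cloud> ", nrow(x$points), " points (", x$source_plane, ")\n",
      sep = "")
  invisible(x)
}

n_points <- function(cloud) nrow(as_point_matrix(cloud))

#' Project contour pixels of a slice into world coordinates
#'
#' Maps each `(row, col)` contour pixel through the slice's recorded
#' row/col axis permutation and the volume geometry (per-axis spacing and
#' origin, with the slice index supplying the third voxel index):
#' `world = origin_mm + c(ix, iy, iz) * spacing_mm`. Because sagittal and
#' coronal slices record their z-axis flip in `row_axis`, all three planes
#' project into the axial world frame by construction and the mapping is
#' exactly invertible back to `(row, col, index)`.
#'
#' @param contour a validated `ct_contour`.
#' @param slice the `planar_slice` the contour was extracted from.
#' @return A [point_cloud()] tagged with the slice orientation.
#' @export
contour_to_world <- function(contour, slice) {
  stopifnot(inherits(slice, "planar_slice"))
  pts <- contour$points
  idx <- slice_to_voxel_index(slice, pts[, 1], pts[, 2])
  n <- slice$geometry$shape
  if (any(idx < 0L) || any(idx[, 1] >= n[1]) || any(idx[, 2] >= n[2]) ||
      any(idx[, 3] >= n[3]))
    stop("contour points outside the volume geometry")
  w <- sweep(sweep(idx, 2, slice$geometry$spacing_mm, "*"), 2,
             slice$geometry$origin_mm, "+")
  point_cloud(w, slice$orientation)
}

#' Map world points back to voxel indices
#'
#' Exact inverse of the projection used by [contour_to_world()]; useful for
#' verifying that every reconstructed point originates from an in-band
#' voxel.
#'
#' @param points a [point_cloud()] or n x 3 matrix (mm).
#' @param volume the source [voxel_volume()].
#' @return n x 3 matrix of fractional 0-based voxel indices.
#' @export
world_to_voxel_index <- function(points, volume) {
  p <- as_point_matrix(points)
  sweep(sweep(p, 2, volume$origin_mm), 2, volume$spacing_mm, "/")
}

#' Axis-aligned bounding box of an axial cloud
#'
#' The axial plane is the standard acquisition orientation and carries the
#' fewest external artifacts, so its componentwise min/max define the
#' acceptable coordinate ranges used to clip the sagittal and coronal
#' clouds.
#'
#' @param cloud a nonempty [point_cloud()].
#' @return An object of class `bounding_box3d` with `min_xyz`, `max_xyz`.
#' @export
axial_bounding_box <- function(cloud) {
  p <- as_point_matrix(cloud)
  if (nrow(p) == 0L) stop("empty point cloud")
  structure(list(min_xyz = apply(p, 2, min), max_xyz = apply(p, 2, max)),
            class = "bounding_box3d")
}

#' Clip a cloud to a closed bounding box
#'
#' Retains exactly the points with `min_xyz <= p <= max_xyz` componentwise.
#' Idempotent.
#'
#' @param cloud a [point_cloud()].
#' @param box a `bounding_box3d`.
#' @return The clipped [point_cloud()].
#' @export
clip_to_box <- function(cloud, box) {
  stopifnot(inherits(box, "bounding_box3d"))
  if (any(box$min_xyz > box$max_xyz)) stop("invalid bounding box")
  p <- as_point_matrix(cloud)
  keep <- p[, 1] >= box$min_xyz[1] & p[, 1] <= box$max_xyz[1] &
    p[, 2] >= box$min_xyz[2] & p[, 2] <= box$max_xyz[2] &
    p[, 3] >= box$min_xyz[3] & p[, 3] <= box$max_xyz[3]
  point_cloud(p[keep, , drop = FALSE],
              if (inherits(cloud, "point_cloud")) cloud$source_plane
              else "merged")
}

#' Voxel-grid downsampling
#'
#' Partitions space into an axis-aligned cubic grid of edge `voxel_mm`
#' anchored at the cloud's componentwise minimum and replaces the points of
#' each occupied cell by their centroid, so the output size equals the
#' number of occupied cells. The result has set semantics: it is
#' independent of the input point order.
#'
#' @param cloud a [point_cloud()].
#' @param voxel_mm grid edge length in mm, > 0.
#' @return The downsampled [point_cloud()].
#' @export
voxel_downsample <- function(cloud, voxel_mm = 1.0) {
  if (voxel_mm <= 0) stop("voxel_mm must be > 0")
  p <- as_point_matrix(cloud)
  plane <- if (inherits(cloud, "point_cloud")) cloud$source_plane else
    "merged"
  if (nrow(p) == 0L) return(point_cloud(p, plane))
  anchor <- apply(p, 2, min)
  ijk <- floor(sweep(p, 2, anchor) / voxel_mm)
  nj <- max(ijk[, 2]) + 1
  nk <- max(ijk[, 3]) + 1
  key <- (ijk[, 1] * nj + ijk[, 2]) * nk + ijk[, 3]
  g <- rowsum(cbind(p, 1), group = key, reorder = TRUE)
  point_cloud(g[, 1:3, drop = FALSE] / g[, 4], plane)
}

#' Merge uniplanar clouds into the triplanar cloud
#'
#' Geometric addition (set union) of the axial, sagittal and coronal clouds
#' followed by a second voxel downsampling at the same voxel size - the
#' two-stage scheme: each uniplanar cloud is downsampled first, the union
#' is downsampled again after merging.
#'
#' @param axial,sagittal,coronal [point_cloud()]s in the common world
#'   frame; `sagittal`/`coronal` may be `NULL`.
#' @param voxel_mm edge length of the second-stage downsampling grid.
#' @return The merged [point_cloud()] with `source_plane = "merged"`.
#' @export
merge_triplanar <- function(axial, sagittal = NULL, coronal = NULL,
                            voxel_mm = 1.0) {
  parts <- Filter(Negate(is.null), list(axial, sagittal, coronal))
  all_pts <- do.call(rbind, lapply(parts, as_point_matrix))
  voxel_downsample(point_cloud(all_pts, "merged"), voxel_mm)
}

#' Outlier removal parameters
#'
#' @param radius_mm search radius of the density (radius) filter.
#' @param min_neighbors minimum neighbor count within `radius_mm` for a
#'   point to survive the density pass.
#' @param stat_k neighbor count of the statistical pass.
#' @param stat_std_ratio standard-deviation multiplier of the statistical
#'   pass.
#' @return An object of class `outlier_params`.
#' @export
outlier_params <- function(radius_mm = 2.0, min_neighbors = 4L,
                           stat_k = 20L, stat_std_ratio = 2.0) {
  if (radius_mm <= 0 || min_neighbors <= 0 || stat_k <= 0 ||
      stat_std_ratio <= 0)
    stop("outlier parameters must be positive")
  structure(list(radius_mm = radius_mm,
                 min_neighbors = as.integer(min_neighbors),
                 stat_k = as.integer(stat_k),
                 stat_std_ratio = stat_std_ratio),
            class = "outlier_params")
}

#' Two-pass outlier removal
#'
#' First a local-density (radius) pass removes points with fewer than
#' `min_neighbors` neighbors within `radius_mm`; then a statistical pass
#' removes points whose mean distance to their `stat_k` nearest neighbors
#' exceeds the global mean by more than `stat_std_ratio` standard
#' deviations. The order (density, then statistical) is fixed.
#'
#' @param cloud a [point_cloud()].
#' @param params an [outlier_params()].
#' @return The cleaned [point_cloud()]. Clouds with at most
#'   `stat_k + 1` points are returned unchanged with a warning.
#' @export
remove_outliers <- function(cloud, params = outlier_params()) {
  stopifnot(inherits(params, "outlier_params"))
  p <- as_point_matrix(cloud)
  plane <- if (inherits(cloud, "point_cloud")) cloud$source_plane else
    "merged"
  if (nrow(p) <= params$stat_k + 1L) {
    warning("cloud smaller than stat_k + 1; returned unchanged")
    return(point_cloud(p, plane))
  }
  k1 <- min(nrow(p), params$min_neighbors + 1L)
  nn <- RANN::nn2(p, p, k = k1)
  counts <- rowSums(nn$nn.dists[, -1, drop = FALSE] <= params$radius_mm)
  p <- p[counts >= params$min_neighbors, , drop = FALSE]
  if (nrow(p) <= params$stat_k + 1L) {
    warning("density pass left fewer than stat_k + 1 points; ",
            "statistical pass skipped")
    return(point_cloud(p, plane))
  }
  nn <- RANN::nn2(p, p, k = params$stat_k + 1L)
  md <- rowMeans(nn$nn.dists[, -1, drop = FALSE])
  keep <- md <= mean(md) + params$stat_std_ratio * sd(md)
  point_cloud(p[keep, , drop = FALSE], plane)
}
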