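#' Construct a Hounsfield-unit voxel volume
#'
#' A `voxel_volume` couples a 3D HU scalar grid with its acquisition
#' geometry. The grid is stored as an array with dimensions `(nx, ny, nz)`
#' following the DICOM patient coordinate convention of the source series:
#' x grows along image columns (left-right), y along image rows
#' (anterior-posterior), z across slices (feet-head). Voxel `(i, j, k)`
#' (0-based) has its center at `origin_mm + c(i, j, k) * spacing_mm`.
#'
#' @param hu 3D numeric array of Hounsfield units, dimensions `(nx, ny, nz)`.
#' @param spacing_mm numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin_mm numeric length-3, world position (mm) of voxel (0,0,0).
#' @return An object of class `voxel_volume` with fields `hu`, `spacing_mm`,
#'   `origin_mm` and `shape`.
#' @export
voxel_volume <- function(hu, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(hu) || length(dim(hu)) != 3L)
    stop("'hu' must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 strictly positive finite values")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("'origin_mm' must be 3 finite values")
  if (any(!is.finite(hu)))
    stop("'hu' contains non-finite values")
  storage.mode(hu) <- "double"
  structure(
    list(hu = hu, spacing_mm = spacing_mm, origin_mm = origin_mm,
         shape = dim(hu)),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(x$shape, collapse = " x "),
      " voxels, spacing (", paste(format(x$spacing_mm), collapse = ", "),
      ") mm, origin (", paste(format(x$origin_mm), collapse = ", "),
      ") mm, HU range [", paste(format(range(x$hu)), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

plane_orientations <- c("axial", "sagittal", "coronal")

#' Reslice a volume into a stack of planar slices
#'
#' Produces the ordered stack of 2D HU slices for one anatomical plane by
#' pure re-indexing of the voxel grid; no interpolation is performed, so
#' every voxel of the volume appears in exactly one slice of each stack.
#'
#' Image conventions (recorded per slice in `row_axis` / `col_axis` and
#' consumed by [contour_to_world()]):
#' * axial, slice `k` along z: rows traverse +y, columns +x; shape `(ny, nx)`.
#' * sagittal, slice `k` along x: rows traverse -z (so the head appears
#'   upright, row 0 at the cranial end), columns +y; shape `(nz, ny)`.
#' * coronal, slice `k` along y: rows traverse -z, columns +x; shape
#'   `(nz, nx)`.
#'
#' @param volume a [voxel_volume()].
#' @param orientation one of `"axial"`, `"sagittal"`, `"coronal"`.
#' @return A list of `planar_slice` objects, ordered by slice index
#'   (0-based, increasing along the slicing axis).
#' @export
reslice <- function(volume, orientation = c("axial", "sagittal", "coronal")) {
  stopifnot(inherits(volume, "voxel_volume"))
  orientation <- match.arg(orientation)
  n <- volume$shape
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  nk <- switch(orientation, axial = nz, sagittal = nx, coronal = ny)
  lapply(seq_len(nk) - 1L, function(k) extract_slice(volume, orientation, k))
}

# single slice by 0-based index; pure index permutation of the grid
extract_slice <- function(volume, orientation, k) {
  n <- volume$shape
  nz <- n[3]
  pix <- switch(orientation,
    axial = t(volume$hu[, , k + 1L]),
    sagittal = t(volume$hu[k + 1L, , ])[nz:1, , drop = FALSE],
    coronal = t(volume$hu[, k + 1L, ])[nz:1, , drop = FALSE]
  )
  axes <- switch(orientation,
    axial = list(row = "+y", col = "+x"),
    sagittal = list(row = "-z", col = "+y"),
    coronal = list(row = "-z", col = "+x")
  )
  structure(
    list(pixels = pix, orientation = orientation, index = as.integer(k),
         row_axis = axes$row, col_axis = axes$col,
         geometry = list(spacing_mm = volume$spacing_mm,
                         origin_mm = volume$origin_mm, shape = n)),
    class = "planar_slice"
  )
}

#' @export
print.planar_slice <- function(x, ...) {
  cat("<planar_slice> ", x$orientation, " #", x$index, ", ",
      nrow(x$pixels), " x ", ncol(x$pixels), " px (rows ", x$row_axis,
      ", cols ", x$col_axis, ")\n", sep = "")
  invisible(x)
}

# map (row, col) pixel coordinates (0-based) of a slice to 0-based voxel
# indices (ix, iy, iz); inverse of the extract_slice re-indexing
slice_to_voxel_index <- function(slice, row, col) {
  n <- slice$geometry$shape
  k <- slice$index
  switch(slice$orientation,
    axial = cbind(ix = col, iy = row, iz = rep(k, length(row))),
    sagittal = cbind(ix = rep(k, length(row)), iy = col, iz = n[3] - 1L - row),
    coronal = cbind(ix = col, iy = rep(k, length(row)), iz = n[3] - 1L - row)
  )
}
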