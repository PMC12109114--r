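#' Specify a synthetic layered-ellipsoid head phantom
#'
#' The phantom emulates a head CT at the level the downstream pipeline
#' cares about: concentric ellipsoidal layers (air / skin / skull / brain)
#' whose HU values straddle the soft-tissue threshold band, anisotropic
#' voxel spacing with a non-zero world origin, and optional artifacts
#' (scanner-table slab, scalp fiducial spheres, intracranial cavities, a
#' nose-like protrusion). Every voxel is classified by its center point, so
#' the analytic outer skin ellipsoid is an exact ground-truth surface for
#' the reconstruction.
#'
#' Layer HU defaults: air -1000, skin +40, skull +700, brain +30, so that
#' with the default threshold band `[-200, +220]` skin and brain are
#' foreground while air and skull are background.
#'
#' @param grid_shape integer length-3, voxel counts `(nx, ny, nz)`.
#' @param spacing_mm numeric length-3, voxel size in mm; all > 0.
#' @param origin_mm numeric length-3, world position of voxel (0,0,0).
#' @param skin_semiaxes_mm,skull_semiaxes_mm,brain_semiaxes_mm numeric
#'   length-3 semi-axes of the concentric layer ellipsoids; must be strictly
#'   decreasing component-wise from skin to brain.
#' @param center_mm world center of the layer ellipsoids; defaults to the
#'   grid center.
#' @param hu_air,hu_skin,hu_skull,hu_brain layer intensities in HU.
#'   `hu_air < -200`; `hu_skin`, `hu_brain` within `[-200, 220]`;
#'   `hu_skull > 220`.
#' @param artifacts list of artifact specs, see [artifact_table_slab()],
#'   [artifact_fiducial_sphere()], [artifact_intracranial_cavity()],
#'   [artifact_nose()].
#' @param seed integer RNG seed recorded in the spec (used by stochastic
#'   helpers such as [sample_surface_cloud()] when none is given).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, spacing_mm, origin_mm = c(0, 0, 0),
                         skin_semiaxes_mm, skull_semiaxes_mm,
                         brain_semiaxes_mm, center_mm = NULL,
                         hu_air = -1000, hu_skin = 40, hu_skull = 700,
                         hu_brain = 30, artifacts = list(), seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (is.null(center_mm))
    center_mm <- origin_mm + (grid_shape - 1) * spacing_mm / 2
  spec <- structure(
    list(grid_shape = grid_shape, spacing_mm = spacing_mm,
         origin_mm = origin_mm, center_mm = as.numeric(center_mm),
         skin_semiaxes_mm = as.numeric(skin_semiaxes_mm),
         skull_semiaxes_mm = as.numeric(skull_semiaxes_mm),
         brain_semiaxes_mm = as.numeric(brain_semiaxes_mm),
         hu_air = hu_air, hu_skin = hu_skin, hu_skull = hu_skull,
         hu_brain = hu_brain, artifacts = artifacts, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3L || any(grid_shape < 1L))
      stop("phantom spec invariant violated: grid_shape components >= 1")
    if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
      stop("phantom spec invariant violated: spacing components strictly positive")
    if (!all(brain_semiaxes_mm < skull_semiaxes_mm) ||
        !all(skull_semiaxes_mm < skin_semiaxes_mm))
      stop("phantom spec invariant violated: brain < skull < skin semi-axes component-wise")
    if (hu_air >= -200)
      stop("phantom spec invariant violated: hu_air < -200")
    if (hu_skin < -200 || hu_skin > 220 || hu_brain < -200 || hu_brain > 220)
      stop("phantom spec invariant violated: hu_skin and hu_brain within [-200, 220]")
    if (hu_skull <= 220)
      stop("phantom spec invariant violated: hu_skull > 220")
  })
  for (a in spec$artifacts) validate_artifact(a, spec)
  invisible(spec)
}

new_artifact <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "artifact_spec")
}

#' Artifact specifications for phantom volumes
#'
#' Artifacts overwrite the layered-ellipsoid HU field in list order and
#' model the non-patient structures the contour filters must reject:
#'
#' * `artifact_table_slab()`: an axis-aligned scanner-table box strictly
#'   below the head (larger y / larger axial row index), soft-tissue HU.
#' * `artifact_fiducial_sphere()`: a small sphere whose center lies on the
#'   outer skin ellipsoid (within one voxel), emulating a scalp marker.
#' * `artifact_intracranial_cavity()`: an air-density sphere that may break
#'   the closure of the skin ring in 2D slices.
#' * `artifact_nose()`: an ellipsoidal protrusion of skin-range HU attached
#'   to the head, exercising the row-crossing filter on complex anatomy.
#'
#' @param center_mm world center of the artifact (mm).
#' @param size_mm table slab edge lengths `(x, y, z)` in mm.
#' @param radius_mm sphere radius in mm.
#' @param semiaxes_mm nose ellipsoid semi-axes in mm.
#' @param hu_value HU written into voxels covered by the artifact.
#' @return An object of class `artifact_spec`.
#' @name artifacts
NULL

#' @rdname artifacts
#' @export
artifact_table_slab <- function(center_mm, size_mm, hu_value = 40) {
  new_artifact("table_slab", list(center_mm = as.numeric(center_mm),
                                  size_mm = as.numeric(size_mm),
                                  hu_value = hu_value))
}

#' @rdname artifacts
#' @export
artifact_fiducial_sphere <- function(center_mm, radius_mm = 4, hu_value = 120) {
  new_artifact("fiducial_sphere", list(center_mm = as.numeric(center_mm),
                                       radius_mm = radius_mm,
                                       hu_value = hu_value))
}

#' @rdname artifacts
#' @export
artifact_intracranial_cavity <- function(center_mm, radius_mm = 10,
                                         hu_value = -1000) {
  new_artifact("intracranial_cavity", list(center_mm = as.numeric(center_mm),
                                           radius_mm = radius_mm,
                                           hu_value = hu_value))
}

#' @rdname artifacts
#' @export
artifact_nose <- function(center_mm, semiaxes_mm, hu_value = 40) {
  new_artifact("nose", list(center_mm = as.numeric(center_mm),
                            semiaxes_mm = as.numeric(semiaxes_mm),
                            hu_value = hu_value))
}

validate_artifact <- function(a, spec) {
  if (!inherits(a, "artifact_spec"))
    stop("artifacts must be created with the artifact_*() constructors")
  if (a$kind == "table_slab") {
    slab_ymin <- a$center_mm[2] - a$size_mm[2] / 2
    head_ymax <- spec$center_mm[2] + spec$skin_semiaxes_mm[2]
    if (slab_ymin <= head_ymax)
      stop("artifact invariant violated: table_slab lies strictly below ",
           "(larger y than) the skin ellipsoid")
  }
  if (a$kind == "fiducial_sphere") {
    d <- point_ellipsoid_distance(matrix(a$center_mm, 1), spec$center_mm,
                                  spec$skin_semiaxes_mm)
    if (d > max(spec$spacing_mm))
      stop("artifact invariant violated: fiducial_sphere center must lie ",
           "on the skin ellipsoid surface within 1 voxel")
  }
  invisible(a)
}

# separable <=1 quadratic-form mask for an axis-aligned ellipsoid evaluated
# at all voxel centers; xs/ys/zs are the per-axis center coordinate vectors
ellipsoid_mask <- function(xs, ys, zs, center, semiaxes) {
  ex <- ((xs - center[1]) / semiaxes[1])^2
  ey <- ((ys - center[2]) / semiaxes[2])^2
  ez <- ((zs - center[3]) / semiaxes[3])^2
  outer(outer(ex, ey, "+"), ez, "+") <= 1
}

sphere_mask <- function(xs, ys, zs, center, radius) {
  outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
        (zs - center[3])^2, "+") <= radius^2
}

box_mask <- function(xs, ys, zs, center, size) {
  inx <- abs(xs - center[1]) <= size[1] / 2
  iny <- abs(ys - center[2]) <= size[2] / 2
  inz <- abs(zs - center[3]) <= size[3] / 2
  outer(outer(inx, iny, "&"), inz, "&")
}

#' Build a phantom HU volume from its specification
#'
#' Each voxel receives the HU value of the innermost layer ellipsoid that
#' contains the voxel center, then artifacts overwrite covered voxels in
#' list order. The construction is purely arithmetic and therefore
#' bit-reproducible for a fixed spec.
#'
#' @param spec a [phantom_spec()].
#' @return A [voxel_volume()].
#' @export
build_phantom <- function(spec) {
  validate_phantom_spec(spec)
  n <- spec$grid_shape
  xs <- spec$origin_mm[1] + (seq_len(n[1]) - 1) * spec$spacing_mm[1]
  ys <- spec$origin_mm[2] + (seq_len(n[2]) - 1) * spec$spacing_mm[2]
  zs <- spec$origin_mm[3] + (seq_len(n[3]) - 1) * spec$spacing_mm[3]
  hu <- array(spec$hu_air, dim = n)
  hu[ellipsoid_mask(xs, ys, zs, spec$center_mm, spec$skin_semiaxes_mm)] <-
    spec$hu_skin
  hu[ellipsoid_mask(xs, ys, zs, spec$center_mm, spec$skull_semiaxes_mm)] <-
    spec$hu_skull
  hu[ellipsoid_mask(xs, ys, zs, spec$center_mm, spec$brain_semiaxes_mm)] <-
    spec$hu_brain
  for (a in spec$artifacts) {
    m <- switch(a$kind,
      table_slab = box_mask(xs, ys, zs, a$center_mm, a$size_mm),
      fiducial_sphere = sphere_mask(xs, ys, zs, a$center_mm, a$radius_mm),
      intracranial_cavity = sphere_mask(xs, ys, zs, a$center_mm, a$radius_mm),
      nose = ellipsoid_mask(xs, ys, zs, a$center_mm, a$semiaxes_mm),
      stop("unknown artifact kind: ", a$kind)
    )
    hu[m] <- a$hu_value
  }
  voxel_volume(hu, spec$spacing_mm, spec$origin_mm)
}

#' Distance from points to the phantom's outer skin surface
#'
#' Computes, for each point, the Euclidean distance to the nearest point on
#' the analytic outer skin ellipsoid, plus the RMS over all points. Used as
#' the ground-truth accuracy measure for reconstructed clouds.
#'
#' @param points a [point_cloud()] or an n x 3 matrix of world mm
#'   coordinates.
#' @param spec the [phantom_spec()] that generated the volume.
#' @return list with `distance_mm` (per point) and `rms_mm`.
#' @export
surface_distance <- function(points, spec) {
  pts <- as_point_matrix(points)
  if (nrow(pts) == 0L) stop("empty point cloud")
  d <- point_ellipsoid_distance(pts, spec$center_mm, spec$skin_semiaxes_mm)
  list(distance_mm = d, rms_mm = sqrt(mean(d^2)))
}

#' Nearest-point distance to an axis-aligned ellipsoid
#'
#' Solves, per point, the Lagrange stationarity condition for the nearest
#' point on the ellipsoid `sum(((x - center)/semiaxes)^2) = 1` by bisection
#' followed by Newton polishing (tolerance 1e-9 mm on the surface residual);
#' no closed form exists for triaxial ellipsoids. Exact closed form is used
#' when all semi-axes are equal (sphere).
#'
#' @param points n x 3 matrix of query points (mm).
#' @param center,semiaxes ellipsoid center and semi-axes (mm).
#' @return numeric vector of distances (mm), >= 0, zero on the surface.
#' @export
point_ellipsoid_distance <- function(points, center, semiaxes) {
  p <- sweep(as_point_matrix(points), 2, center)
  a <- as.numeric(semiaxes)
  if (max(a) - min(a) < 1e-12)          # sphere: exact
    return(abs(sqrt(rowSums(p^2)) - a[1]))
  # degenerate on-center points: nearest point sits on the smallest axis
  r0 <- sqrt(rowSums(p^2))
  deg <- r0 < 1e-12
  # avoid exact-zero components so the largest Lagrange root is well defined
  p[abs(p) < 1e-12] <- 1e-12
  a2 <- a^2
  b2 <- sweep(p^2, 2, a2, "*")          # (a_i p_i)^2 per point
  f <- function(t) rowSums(b2 / (outer(t, a2, "+"))^2) - 1
  lo <- rep(-min(a2) + 1e-12 * min(a2), nrow(p))
  hi <- pmax(max(a) * sqrt(rowSums(p^2)), 0) + max(a2)
  for (i in 1:100) {                    # bisection: robust bracket shrink
    mid <- (lo + hi) / 2
    pos <- f(mid) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  t <- (lo + hi) / 2
  for (i in 1:5) {                      # Newton polish on the bracketed root
    ft <- rowSums(b2 / (outer(t, a2, "+"))^2) - 1
    fp <- -2 * rowSums(b2 / (outer(t, a2, "+"))^3)
    step <- ft / fp
    t2 <- t - step
    ok <- t2 > lo & t2 < hi
    t[ok] <- t2[ok]
  }
  x <- p * sweep(outer(t, a2, "+"), 2, a2, "/")^-1  # x_i = a_i^2 p_i/(t+a_i^2)
  d <- sqrt(rowSums((x - p)^2))
  d[deg] <- min(a)
  d
}

#' Densely sample the phantom's analytic skin surface
#'
#' Draws an area-uniform sample of points on the outer skin ellipsoid by
#' rejection sampling over sphere directions weighted by the local surface
#' area element. Serves as the ground-truth "model" cloud for registration
#' and coverage evaluation.
#'
#' @param spec a [phantom_spec()].
#' @param n number of surface points to draw.
#' @param seed RNG seed; defaults to the spec's seed.
#' @return A [point_cloud()] with `source_plane = "ground_truth"`.
#' @export
sample_surface_cloud <- function(spec, n = 100000L, seed = spec$seed) {
  a <- spec$skin_semiaxes_mm
  out <- matrix(numeric(0), 0, 3)
  wmax <- max(a[2] * a[3], a[1] * a[3], a[1] * a[2])
  rs <- local({
    set.seed(seed)
    function(m) {
      u <- matrix(rnorm(3 * m), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      w <- sqrt((a[2] * a[3] * u[, 1])^2 + (a[1] * a[3] * u[, 2])^2 +
                  (a[1] * a[2] * u[, 3])^2)
      u[runif(m) <= w / wmax, , drop = FALSE]
    }
  })
  while (nrow(out) < n)
    out <- rbind(out, rs(2L * n))
  pts <- sweep(out[seq_len(n), , drop = FALSE], 2, a, "*")
  point_cloud(sweep(pts, 2, spec$center_mm, "+"), "ground_truth")
}

#' Write / read the analytic-surface sidecar of a phantom series
#'
#' The sidecar is a YAML file recording every field of the phantom spec so
#' that a reconstructed cloud can be scored against the analytic surface
#' without re-deriving it from the voxel data.
#'
#' @param spec a [phantom_spec()].
#' @param path file path of the YAML sidecar.
#' @return `write_phantom_spec()` returns `path` invisibly;
#'   `read_phantom_spec()` returns the reconstructed [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  x <- unclass(spec)
  x$artifacts <- lapply(spec$artifacts, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  arts <- lapply(x$artifacts, function(a) {
    kind <- a$kind
    a$kind <- NULL
    do.call(switch(kind,
                   table_slab = artifact_table_slab,
                   fiducial_sphere = artifact_fiducial_sphere,
                   intracranial_cavity = artifact_intracranial_cavity,
                   nose = artifact_nose),
            a)
  })
  phantom_spec(grid_shape = x$grid_shape, spacing_mm = x$spacing_mm,
               origin_mm = x$origin_mm, center_mm = x$center_mm,
               skin_semiaxes_mm = x$skin_semiaxes_mm,
               skull_semiaxes_mm = x$skull_semiaxes_mm,
               brain_semiaxes_mm = x$brain_semiaxes_mm,
               hu_air = x$hu_air, hu_skin = x$hu_skin,
               hu_skull = x$hu_skull, hu_brain = x$hu_brain,
               artifacts = arts, seed = x$seed)
}

#' Reference sphere phantom for pipeline evaluation
#'
#' A spherical head (default radius 60 mm) on a grid with anisotropic
#' spacing, margins chosen so the head clears the default centroid and
#' equipment-region boxes in all three planes. With
#' `with_artifacts = TRUE`, the study artifact set is added: a scanner
#' table slab (HU 40) below the head, three 4 mm fiducial spheres on the
#' scalp, and a 10 mm air cavity breaking the skin ring at the crown.
#'
#' @param radius_mm outer skin radius (mm); skull and brain surfaces sit
#'   8 mm and 15 mm deeper.
#' @param spacing_mm voxel size (mm); the default undersamples the poles
#'   axially (slice spacing above in-plane spacing).
#' @param with_artifacts add the study artifact set.
#' @param seed recorded RNG seed.
#' @return A [phantom_spec()].
#' @export
sphere_phantom_spec <- function(radius_mm = 60,
                                spacing_mm = c(0.5, 0.5, 0.625),
                                with_artifacts = FALSE, seed = 1L) {
  r <- radius_mm
  lo <- c(-r - 10, -r - 15, -r - 25)
  hi <- c(r + 10, r + 35, r + 4.375)
  shape <- ceiling((hi - lo) / spacing_mm)
  arts <- list()
  if (with_artifacts) {
    d <- r / sqrt(2)
    arts <- list(
      artifact_table_slab(center_mm = c(0, r + 8, 0),
                          size_mm = c(2 * r + 20, 8, 4 * r / 3),
                          hu_value = 40),
      artifact_fiducial_sphere(c(0, -r, 0), radius_mm = 4, hu_value = 120),
      artifact_fiducial_sphere(c(d, -d, 0), radius_mm = 4, hu_value = 120),
      artifact_fiducial_sphere(c(0, -0.6 * r, 0.8 * r), radius_mm = 4,
                               hu_value = 120),
      artifact_intracranial_cavity(c(0, 0, r), radius_mm = 10,
                                   hu_value = -1000)
    )
  }
  phantom_spec(grid_shape = shape, spacing_mm = spacing_mm,
               origin_mm = lo, center_mm = c(0, 0, 0),
               skin_semiaxes_mm = rep(r, 3),
               skull_semiaxes_mm = rep(r - 8, 3),
               brain_semiaxes_mm = rep(r - 15, 3),
               artifacts = arts, seed = seed)
}
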