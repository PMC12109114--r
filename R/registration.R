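#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1 (checked to
#'   1e-9).
#' @param translation numeric length-3, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points a [point_cloud()] or n x 3 matrix.
#' @return Transformed points in the same container type.
#' @export
apply_transform <- function(transform, points) {
  p <- as_point_matrix(points)
  q <- sweep(p %*% t(transform$rotation), 2, transform$translation, "+")
  if (inherits(points, "point_cloud"))
    point_cloud(q, points$source_plane)
  else q
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b [rigid_transform()]s.
#' @return The composite [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Rotation matrix about a unit axis
#' @param axis length-3 axis (normalized internally).
#' @param angle_rad rotation angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_rad) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

#' Count points of one cloud absent from another
#'
#' A query point is unique iff no reference point lies within `radius_mm`
#' (closed ball: a neighbor at exactly the radius disqualifies). Computed
#' with a k-d tree nearest-neighbor search. The unique-point percentage of
#' the triplanar cloud versus the axial cloud quantifies the enrichment
#' contributed by the sagittal and coronal planes.
#'
#' @param query,reference nonempty [point_cloud()]s in a common frame.
#' @param radius_mm search tolerance in mm, > 0.
#' @return List with `count`, `fraction` (`count / n_query`), `percent`,
#'   and `unique_cloud` (the unique subset as a [point_cloud()]).
#' @export
unique_points <- function(query, reference, radius_mm = 1.0) {
  if (radius_mm <= 0) stop("radius_mm must be positive")
  q <- as_point_matrix(query)
  r <- as_point_matrix(reference)
  if (nrow(q) == 0L || nrow(r) == 0L) stop("clouds must be nonempty")
  d1 <- RANN::nn2(r, q, k = 1L)$nn.dists[, 1]
  uniq <- d1 > radius_mm
  list(count = sum(uniq), fraction = mean(uniq), percent = 100 * mean(uniq),
       unique_cloud = point_cloud(q[uniq, , drop = FALSE], "unique"))
}

#' ICP parameters
#'
#' @param rms_delta_mm convergence threshold on the RMS improvement
#'   between iterations (mm).
#' @param overlap_fraction fraction of closest correspondences retained
#'   each iteration (farthest-point removal), in (0, 1].
#' @param max_samples cap on the number of source points used; when the
#'   source is larger it is randomly subsampled (seeded).
#' @param max_iterations iteration cap.
#' @param seed RNG seed for the subsampling.
#' @return An object of class `icp_params`.
#' @export
icp_params <- function(rms_delta_mm = 1e-4, overlap_fraction = 0.90,
                       max_samples = 100000L, max_iterations = 50L,
                       seed = 1L) {
  if (overlap_fraction <= 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in (0, 1]")
  structure(list(rms_delta_mm = rms_delta_mm,
                 overlap_fraction = overlap_fraction,
                 max_samples = as.integer(max_samples),
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "icp_params")
}

# closed-form least-squares rigid fit (orthogonal Procrustes / SVD)
procrustes_rigid <- function(src, dst) {
  ms <- colMeans(src); md <- colMeans(dst)
  H <- crossprod(sweep(src, 2, ms), sweep(dst, 2, md))
  s <- svd(H)
  if (s$d[2] < 1e-12 * max(s$d[1], 1))
    stop("degenerate geometry: rank-deficient cross-covariance")
  D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% D %*% t(s$u)
  rigid_transform(R, md - as.numeric(R %*% ms))
}

#' Rigid ICP registration with farthest-point trimming
#'
#' Iterates nearest-neighbor correspondence search (k-d tree) and a
#' closed-form least-squares rigid update, keeping only the
#' `overlap_fraction` closest correspondences each iteration
#' (farthest-point removal), until the RMS improvement drops below
#' `rms_delta_mm` or `max_iterations` is reached. `init` stands in for the
#' coarse manual alignment that precedes fine registration.
#'
#' @param source,target [point_cloud()]s with at least 3 non-collinear
#'   points; `source` is moved onto `target`.
#' @param params an [icp_params()].
#' @param init initial [rigid_transform()] applied to the source.
#' @return A `registration_result`: `transform` (total source-to-target
#'   transform), `rms_mm` (RMS distance of the retained correspondences at
#'   the final pose), `iterations`, `converged`, and `rms_history`.
#' @export
icp_register <- function(source, target, params = icp_params(),
                         init = rigid_transform()) {
  src0 <- as_point_matrix(source)
  tgt <- as_point_matrix(target)
  if (nrow(src0) < 3L || nrow(tgt) < 3L)
    stop("both clouds need at least 3 points")
  if (nrow(src0) > params$max_samples) {
    idx <- local({
      set.seed(params$seed)
      sample.int(nrow(src0), params$max_samples)
    })
    src0 <- src0[idx, , drop = FALSE]
  }
  transform <- init
  n_keep <- max(3L, ceiling(params$overlap_fraction * nrow(src0)))
  rms_prev <- Inf
  history <- numeric(0)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    moved <- apply_transform(transform, src0)
    nn <- RANN::nn2(tgt, moved, k = 1L)
    keep <- order(nn$nn.dists[, 1])[seq_len(n_keep)]
    rms <- sqrt(mean(nn$nn.dists[keep, 1]^2))
    history <- c(history, rms)
    if (rms < params$rms_delta_mm || rms_prev - rms < params$rms_delta_mm) {
      converged <- TRUE
      break
    }
    if (iter >= params$max_iterations) break
    upd <- procrustes_rigid(moved[keep, , drop = FALSE],
                            tgt[nn$nn.idx[keep, 1], , drop = FALSE])
    transform <- compose_transform(upd, transform)
    rms_prev <- rms
  }
  structure(list(transform = transform, rms_mm = history[length(history)],
                 iterations = iter, converged = converged,
                 rms_history = history),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result> RMS ", format(x$rms_mm), " mm after ",
      x$iterations, " iterations (",
      if (x$converged) "converged" else "iteration cap", ")\n", sep = "")
  invisible(x)
}

#' One-sided coverage distance field
#'
#' For every ground-truth point, the distance to the nearest test-cloud
#' point; points at least `cutoff_mm` away are flagged as regions of the
#' reference surface that the reconstruction misses.
#'
#' @param gt_cloud ground-truth [point_cloud()] (registered to the test
#'   cloud's frame).
#' @param test_cloud the reconstructed [point_cloud()]; empty means every
#'   ground-truth point is flagged.
#' @param cutoff_mm flagging distance, mm.
#' @return List with `distance_mm` (per ground-truth point), `flagged`
#'   (logical), and `flagged_fraction`.
#' @export
coverage_field <- function(gt_cloud, test_cloud, cutoff_mm = 1.0) {
  g <- as_point_matrix(gt_cloud)
  t_ <- as_point_matrix(test_cloud)
  if (nrow(g) == 0L) stop("empty ground-truth cloud")
  if (nrow(t_) == 0L) {
    d <- rep(Inf, nrow(g))
  } else {
    d <- RANN::nn2(t_, g, k = 1L)$nn.dists[, 1]
  }
  flagged <- d >= cutoff_mm
  list(distance_mm = d, flagged = flagged,
       flagged_fraction = mean(flagged))
}
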