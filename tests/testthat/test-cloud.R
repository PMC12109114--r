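dummy_volume <- function(shape = c(60, 60, 40), spacing = c(0.5, 0.5, 0.625),
                         origin = c(-100, -100, -50)) {
  voxel_volume(array(0, dim = shape), spacing, origin)
}

test_that("contour points project to world mm by the affine geometry", {
  vol0 <- dummy_volume(c(30, 30, 10), c(1, 1, 1), c(0, 0, 0))
  sl0 <- ct2skin:::extract_slice(vol0, "axial", 0)
  ct <- ct2skin:::new_contour(rbind(c(0, 0), c(0, 2), c(2, 2), c(2, 0)))
  w <- contour_to_world(ct, sl0)
  expect_equal(w$points[1, ], c(x = 0, y = 0, z = 0))

  vol <- dummy_volume()
  sl5 <- ct2skin:::extract_slice(vol, "axial", 5)
  ct2 <- ct2skin:::new_contour(rbind(c(20, 10), c(20, 12), c(22, 12)))
  w2 <- contour_to_world(ct2, sl5)
  expect_equal(w2$points[1, ], c(x = -95.0, y = -90.0, z = -46.875))
})

test_that("projection is exactly invertible for every orientation", {
  vol <- dummy_volume()
  set.seed(8)
  for (o in c("axial", "sagittal", "coronal")) {
    nk <- switch(o, axial = vol$shape[3], sagittal = vol$shape[1],
                 coronal = vol$shape[2])
    k <- sample(0:(nk - 1), 1)
    sl <- ct2skin:::extract_slice(vol, o, k)
    d <- dim(sl$pixels)
    pts <- cbind(sample(0:(d[1] - 1), 30, TRUE),
                 sample(0:(d[2] - 1), 30, TRUE))
    ct <- ct2skin:::new_contour(pts)
    w <- contour_to_world(ct, sl)
    idx <- world_to_voxel_index(w, vol)
    fwd <- ct2skin:::slice_to_voxel_index(sl, pts[, 1], pts[, 2])
    expect_lt(max(abs(idx - fwd)), 1e-9)
  }
})

test_that("every projected phantom point maps back to an in-band voxel", {
  spec <- small_sphere_spec()
  vol <- build_phantom(spec)
  ex <- extract_plane_clouds(vol)
  for (plane in names(ex$clouds)) {
    idx <- round(world_to_voxel_index(ex$clouds[[plane]], vol)) + 1
    hu <- vol$hu[idx]
    expect_true(all(hu >= -200 & hu <= 220))
  }
})

test_that("axial bounding box and clipping agree with per-point comparison", {
  p1 <- matrix(c(1, 2, 3), 1)
  b1 <- axial_bounding_box(point_cloud(p1))
  expect_equal(b1$min_xyz, b1$max_xyz)

  p2 <- rbind(c(0, 5, -2), c(3, -1, 7))
  b2 <- axial_bounding_box(point_cloud(p2))
  expect_equal(unname(b2$min_xyz), c(0, -1, -2))
  expect_equal(unname(b2$max_xyz), c(3, 5, 7))
  expect_error(axial_bounding_box(point_cloud(matrix(0, 0, 3))))

  set.seed(20)
  cl <- point_cloud(matrix(runif(900, -10, 10), ncol = 3))
  box <- structure(list(min_xyz = c(-5, -4, -6), max_xyz = c(5, 6, 4)),
                   class = "bounding_box3d")
  kept <- clip_to_box(cl, box)
  oracle_keep <- apply(cl$points, 1, function(p)
    all(p >= box$min_xyz) && all(p <= box$max_xyz))
  expect_equal(nrow(kept$points), sum(oracle_keep))
  # closed box: boundary points retained
  edge <- point_cloud(rbind(c(5, 6, 4), c(5.0001, 0, 0)))
  expect_equal(nrow(clip_to_box(edge, box)$points), 1)
  # idempotence and identity on interior clouds
  expect_equal(clip_to_box(kept, box)$points, kept$points)
})

test_that("voxel downsampling: centroids per occupied cell, hashing oracle, order invariance", {
  # 8 points inside one voxel collapse to their centroid
  set.seed(2)
  p8 <- matrix(runif(24, 0, 0.9), ncol = 3)
  d8 <- voxel_downsample(point_cloud(p8), 1)
  expect_equal(nrow(d8$points), 1)
  expect_equal(unname(d8$points[1, ]), unname(colMeans(p8)))

  # points on a 2 mm lattice survive 1 mm downsampling unchanged
  g <- as.matrix(expand.grid(x = seq(0, 6, 2), y = seq(0, 6, 2),
                             z = seq(0, 4, 2)))
  dg <- voxel_downsample(point_cloud(g), 1)
  expect_equal(nrow(dg$points), nrow(g))

  # occupied-voxel count vs floor-division hashing oracle on random clouds
  for (rep in 1:5) {
    cl <- matrix(runif(600, -7, 13), ncol = 3)
    v <- 1.7
    ds <- voxel_downsample(point_cloud(cl), v)
    anchor <- apply(cl, 2, min)
    keys <- apply(floor(sweep(cl, 2, anchor) / v), 1, paste, collapse = ",")
    expect_equal(nrow(ds$points), length(unique(keys)))
  }

  # set semantics: permuting the input leaves the result unchanged
  cl <- matrix(runif(300, 0, 20), ncol = 3)
  a <- voxel_downsample(point_cloud(cl), 1)
  b <- voxel_downsample(point_cloud(cl[sample(nrow(cl)), ]), 1)
  expect_equal(a$points[order(a$points[, 1], a$points[, 2]), ],
               b$points[order(b$points[, 1], b$points[, 2]), ])

  expect_equal(nrow(voxel_downsample(point_cloud(matrix(0, 0, 3)), 1)$points),
               0)
  expect_error(voxel_downsample(point_cloud(cl), 0))
})

test_that("triplanar merging is union + second-stage downsampling", {
  set.seed(6)
  cl <- point_cloud(matrix(runif(300, 0, 30), ncol = 3), "axial")
  ds <- voxel_downsample(cl, 1)
  # three identical clouds collapse to one downsampled copy
  m <- merge_triplanar(cl, cl, cl, 1)
  expect_equal(nrow(m$points), nrow(ds$points))
  expect_equal(m$source_plane, "merged")

  # disjoint lattice-aligned clouds separated far beyond the voxel:
  # sizes add (lattice alignment keeps counts independent of grid phase)
  lat <- as.matrix(expand.grid(x = seq(0, 8, 2), y = seq(0, 8, 2), z = 0))
  d1 <- voxel_downsample(point_cloud(lat), 1)
  d2 <- voxel_downsample(point_cloud(sweep(lat, 2, c(100, 0, 0), "+")), 1)
  m2 <- merge_triplanar(d1, d2, NULL, 1)
  expect_equal(nrow(m2$points), nrow(d1$points) + nrow(d2$points))
})

test_that("outlier removal matches a brute-force all-pairs oracle", {
  spec <- small_sphere_spec()
  surf <- sample_surface_cloud(spec, n = 8000, seed = 3)
  # dense surface cloud with defaults: the surface itself is preserved
  # (no point fails the density pass; only the extreme kNN-distance tail
  # of the statistical pass may go, never more than a few percent)
  kept <- remove_outliers(surf, outlier_params())
  expect_gt(nrow(kept$points), 0.94 * 8000)

  # one isolated point 50 mm away is always removed (zero radius neighbors)
  iso <- point_cloud(rbind(surf$points, c(0, 0, 25 + 50)))
  kept2 <- remove_outliers(iso, outlier_params())
  expect_lt(max(point_ellipsoid_distance(kept2$points, spec$center_mm,
                                         spec$skin_semiaxes_mm)), 2)

  # oracle replication of both passes on a noisy cloud
  set.seed(9)
  noisy <- rbind(surf$points[1:800, ],
                 matrix(runif(45, -80, 80), ncol = 3))
  pars <- outlier_params(radius_mm = 3, min_neighbors = 3, stat_k = 10,
                         stat_std_ratio = 1.5)
  got <- remove_outliers(point_cloud(noisy), pars)$points
  D <- as.matrix(dist(noisy))
  diag(D) <- Inf
  keep1 <- rowSums(D <= pars$radius_mm) >= pars$min_neighbors
  p2 <- noisy[keep1, , drop = FALSE]
  D2 <- as.matrix(dist(p2))
  diag(D2) <- Inf
  md <- apply(D2, 1, function(r) mean(sort(r)[1:pars$stat_k]))
  keep2 <- md <= mean(md) + pars$stat_std_ratio * sd(md)
  expect_equal(got, p2[keep2, , drop = FALSE])

  # too-small clouds come back unchanged with a warning
  tiny <- point_cloud(matrix(runif(30), ncol = 3))
  expect_warning(out <- remove_outliers(tiny, outlier_params()), "unchanged")
  expect_equal(nrow(out$points), 10)
})
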