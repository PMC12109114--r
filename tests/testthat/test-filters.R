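test_that("centroid gate passes head-like contours and rejects bottom equipment", {
  cfg <- filter_config()
  center_disk <- extract_contours(disk_mask(100, 100, 50, 50, 20))
  expect_true(centroid_gate(center_disk, cfg, c(100, 100))$accepted)

  bottom_disk <- extract_contours(disk_mask(100, 100, 95, 50, 4))
  v <- centroid_gate(bottom_disk, cfg, c(100, 100))
  expect_false(v$accepted)
  expect_equal(v$reason, "centroid_out_of_range")
  expect_true(is.finite(v$area_px))   # area still reported for the carry

  # a box covering the whole image is a vacuous gate
  cfg_all <- filter_config(centroid_valid_box = c(0, 1, 0, 1))
  expect_true(centroid_gate(bottom_disk, cfg_all, c(100, 100))$accepted)
})

test_that("first-row connection fills between first and last white pixels only", {
  m <- matrix(0L, 20, 60)
  m[3, c(10, 50)] <- 255L
  m[10, 5] <- 255L
  class(m) <- c("binary_mask", class(m))
  cm <- connect_first_row(m)
  expect_equal(attr(cm, "connection_row"), 2L)   # 0-based
  expect_true(all(cm[3, 10:50] == 255L))
  # edits confined to that single row
  changed <- which(unclass(cm) != unclass(m), arr.ind = TRUE)
  expect_true(all(changed[, 1] == 3))

  # all-zero mask is untouched
  z <- matrix(0L, 5, 5)
  class(z) <- c("binary_mask", class(z))
  expect_true(is.na(attr(connect_first_row(z), "connection_row")))

  # foreground growth equals (last - first + 1) - prior count in that row
  set.seed(12)
  for (rep in 1:10) {
    mm <- matrix(0L, 30, 40)
    mm[cbind(sample(1:30, 25, TRUE), sample(1:40, 25, TRUE))] <- 255L
    class(mm) <- c("binary_mask", class(mm))
    r <- which(rowSums(mm == 255L) > 0)[1]
    cols <- which(mm[r, ] == 255L)
    expected_gain <- (max(cols) - min(cols) + 1) - length(cols)
    expect_equal(sum(connect_first_row(mm) == 255L) - sum(mm == 255L),
                 expected_gain)
  }
})

test_that("connection-row stripping deletes exactly the points on that row", {
  pts <- rbind(cbind(0, 0:4),                 # 5 points on row 0
               cbind(1:5, 5), cbind(5, 4:0), cbind(4:1, 0))
  ct <- ct2skin:::new_contour(pts)
  st <- strip_connection_row(ct, 0)
  expect_equal(nrow(st$points), nrow(pts) - 5)
  expect_true(all(st$points[, 1] != 0))
  expect_equal(st$area_px, ct$area_px)        # cached area retained

  # no points on the row: unchanged
  expect_equal(strip_connection_row(ct, 99)$points, ct$points)
  # degenerate: everything stripped
  flat <- ct2skin:::new_contour(cbind(c(0, 0, 0), c(0, 2, 4)))
  expect_null(strip_connection_row(flat, 0))
})

test_that("solidity filter rejects large irregular contours and skips small ones", {
  cfg <- filter_config()
  big_disk <- extract_contours(disk_mask(300, 300, 150, 150, 130))[[1]]
  expect_gt(big_disk$area_px, 40000)
  v <- solidity_check(big_disk, cfg)
  expect_true(v$accepted)
  expect_gt(v$solidity, 0.98)

  # large L-shape: exact solidity 6/7 < 0.88
  L <- matrix(0L, 320, 320)
  L <- rect_mask_set(L, 11, 310, 11, 160)
  L <- rect_mask_set(L, 161, 310, 11, 310)
  class(L) <- c("binary_mask", class(L))
  ct <- extract_contours(L)[[1]]
  expect_gt(ct$area_px, 40000)
  vL <- solidity_check(ct, cfg)
  expect_false(vL$accepted)
  expect_equal(vL$reason, "low_solidity")
  expect_equal(vL$solidity, 6 / 7, tolerance = 0.01)

  # small irregular contour (area ~1000) is not tested at all
  sm <- matrix(0L, 60, 60)
  sm <- rect_mask_set(sm, 10, 40, 10, 25)
  sm <- rect_mask_set(sm, 30, 50, 20, 50)
  class(sm) <- c("binary_mask", class(sm))
  ct_sm <- extract_contours(sm)[[1]]
  expect_lt(ct_sm$area_px, 40000)
  expect_true(solidity_check(ct_sm, cfg)$accepted)
})

test_that("four-direction scan fires only on triggered slices with off-contour foreground on a cardinal ray", {
  cfg <- filter_config()
  m <- disk_mask(120, 160, 60, 60, 25)
  ct <- extract_contours(m)[[1]]
  trigger_area <- ct$area_px * 2      # 50% jump: trigger active

  # clean mask: nothing outside the contour
  expect_true(four_direction_check(m, ct, trigger_area, cfg)$accepted)

  # blob on the +col ray from the centroid, outside the disk
  m_on <- rect_mask_set(m, 58, 62, 118, 122)
  ct_on <- extract_contours(m_on)[[1]]     # disk is still largest
  expect_equal(ct_on$area_px, ct$area_px)
  v <- four_direction_check(m_on, ct_on, trigger_area, cfg)
  expect_false(v$accepted)
  expect_equal(v$reason, "four_direction_fail")
  # the blob really is outside the polygon (point-in-polygon oracle)
  expect_false(any(ct2skin:::points_in_polygon(cbind(59, 119), ct$points)))

  # same blob moved off all four rays (diagonal): the scan is blind to it
  m_off <- rect_mask_set(m, 98, 102, 118, 122)
  ct_off <- extract_contours(m_off)[[1]]
  expect_true(four_direction_check(m_off, ct_off, trigger_area, cfg)$accepted)

  # without an area jump the filter is not triggered at all
  expect_true(four_direction_check(m_on, ct_on, ct_on$area_px, cfg)$accepted)
  # and the first slice of a plane never triggers
  expect_true(four_direction_check(m_on, ct_on, NULL, cfg)$accepted)
})

test_that("row-crossing filter counts separated contour pixels per scanned row", {
  cfg <- filter_config()

  # convex contour: two crossings per row, always passes
  disk <- extract_contours(disk_mask(100, 100, 50, 50, 30))[[1]]
  expect_true(row_crossing_check(disk, c(100, 100), cfg)$accepted)

  # 6-tooth comb spanning 8 scanned rows: rejected
  comb <- extract_contours(comb_mask(60, 80, 6, 30))[[1]]
  v <- row_crossing_check(comb, c(60, 80), cfg)
  expect_false(v$accepted)
  expect_equal(v$reason, "row_crossing_fail")

  # oracle: count crossings by direct row scan of the contour pixels
  pts <- comb$points
  bad <- 0
  for (r in seq(0, 59, by = cfg$row_step)) {
    cols <- sort(pts[pts[, 1] == r, 2])
    if (length(cols) == 0) next
    cnt <- 1; last <- cols[1]
    for (cc in cols[-1]) if (cc - last >= cfg$min_pixel_gap) {
      cnt <- cnt + 1; last <- cc
    }
    if (cnt >= cfg$crossings_per_row_trigger) bad <- bad + 1
  }
  expect_gt(bad, cfg$bad_row_limit)

  # same comb limited to 3 scanned rows: under the bad-row limit, passes
  comb_short <- extract_contours(comb_mask(60, 80, 6, 10))[[1]]
  expect_true(row_crossing_check(comb_short, c(60, 80), cfg)$accepted)
})

test_that("equipment-region check fires iff foreground intersects a region", {
  cfg <- filter_config()   # bottom 12% band
  m <- disk_mask(100, 100, 40, 50, 25)       # head clear of the band
  expect_true(equipment_region_check(m, cfg)$accepted)

  slab <- rect_mask_set(m, 93, 97, 10, 90)   # table slab inside the band
  class(slab) <- c("binary_mask", class(slab))
  v <- equipment_region_check(slab, cfg)
  expect_false(v$accepted)
  expect_equal(v$reason, "equipment_region_hit")

  # no regions configured: vacuous pass
  cfg0 <- filter_config(equipment_regions = list())
  expect_true(equipment_region_check(slab, cfg0)$accepted)
})

test_that("the full chain accepts clean head slices and repairs broken rings", {
  spec <- small_sphere_spec()
  vol <- build_phantom(spec)
  mid <- reslice(vol, "axial")[[round(vol$shape[3] / 2)]]
  v <- validate_slice(binarize_slice(mid))
  expect_true(v$accepted)
  # accepted contour hugs the analytic skin circle at this slice's z
  z <- spec$origin_mm[3] + mid$index * spec$spacing_mm[3]
  r_z <- sqrt(25^2 - z^2)
  ctr_px <- c((0 - spec$origin_mm[2]) / spec$spacing_mm[2],
              (0 - spec$origin_mm[1]) / spec$spacing_mm[1])
  rad <- sqrt((v$contour$points[, 1] - ctr_px[1])^2 +
                (v$contour$points[, 2] - ctr_px[2])^2)
  expect_lt(max(abs(rad - r_z)), 1.6)

  # ring broken at the top + inner structure: the pixel connection restores
  # the outer ring, so the largest contour encloses the full head again
  ring <- disk_mask(100, 100, 50, 50, 30)
  ring[disk_mask(100, 100, 50, 50, 24) == 255L] <- 0L
  ring[disk_mask(100, 100, 50, 50, 15) == 255L] <- 255L  # "brain"
  broken <- ring
  broken[1:30, 48:52] <- 0L                  # gap at the top of the ring
  class(broken) <- c("binary_mask", class(broken))
  raw_largest <- extract_contours(broken)[[1]]
  vb <- validate_slice(broken)
  expect_true(vb$accepted)
  expect_gt(vb$area_px, pi * 28^2)           # encloses the disk, not the band
  expect_gt(vb$area_px, raw_largest$area_px) # connection grew the contour

  # all-air slice
  air <- matrix(0L, 50, 50)
  class(air) <- c("binary_mask", class(air))
  expect_equal(validate_slice(air)$reason, "no_contour")

  # verdicts are deterministic
  expect_identical(validate_slice(broken), validate_slice(broken))
})

test_that("solidity of rasterized convex shapes stays near 1 and in (0, 1]", {
  for (r in c(10, 20, 35)) {
    ct <- extract_contours(disk_mask(90, 90, 45, 45, r))[[1]]
    s <- contour_solidity(ct)
    expect_true(s > 0.9 && s <= 1)   # staircase rasterization cost
  }
})
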