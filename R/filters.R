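#' Configuration of the contour-validity filter chain
#'
#' Bundles every tunable of the five slice filters. Box-like parameters
#' (`centroid_valid_box`, `equipment_regions`) are expressed as fractional
#' image rectangles `c(row_min, row_max, col_min, col_max)` in `[0, 1]` of
#' the image extent, so one configuration applies across plane geometries
#' and image sizes; they are converted to pixel rectangles per image.
#'
#' Defaults:
#' * `centroid_valid_box`: centroid must lie in the central 80% of columns
#'   and the upper 90% of rows, so head centroids pass while equipment
#'   below/beside the head fails.
#' * `solidity_threshold 0.88`, tested only for contours with enclosed area
#'   strictly greater than `solidity_min_area_px = 40000` pixels (large,
#'   nominally round head cross-sections).
#' * `area_delta_trigger 0.15`: the four-direction scan runs when the
#'   contour area jumps by more than 15% relative to the previous slice of
#'   the same plane, the signature of a misidentified largest contour;
#'   consecutive sub-millimeter head slices change area slowly.
#' * row-crossing filter: rows scanned in steps of 4, contour pixels count
#'   when at least 4 columns from the last counted one, a row is bad from
#'   4 such pixels, and the slice is excluded when more than 4 rows are bad.
#' * `equipment_regions`: one full-width band over the bottom 12% of rows.
#'
#' @param centroid_valid_box fractional rectangle the candidate contour's
#'   centroid must fall in.
#' @param solidity_threshold minimum accepted solidity, in (0, 1].
#' @param solidity_min_area_px area gate (pixels) above which solidity is
#'   tested.
#' @param area_delta_trigger relative area change versus the previous
#'   slice beyond which the four-direction scan is run.
#' @param row_step row stride of the row-crossing filter (pixels).
#' @param min_pixel_gap minimum column gap between counted contour pixels.
#' @param crossings_per_row_trigger counted pixels per row that mark the
#'   row as bad.
#' @param bad_row_limit bad-row count above which the slice is excluded.
#' @param equipment_regions list of fractional rectangles checked for any
#'   foreground pixel.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(centroid_valid_box = c(0, 0.90, 0.10, 0.90),
                          solidity_threshold = 0.88,
                          solidity_min_area_px = 40000,
                          area_delta_trigger = 0.15,
                          row_step = 4L,
                          min_pixel_gap = 4L,
                          crossings_per_row_trigger = 4L,
                          bad_row_limit = 4L,
                          equipment_regions = list(c(0.88, 1, 0, 1))) {
  if (solidity_threshold <= 0 || solidity_threshold > 1)
    stop("solidity_threshold must be in (0, 1]")
  counts <- c(row_step, min_pixel_gap, crossings_per_row_trigger,
              bad_row_limit)
  if (any(counts <= 0)) stop("filter counts must be positive")
  structure(list(centroid_valid_box = centroid_valid_box,
                 solidity_threshold = solidity_threshold,
                 solidity_min_area_px = solidity_min_area_px,
                 area_delta_trigger = area_delta_trigger,
                 row_step = as.integer(row_step),
                 min_pixel_gap = as.integer(min_pixel_gap),
                 crossings_per_row_trigger =
                   as.integer(crossings_per_row_trigger),
                 bad_row_limit = as.integer(bad_row_limit),
                 equipment_regions = equipment_regions),
            class = "filter_config")
}

verdict <- function(reason, contour = NULL, area_px = NA_real_,
                    solidity = NA_real_) {
  structure(list(accepted = identical(reason, "ok"), reason = reason,
                 contour = contour, area_px = area_px, solidity = solidity),
            class = "slice_verdict")
}

#' @export
print.slice_verdict <- function(x, ...) {
  cat("<slice_verdict> ", if (x$accepted) "accepted" else "rejected",
      " (", x$reason, ")\n", sep = "")
  invisible(x)
}

# fractional rectangle -> 1-based pixel index ranges for an image of dims d
frac_rect_to_px <- function(rect, d) {
  list(rows = max(1L, floor(rect[1] * d[1]) + 1L):min(d[1],
                                                      ceiling(rect[2] * d[1])),
       cols = max(1L, floor(rect[3] * d[2]) + 1L):min(d[2],
                                                      ceiling(rect[4] * d[2])))
}

#' Centroid gate: reject slices whose candidate contour sits off-head
#'
#' The largest contour is the outer-skin candidate; when its center of mass
#' falls outside the configured fractional rectangle the slice is excluded
#' as equipment-dominated.
#'
#' @param contours nonempty list from [extract_contours()] (sorted).
#' @param cfg a [filter_config()].
#' @param image_shape `c(rows, cols)` of the mask.
#' @return A `slice_verdict` with reason `"ok"` or
#'   `"centroid_out_of_range"`.
#' @export
centroid_gate <- function(contours, cfg, image_shape) {
  stopifnot(length(contours) > 0L)
  cen <- contours[[1]]$centroid_px
  fr <- cen[1] / (image_shape[1] - 1)
  fc <- cen[2] / (image_shape[2] - 1)
  b <- cfg$centroid_valid_box
  if (fr < b[1] || fr > b[2] || fc < b[3] || fc > b[4])
    return(verdict("centroid_out_of_range",
                   area_px = contours[[1]]$area_px))
  verdict("ok", contours[[1]], area_px = contours[[1]]$area_px)
}

#' Connect the first foreground row of a mask
#'
#' In the topmost row containing any foreground pixel, all pixels between
#' the first and the last foreground pixel are set to foreground. This
#' restores the closure of a skin ring broken by intracranial noise so the
#' outer contour again encloses the whole head; no other pixel is touched.
#' The modified row index (0-based) is recorded in the
#' `"connection_row"` attribute for later removal by
#' [strip_connection_row()].
#'
#' @param mask a `binary_mask`.
#' @return The mask, possibly with one row edited; identity (attribute
#'   `NA`) when the mask has no foreground.
#' @export
connect_first_row <- function(mask) {
  as_mask_matrix(mask)
  rows <- which(rowSums(mask == 255L) > 0L)
  if (length(rows) == 0L) {
    attr(mask, "connection_row") <- NA_integer_
    return(mask)
  }
  r <- rows[1]
  cc <- range(which(mask[r, ] == 255L))
  mask[r, cc[1]:cc[2]] <- 255L
  attr(mask, "connection_row") <- r - 1L
  mask
}

#' Remove contour points lying on the connection row
#'
#' The pixel-connection line of [connect_first_row()] is synthetic data, so
#' the contour points on that row are deleted before 3D projection;
#' remaining points keep their order and the cached area/centroid of the
#' full contour are retained (the stripped point list is not a closed
#' polygon).
#'
#' @param contour a `ct_contour`.
#' @param row_index 0-based connection row (NA for no-op).
#' @return The stripped `ct_contour`, or `NULL` when fewer than 3 points
#'   remain (the caller rejects the slice with `no_contour`).
#' @export
strip_connection_row <- function(contour, row_index) {
  if (is.na(row_index)) return(contour)
  keep <- contour$points[, 1] != row_index
  if (sum(keep) < 3L) return(NULL)
  contour$points <- contour$points[keep, , drop = FALSE]
  contour
}

#' Solidity filter for large contours
#'
#' For contours whose enclosed area exceeds `solidity_min_area_px`,
#' solidity (contour area / convex hull area) below `solidity_threshold`
#' indicates intracranial noise distorting the skin boundary and the slice
#' is excluded. Smaller contours are not tested.
#'
#' @param contour a `ct_contour`.
#' @param cfg a [filter_config()].
#' @return A `slice_verdict` with reason `"ok"` or `"low_solidity"`; the
#'   computed solidity is reported in the `solidity` field when tested.
#' @export
solidity_check <- function(contour, cfg) {
  if (contour$area_px <= cfg$solidity_min_area_px)
    return(verdict("ok", contour, area_px = contour$area_px))
  s <- contour_solidity(contour)
  if (!is.finite(s) || s < cfg$solidity_threshold)
    return(verdict("low_solidity", area_px = contour$area_px, solidity = s))
  verdict("ok", contour, area_px = contour$area_px, solidity = s)
}

#' Four-direction scan for foreground outside the largest contour
#'
#' Triggered when the contour area changes by more than
#' `area_delta_trigger` (relative) versus the previous slice of the same
#' plane - the signature of a largest contour misidentified after a
#' discontinuity that excluded a significant portion of the region. Casts
#' single-pixel rays from the contour centroid along +/-row and +/-col; if
#' any foreground pixel on a ray lies outside the contour polygon (and is
#' not a boundary pixel), the true skin region was not enclosed and the
#' slice is discarded. Not triggered for the first slice of a plane (no
#' reference area).
#'
#' @param mask the (connected) `binary_mask` the contour was traced from.
#' @param contour the largest `ct_contour`.
#' @param prev_area_px largest-contour area of the previous slice
#'   (regardless of its verdict), or `NULL`.
#' @param cfg a [filter_config()].
#' @return A `slice_verdict` with reason `"ok"` or `"four_direction_fail"`.
#' @export
four_direction_check <- function(mask, contour, prev_area_px, cfg) {
  ok <- verdict("ok", contour, area_px = contour$area_px)
  if (is.null(prev_area_px)) return(ok)
  if (abs(contour$area_px - prev_area_px) / prev_area_px <=
      cfg$area_delta_trigger)
    return(ok)
  d <- dim(mask)
  r0 <- round(contour$centroid_px[1]); c0 <- round(contour$centroid_px[2])
  if (r0 < 0 || r0 > d[1] - 1 || c0 < 0 || c0 > d[2] - 1)
    return(verdict("four_direction_fail", area_px = contour$area_px))
  ray <- rbind(cbind(r0, 0:(d[2] - 1L)), cbind(0:(d[1] - 1L), c0))
  white <- mask[ray[, 1] + ray[, 2] * d[1] + 1L] == 255L
  ray <- ray[white, , drop = FALSE]
  if (nrow(ray) == 0L) return(ok)
  conkey <- contour$points[, 1] * d[2] + contour$points[, 2]
  onb <- (ray[, 1] * d[2] + ray[, 2]) %in% conkey
  cand <- ray[!onb, , drop = FALSE]
  if (nrow(cand) == 0L) return(ok)
  if (any(!points_in_polygon(cand, contour$points)))
    return(verdict("four_direction_fail", area_px = contour$area_px))
  ok
}

#' Row-crossing (pixel-counting) filter
#'
#' Iterates over image rows in steps of `row_step` and counts, per scanned
#' row, the contour pixels separated by at least `min_pixel_gap` columns
#' from the last counted one. Rows reaching `crossings_per_row_trigger`
#' such pixels increment a bad-row counter; the slice is excluded when the
#' counter exceeds `bad_row_limit`. A valid convex skin boundary crosses
#' each row at most twice, while residual noise in anatomically complex
#' regions (ears, nose) produces many well-separated crossings.
#'
#' @param contour a `ct_contour` (boundary pixels are counted, not filled
#'   region pixels).
#' @param image_shape `c(rows, cols)` of the mask.
#' @param cfg a [filter_config()].
#' @return A `slice_verdict` with reason `"ok"` or `"row_crossing_fail"`.
#' @export
row_crossing_check <- function(contour, image_shape, cfg) {
  scan_rows <- seq(0L, image_shape[1] - 1L, by = cfg$row_step)
  pts <- contour$points[contour$points[, 1] %in% scan_rows, , drop = FALSE]
  bad <- 0L
  if (nrow(pts) > 0L) {
    for (cols in split(pts[, 2], pts[, 1])) {
      cols <- sort(cols)
      cnt <- 1L
      last <- cols[1]
      for (cc in cols[-1]) {
        if (cc - last >= cfg$min_pixel_gap) {
          cnt <- cnt + 1L
          last <- cc
        }
      }
      if (cnt >= cfg$crossings_per_row_trigger) bad <- bad + 1L
    }
  }
  if (bad > cfg$bad_row_limit)
    return(verdict("row_crossing_fail", area_px = contour$area_px))
  verdict("ok", contour, area_px = contour$area_px)
}

#' Equipment-region check
#'
#' Rejects the slice iff any foreground pixel falls inside one of the
#' configured regions, which mark where medical equipment (scanner table,
#' head holder) is expected and the head never is.
#'
#' @param mask a `binary_mask` (the raw mask, before pixel connection).
#' @param cfg a [filter_config()].
#' @return A `slice_verdict` with reason `"ok"` or
#'   `"equipment_region_hit"`.
#' @export
equipment_region_check <- function(mask, cfg) {
  d <- dim(mask)
  for (rect in cfg$equipment_regions) {
    px <- frac_rect_to_px(rect, d)
    if (any(mask[px$rows, px$cols] == 255L))
      return(verdict("equipment_region_hit"))
  }
  verdict("ok")
}

#' Run the full slice-validity filter chain
#'
#' Orchestrates, in fixed order: contour detection, centroid gate, largest
#' contour selection, first-row pixel connection, re-detection and largest
#' contour selection, connection-row stripping, solidity filter,
#' area-delta-triggered four-direction scan, row-crossing filter and
#' equipment-region check. The first rejection wins; otherwise the
#' validated outer-skin contour (with the connection row stripped) is
#' returned for 3D projection. Rejection verdicts still report the
#' largest-contour area (`area_px`) so the caller can carry it as the
#' area-delta reference for the next slice.
#'
#' @param mask a `binary_mask` from [binarize_slice()].
#' @param prev_area_px largest-contour area of the previous slice of the
#'   same plane (whatever its verdict), or `NULL` for the first slice.
#' @param cfg a [filter_config()].
#' @return A `slice_verdict`; when accepted, `$contour` holds the
#'   validated contour and `$area_px` the enclosed area to carry to the
#'   next slice.
#' @export
validate_slice <- function(mask, prev_area_px = NULL, cfg = filter_config()) {
  contours <- extract_contours(mask)
  if (length(contours) == 0L) return(verdict("no_contour"))
  vg <- centroid_gate(contours, cfg, dim(mask))
  if (!vg$accepted) return(vg)
  connected <- connect_first_row(mask)
  conn_row <- attr(connected, "connection_row")
  contours2 <- extract_contours(connected)
  if (length(contours2) == 0L) return(verdict("no_contour"))
  largest <- contours2[[1]]
  stripped <- strip_connection_row(largest, conn_row)
  if (is.null(stripped)) return(verdict("no_contour"))
  vs <- solidity_check(largest, cfg)
  if (!vs$accepted) return(vs)
  vf <- four_direction_check(connected, largest, prev_area_px, cfg)
  if (!vf$accepted) return(vf)
  vr <- row_crossing_check(largest, dim(mask), cfg)
  if (!vr$accepted) return(vr)
  ve <- equipment_region_check(mask, cfg)
  if (!ve$accepted) {
    ve$area_px <- largest$area_px
    return(ve)
  }
  verdict("ok", stripped, area_px = largest$area_px,
          solidity = vs$solidity)
}
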