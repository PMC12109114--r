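#' Hounsfield-unit threshold range
#'
#' The default band `[-200, +220]` HU isolates skin and other soft tissue:
#' air (~ -1000 HU) and bone (>> +220 HU) fall outside it. Both endpoints
#' are included (closed interval).
#'
#' @param hu_min,hu_max band limits in HU, `hu_min <= hu_max`.
#' @return An object of class `hu_range`.
#' @export
hu_range <- function(hu_min = -200, hu_max = 220) {
  if (hu_min > hu_max) stop("hu_min must be <= hu_max")
  structure(list(hu_min = hu_min, hu_max = hu_max), class = "hu_range")
}

#' Binarize an HU slice by in-range thresholding
#'
#' A pixel becomes foreground (255) iff `hu_min <= value <= hu_max`, else
#' background (0). No morphology or smoothing is applied anywhere in the
#' pipeline: the mask is the raw thresholded data, preserving the original
#' anatomical boundaries.
#'
#' @param slice a `planar_slice` from [reslice()], or a plain HU matrix.
#' @param range an [hu_range()].
#' @return A `binary_mask`: integer matrix of 0/255 with provenance
#'   attributes `orientation` and `index`.
#' @export
binarize_slice <- function(slice, range = hu_range()) {
  px <- if (inherits(slice, "planar_slice")) slice$pixels else slice
  m <- matrix(0L, nrow(px), ncol(px))
  m[px >= range$hu_min & px <= range$hu_max] <- 255L
  structure(m, class = c("binary_mask", class(m)),
            orientation = if (inherits(slice, "planar_slice"))
              slice$orientation else NA_character_,
            index = if (inherits(slice, "planar_slice"))
              slice$index else NA_integer_)
}

as_mask_matrix <- function(mask) {
  if (!all(mask %in% c(0L, 255L)))
    stop("binary mask must contain only 0 and 255")
  mask
}
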