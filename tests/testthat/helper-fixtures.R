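# Shared fixtures, all generated in code.

# small sphere head for fast end-to-end runs
small_sphere_spec <- function(with_artifacts = FALSE) {
  sphere_phantom_spec(radius_mm = 25, spacing_mm = c(1, 1, 1.25),
                      with_artifacts = with_artifacts)
}

# asymmetric head: rotation is observable, used for registration tests
ellipsoid_spec <- function() {
  phantom_spec(grid_shape = c(40, 40, 40), spacing_mm = c(2, 2, 2),
               origin_mm = c(-40, -40, -40),
               skin_semiaxes_mm = c(28, 36, 32),
               skull_semiaxes_mm = c(22, 30, 26),
               brain_semiaxes_mm = c(18, 26, 22))
}

# filled disk mask (0/255), 1-based center, for contour fixtures
disk_mask <- function(nr, nc, cr, cc, radius) {
  m <- matrix(0L, nr, nc)
  rr <- row(m) - cr
  ccx <- col(m) - cc
  m[rr^2 + ccx^2 <= radius^2] <- 255L
  class(m) <- c("binary_mask", class(m))
  m
}

rect_mask_set <- function(m, r1, r2, c1, c2) {
  m[r1:r2, c1:c2] <- 255L
  m
}

# comb-shaped mask: n_teeth vertical teeth on a base bar
comb_mask <- function(nr, nc, n_teeth, tooth_rows, tooth_w = 2L, gap = 6L) {
  m <- matrix(0L, nr, nc)
  start <- 5L
  for (i in seq_len(n_teeth)) {
    c1 <- start + (i - 1L) * (tooth_w + gap)
    m[5:(4L + tooth_rows), c1:(c1 + tooth_w - 1L)] <- 255L
  }
  last <- start + (n_teeth - 1L) * (tooth_w + gap) + tooth_w - 1L
  m[(5L + tooth_rows):(8L + tooth_rows), start:last] <- 255L  # base bar
  class(m) <- c("binary_mask", class(m))
  m
}

rotation_error_rad <- function(Ra, Rb) {
  acos(min(1, max(-1, (sum(diag(Ra %*% t(Rb))) - 1) / 2)))
}

inverse_transform <- function(tr) {
  rigid_transform(t(tr$rotation),
                  -as.numeric(t(tr$rotation) %*% tr$translation))
}
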