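---
title: "Triplanar skin-surface reconstruction from head CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triplanar skin-surface reconstruction from head CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Markerless image-guided surgery registers a preoperative CT-derived model
of the patient's skin surface against intraoperative 3D-camera data. The
registration is only as good as the surface model, and two failure modes
dominate: (i) meshing algorithms interpolate across voxels and smooth away
true anatomy, and (ii) anything in the scanner's field of view with
soft-tissue attenuation — table, head holder, dressings, fiducial stickers
— segments together with the skin.

`ct2skin` therefore builds the surface as a *point cloud of raw boundary
pixels*. Each of the three anatomical planes (axial, sagittal, coronal) is
processed independently: slices are binarized by in-range HU thresholding,
the outer contour of the largest foreground region is validated by a chain
of filters, and the surviving contour pixels are projected into world
millimeters through the affine DICOM geometry

\[ w = o + (i_x, i_y, i_z) \cdot (s_x, s_y, s_z), \]

where \(o\) is the volume origin and \(s\) the voxel spacing. The three
uniplanar clouds are fused by geometric addition with a two-stage voxel
downsampling (once per plane, once after merging). Because sagittal and
coronal slices sample the cranial vertex and skull base at in-plane
resolution — typically finer than the axial slice spacing — the fused
"triplanar" cloud recovers the polar regions that axial slicing
undersamples.

No morphology, smoothing or interpolation is applied anywhere: every
output point is the center of an actual thresholded image pixel. Reslicing
is implemented as an axis permutation of the loaded voxel grid, which is
exactly equivalent to slicing with axis-aligned transformation matrices
but introduces no resampling error. Gantry-tilted and oblique series are
rejected rather than resampled.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| HU band | [−200, +220] | HU | isolates soft tissue; closed on both ends |
| solidity threshold | 0.88 | – | contour area / convex hull area |
| solidity area gate | > 40 000 | px | only large, nominally round sections are tested |
| area-delta trigger | 0.15 | relative | arms the four-direction scan |
| row-crossing | step 4, gap 4, trigger 4, limit 4 | px / rows | crowded-row detector |
| centroid box | rows [0, 0.90], cols [0.10, 0.90] | image fraction | candidate centroid must fall inside |
| equipment regions | bottom 12% of rows | image fraction | any foreground rejects the slice |
| downsampling voxel | 1.0 (alt. 0.38) | mm | both stages share one value |
| outlier removal | radius 2 mm / 4 neighbors; k = 20, ratio 2.0 | mm / counts | density pass, then statistical pass |
| ICP | rms Δ 1e−4 mm, overlap 0.90 | mm / fraction | trimmed point-to-point, closed-form update |

The HU interval is treated as closed on both endpoints; with integer CT
data the distinction is invisible, and the symmetric contract is the
simplest to state and test. Both binarization bounds are configurable
(`hu_range()`, CLI flags `--hu-min/--hu-max`).

The centroid and equipment boxes are stored as *fractions* of the image
extent rather than pixel rectangles: one configuration must serve three
plane geometries whose pixel dimensions differ, and the natural
definitions ("bottom 12% of rows", "central 80% of columns") are
fractional to begin with. They are converted to pixel rectangles per
image.

## The filter chain, in processing order

1. **Contour detection.** Connected foreground regions are labelled and
   their outer boundaries traced (holes ignored). Contours are ordered by
   enclosed shoelace area, ties broken by topmost-leftmost start pixel, so
   the "largest contour" is deterministic.
2. **Centroid gate.** If the largest contour's center of mass falls
   outside the valid box, the slice is equipment-dominated and dropped.
3. **Pixel connection.** Intracranial air (sinuses, surgical cavities) can
   break the skin ring so that the outer boundary no longer encloses the
   head. A line drawn between the first and last foreground pixels of the
   topmost foreground row restores closure; contours are re-extracted, and
   the synthetic row is deleted from the contour again before projection
   so no fabricated pixel is ever exported.
4. **Solidity.** Large head sections are nominally convex; solidity
   below 0.88 on a section larger than 40 000 px signals a contour
   distorted by internal noise. The area gate uses strict inequality
   (area must *exceed* the gate).
5. **Four-direction scan.** Armed only when the contour area changes by
   more than 15% relative to the previous slice — the signature of a
   largest contour misidentified after a discontinuity that cut away a
   significant part of the region. Single-pixel rays from the centroid
   along ±row and ±col must find no foreground outside the contour
   polygon. Two design points deserve explanation:
   * *Trigger direction.* The scan arms on a *large* area jump. Arming on
     stable areas instead would run the scan on every ordinary mid-head
     slice, where any coexisting equipment pixel on a cardinal ray —
     a scanner table sits below the head in essentially every slice of a
     real scan — would discard the entire stack. A large jump is both the
     failure signature the filter exists for and the only arming rule
     under which equipment-bearing but correctly-contoured slices survive.
   * *Reference area.* The reference is the previous slice's
     largest-contour area regardless of that slice's verdict (slices with
     no contour leave it unchanged). Carrying only accepted areas lets one
     rejection freeze the reference, keeping the trigger armed and
     cascading the rejection through the rest of the plane.
6. **Row-crossing count.** Residual noise in anatomically intricate
   regions (ear, nose) produces many well-separated boundary pixels per
   image row, where a valid convex section crosses a row at most twice.
   Boundary pixels (not filled-region pixels) are counted every 4th row;
   pixels closer than 4 columns to the last counted one are merged. This
   is implemented as one global parameterized filter; region-restricted
   variants are expressible through configuration rather than hard-coded
   ear/nose instances.
7. **Equipment regions.** A final hard veto: any foreground pixel inside a
   configured region rejects the slice.

The verdict for every slice (plane, index, reason) is returned as a QC
data frame and exportable as CSV/JSON.

## Fusion and outlier removal

The axial plane is acquired natively and carries the fewest external
artifacts, so the axial cloud's componentwise min/max box defines the
acceptable coordinate range; sagittal and coronal points outside it
(table, head holder) are clipped before their own downsampling. The
downsampling representative is the *centroid* of each occupied cell —
the common convention, and configurable in principle since the
alternative (point nearest the cell center) differs negligibly at 1 mm
cells. The grid is anchored at the cloud's componentwise minimum, which
makes the operation deterministic and order-independent (set semantics)
at the cost of an arbitrary but documented grid phase.

Outlier removal runs density-then-statistical: first points with fewer
than 4 neighbors within 2 mm are dropped (at 1 mm cell size a surface
point has ~12 such neighbors), then points whose mean distance to their
20 nearest neighbors exceeds the global mean by 2 standard deviations.
The second pass trims the extreme tail of the neighbor-distance
distribution — a few percent even on clean surfaces, which is the
standard behavior of statistical outlier filters and harmless to surface
accuracy; isolated noise ten or more cells away is removed with
certainty.

## The phantom generator

The generator emulates exactly the features the pipeline is sensitive to:

* concentric ellipsoidal layers (air −1000 / skin +40 / skull +700 /
  brain +30 HU) straddling the threshold band, so binarization produces a
  skin ring around a background skull shell around a foreground brain;
* anisotropic spacing with non-zero origin (finer in-plane than across
  slices, so the poles are axially undersampled);
* a scanner-table slab below the head, in soft-tissue HU;
* fiducial spheres centered on the skin surface;
* an intracranial air cavity breaking ring closure at the crown;
* an optional nose-like protrusion.

Voxels are classified at their centers — the same convention thresholding
applies later — so the outer ellipsoid is an exact analytic ground truth.
Artifact geometry is idealized (boxes and spheres); real headrests,
dressings and CT reconstruction-kernel noise textures are *not* modeled.
Passing phantom tests therefore demonstrates the geometric correctness of
the chain and its artifact-rejection mechanics, not robustness to
scanner-specific noise or true anatomy; the filter defaults ("heuristic"
in origin) may need retuning per scanner protocol.

The phantom is written as a real single-frame CT DICOM series (Explicit
VR Little Endian, one file per slice, unsigned 16-bit pixels with rescale
slope/intercept carrying the HU mapping, monotone slice positions) so the
production reader is exercised; a YAML sidecar records the analytic
surface. The reader applies the rescale, orders slices by world position,
derives slice spacing from inter-slice gaps, and rejects mixed series,
missing geometry tags and gaps non-uniform beyond 1e-3 mm.

## Numerical choices

* **Nearest point on a triaxial ellipsoid** (ground-truth distances) has
  no closed form; the Lagrange stationarity condition is solved per point
  by 100 bisection steps on the bracketed largest root followed by Newton
  polishing, giving surface residuals below 1e−9 mm. Spheres use the
  exact closed form. Exactly-on-center points return the smallest
  semi-axis; points with zero components are perturbed by 1e−12 mm to
  keep the root well-defined (error far below measurement scale).
* **Rigid ICP update** uses the closed-form orthogonal-Procrustes
  solution (SVD with determinant correction) on the trimmed
  correspondence set; per-iteration trimming to the 90% closest
  correspondences implements farthest-point removal. Convergence is
  declared when the RMS improves by less than 1e−4 mm. Rank-deficient
  cross-covariance (collinear geometry) is an error, not a silent
  fallback. Source subsampling above `max_samples` is seeded.
* **Uniqueness and coverage** use closed-ball semantics (a neighbor at
  exactly the search radius disqualifies a point); the radius endpoint
  convention is stated because counts change with it at lattice spacings.
* **Solidity** is computed on the traced boundary polygon (shoelace area
  over convex-hull area); it equals 1 exactly on convex polygons, and
  slightly less on rasterized disks due to staircase corners — the 0.88
  threshold is far from this rasterization cost.
* The sagittal/coronal image convention places the volume's z-axis along
  image rows, negated so row 0 is the cranial end (head upright). The
  choice is recorded per slice (`row_axis`, `col_axis`) and consumed by
  the projection, making the mapping exactly invertible (round-trip error
  0 by construction in floating point below 1e−9 mm).

## Scale of the shipped verification

The test suite runs the full pipeline end-to-end at two scales, chosen as
a compromise between realism and a test run of a few minutes: a 25 mm
sphere at 1 × 1 × 1.25 mm spacing for fast module-level checks, and the
full evaluation phantom — a 60 mm sphere at 0.5 × 0.5 × 0.625 mm
(≈ 23 M voxels, written and re-read as a 239-slice DICOM series) — for
the accuracy, enrichment and artifact-rejection checks, asserting RMS
within half the largest voxel dimension at 1 mm downsampling and within
0.38 mm at 0.38 mm downsampling. Brute-force O(n²) oracles validate every
neighbor-search-based operation on subsamples of ≤ 2000 points.

## Known limitations

* Only axis-aligned, single-frame, explicit-VR-little-endian CT DICOM is
  read; enhanced multi-frame files, compressed transfer syntaxes and
  gantry-tilted series are rejected by design.
* Filter parameters are static; anatomically unusual patients or
  non-soft-tissue kernels may need different thresholds.
* The four-direction scan is blind to foreground that avoids all four
  cardinal rays (documented by a dedicated test).
* Slices rejected by the chain are dropped wholesale; regions visible
  only in rejected slices (ears, nasal tip in complex anatomies) are
  absent from the cloud, which coverage fields make visible.
* Rotation recovery by ICP is ill-posed on rotationally symmetric
  surfaces (spheres); pose-recovery checks use an asymmetric ellipsoid.
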