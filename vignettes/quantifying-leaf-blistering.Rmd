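---
title: "Quantifying leaf blistering and plant morphology from 3D point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leaf blistering and plant morphology from 3D point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafscan)
```

## The problem

Plant variety testing scores many leaf characteristics by eye on ordinal
scales — among them *blistering*, the puckered relief of a lettuce lamina,
and the *size of blisters*. Human scoring is slow and ambiguous. Given a
segmented, high-density 3D point cloud of a single plant or leaf
(millimetre coordinates, +z up), `leafscan` turns both the ruler traits and
these visual traits into numbers:

* **Dimensional traits** — plant height, major/minor diameter viewed from
  above, vertical projected area.
* **Volume estimators** — axis-aligned bounding box, 3D convex hull,
  columnar solid (bounding-box height × footprint area) and voxel volume,
  plus **compactness** = voxel volume / hull volume.
* **Local curvature (LC)** — a bounded per-point statistic of normal-vector
  dispersion that maps blistering to a 0–1 scale, summarised by the
  LC-histogram centroid (LCg) and the smooth-area fraction.

Everything is testable without a scanner: the synthetic module generates
tilted plates, blistered laminae, known-volume solids and mock rosettes
with analytic ground truth.

## Normal estimation

The normal at a point is the unit normal of a least-squares plane fitted to
its neighbourhood. On *organized* clouds (stored as a rows × cols raster,
the native output of a turntable scanner) the neighbourhood is the
`window × window` raster block, clipped at borders; on unorganized clouds
it is the `window`² Euclidean-nearest points (k-d tree via RANN). Three
ordinary-least-squares plane forms exist — z on (x, y), y on (x, z), x on
(y, z) — and each is ill-conditioned when the surface is parallel to its
dependent axis. `fit_plane()` therefore picks the dependent axis with the
largest absolute component of a provisional total-least-squares normal
(smallest principal direction of the centred neighbourhood), then solves
the ordinary LSQ form. The fitted normal's sign is arbitrary, so normals
are oriented into the +z hemisphere (plants are scanned upright; an
upward-facing leaf is (0, 0, 1), rendered blue by the normal colour map).

Degenerate neighbourhoods (collinear points, under-filled border windows
with fewer than 4 points) inherit the nearest valid normal rather than NaN,
so downstream curvature windows stay full; the count is reported.

The default window is 7 (the largest of the customary 3/5/7 sizes) — a good
compromise on smooth laminae. For very fine relief a 3×3 window preserves
more normal dispersion; the blister-sweep analysis below uses it
deliberately.

One caveat shown by the tests: on *curved* neighbourhoods the fitted plane
depends (at second order) on which axis form is solved, so normals on
curved patches are rotation-equivariant only to about a degree, not to
machine precision; on exact planes equivariance is exact.

## Local curvature and its summaries

For each point, LC is computed over a second (larger, default 15 × 15)
neighbourhood of the *oriented* normals:

LC = sqrt(s_nx² + s_ny² + s_nz²),

with s the **population** standard deviation of each normal component.
Population rather than sample SD matters: for unit vectors the summed
population variance is exactly 1 − ‖mean normal‖², so LC is bounded in
[0, 1] and the identity provides a machine-precision oracle (it holds to
1e-12 in the tests). Sample SD would exceed 1 on tiny windows. Orientation
is applied before LC, otherwise arbitrary sign flips would inflate the
dispersion of a perfectly smooth surface.

LC values are binned over [0, 1] in right-open bins of width 0.05 (last bin
closed, values ≥ 1 included). Two summaries follow:

* **LCg**, the histogram centroid: Σ(midpoint × frequency) / Σ frequency.
  The defining sum runs over histogram frequencies, so we compute it over
  bin midpoints; the raw mean LC is also reported (`lc_mean`) as a
  diagnostic. For a flat surface every LC is 0 and LCg equals the lowest
  bin midpoint (0.025) — the centroid's floor, not zero.
* **Smooth fraction**: the share of points with LC < 0.5, the blue-green
  region of the heatmap, a proxy for the size of the blisters' flat tops.

Masks (manually cut-out laminae, excluding midrib and margin) are applied
*before* normal estimation, so excluded points never contaminate windows —
incomplete margin removal is the known failure mode of the blister score.

LC measures the *amount* of convexity/concavity, not its orientation:
distinguishing convex from concave blisters would need the signed normals
and is out of scope.

## Volumes, compactness, dimensions

The bounding box is axis-aligned with z up: height must be readable off a
box side, so a minimum-volume oriented box is deliberately not used. The
convex hull is computed exactly by a quickhull implementation in C++
(volumes match analytic solids to machine precision; a 50k-point sphere
surface is within 0.03 % of 4/3·π·r³). The voxel grid
(`floor(coord / 0.5 mm)`) is anchored at the world origin, so volumes are
translation-sensitive at sub-voxel scale (± one voxel layer). Occupancy
voxelization of a dense solid *overshoots* the true volume by roughly half
a voxel layer of surface, a relative error of about 1.5 · voxel / r for a
ball of radius r: ~5 % at r = 10 mm and ~1.9 % at r = 30 mm with the
default 0.5 mm voxel. This bias is intrinsic to occupancy counting, and is
why the volume-oracle ball in the acceptance checks is lettuce-sized
(r = 30 mm). On real surface scans the voxel volume measures the leaf
shell, which is exactly what compactness wants: voxel/hull separates a
dense head (→ 1) from an open rosette (≪ 1).

The projected area rasterizes the x–y projection at the voxel size; the
raster over-covers the true footprint by up to one boundary ring of cells
(the relevant tolerance in all footprint tests). The minor diameter is the
minimal width of the projected convex hull — the smallest distance between
two parallel supporting lines — rather than any centroid-constrained
caliper, because that is what a ruler measures across a rosette's narrow
side and it is exactly rotation-invariant. The major diameter is the hull
diameter. Both are checked against an exhaustive direction-scan oracle at
0.1° steps.

## The tilted-plate angle benchmark

`estimate_region_angles()` reproduces the scanner-accuracy protocol: a flat
plate at a known tilt is scanned, the cloud is divided into 1/5/10 mm
squares on the x–y plane, a plane is fitted per cell, and the mean and SD
of the per-cell angles are reported. Design choices that matter:

* **Signed angle.** The default angle is the signed tilt about the y axis
  (atan of the fitted x-slope). An unsigned angle `acos(|nz|)` is folded at
  0°, so its mean on a noisy horizontal plate is biased upward by the full
  noise scale; a signed estimator is unbiased at every tilt (and small
  *negative* mean estimates at 0° are possible, as real benches report).
  `signed = FALSE` gives the unsigned tilt for arbitrary surfaces.
* **Depth-axis fit.** Cells are fitted with z as the dependent variable.
  The noise of a depth scanner lives in z; regressing a noisy coordinate on
  clean ones is the unbiased direction, whereas letting the axis selection
  regress x on a noisy z at steep tilts attenuates the slope
  (errors-in-variables) by far more than the benchmark tolerance.
* **Full cells only.** Cells whose point span covers less than half the
  cell in x or y (slivers at the plate edge) are excluded; a sliver's tiny
  lever arm makes its angle estimate wild and it would dominate the SD.

Bench conditions in the tests: 100 × 100 mm plate, 0.1 mm grid spacing
(emulating a high-density scan), 0.3 mm Gaussian depth noise. A bias
analysis (angle bias ∝ spacing² · noise²/tan-curvature) fixed the spacing
before any test was run: at 0.1 mm the worst per-cell-size mean error is
≲ 0.2°, and the SD ordering 1 mm > 5 mm > 10 mm holds at every tilt in
{0, 15, 30, 45, 60}°.

## What the synthetic scans emulate — and what they do not

* `make_tilted_plate()` — the benchmark plate: an organized grid rotated
  about y (`z = tan(tilt)·x`), Gaussian **depth** noise. Noise is applied
  to z only; a turntable scanner's lateral sample positions come from the
  raster, its error is in depth. Isotropic x–y noise would additionally
  cause errors-in-variables attenuation that the depth model does not have.
* `make_blistered_leaf()` — a lamina with height field
  `A · E · sin(2πx/λ) · sin(2πy/λ)`. The envelope
  `E = max(0, 1 − (x/a)² − (y/b)²)` tapers the blisters towards the margin
  (laminae flatten at the rim); `footprint = "ellipse"` crops to the lamina
  (unorganized — a cropped ellipse cannot be a raster), while
  `"rectangle"` keeps the organized grid for raster-window work.
* `make_sphere_surface()` / `make_solid()` — analytic oracles for normals
  and volumes. `make_solid()` offers cell-centred sampling (a 10 mm cube at
  0.25 mm pitch occupies exactly 8000 voxels of 0.5 mm) and
  boundary-inclusive sampling (the cube hull is exactly size³); the two
  conventions cannot be satisfied by one lattice.
* `make_rosette()` — radially placed tapered laminae, pitched upward; an
  end-to-end fixture for the batch pipeline.

All generators are deterministic under a fixed seed (the RNG state is
restored afterwards). They do **not** emulate occlusion, reconstruction
artefacts, leaf thickness, serration, or real lamina vein relief — passing
tests show the estimators are correct on clean geometry with known truth,
not that a particular scanner meets any accuracy figure.

### The blister-amplitude sweep

The mechanism test drives amplitude through {0, 0.5, 1, 2, 4} mm at fixed
wavelength and seed and requires LCg to rise and the smooth fraction to
fall strictly. The conditions were chosen by analysis before freezing:

* Raster windows, not k-NN: on steep folds the 3D k-nearest neighbours of a
  point localize on one flank, so k-NN LC is *non-monotone* at high
  amplitude. Raster windows always span the same x–y extent.
* Wavelength 3 mm at 0.2 mm spacing with the 3 × 3 normals window: the
  smooth fraction only moves strictly at every step if the LC distribution
  straddles the 0.5 threshold at every non-zero amplitude. Gentle 10 mm
  waves never push LC past 0.5 at amplitude 0.5 mm, and large normal
  windows low-pass the relief away; fine blisters with the small window do
  both, and the margin taper spreads the distribution so neither end
  saturates.

With those conditions LCg runs from ≈ 0.14 (noise floor) to ≈ 0.50 across
the sweep — the same order as published lettuce trajectories — and the
smooth fraction falls from 1.0 to ≈ 0.53.

## Numerical choices and degenerate inputs

* Collinearity test in plane fits: second principal variance ≤ 1e-12 of the
  first. Degenerate hull inputs (coplanar clouds) raise a
  `leafscan_error_degenerate`; planar clouds give bounding-box and columnar
  volume 0 with a warning — each estimator degrades in the way that still
  means something.
* Quickhull uses a relative tolerance of 1e-10 × coordinate scale;
  coplanar lattice points on a face are interior and never become vertices.
* Histogram binning is right-open with a closed last bin, so LC = 1 (or a
  hair above from rounding) is counted once, in the top bin.
* Orientation ties (nz = 0) break towards +y, then +x — fully
  deterministic, but physically arbitrary for exactly vertical surfaces.
* Masks are 0-based in files (the interchange convention) and 1-based in R.

## Problem sizes in the test-suite and acceptance runs

Chosen as the package's own verification conditions: 10 000 random
100-normal windows for the LC identity; five plates of ~1e6 points for the
angle bench; a 50 000-point sphere and a 7.2-million-point lattice ball for
the volume oracles; 14 641-point laminae for the blister sweep; ~4 500
point rosettes for the end-to-end determinism checks.

## Limitations

* LC conflates convexity and concavity; it cannot grade blister *direction*.
* LCg depends on the scanner's point density and noise through the normal
  window; values are comparable across plants scanned with one protocol,
  not across instruments.
* No automatic lamina/midrib segmentation: masks are inputs.
* The axis-aligned bounding box depends on the scan frame's x–y
  orientation; only the z axis is canonical.
* No mapping from LCg or smooth fraction to ordinal 1–9 visual grades is
  provided; none is defined, and calibrating one needs scored reference
  material.
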