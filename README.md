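# leafscan

Morphometric and local-curvature phenotyping of segmented 3D plant scans.

Variety testing and growth monitoring of leafy crops score two kinds of
characteristics: those a ruler can measure (height, diameter, volume) and
those a person judges by eye — above all *leaf blistering*, the puckered
relief of a lettuce lamina, and the *size of its blisters*. `leafscan`
computes both kinds from a single segmented point cloud (millimetre
coordinates, +z up), and ships a synthetic-scan module so every estimator
is verifiable against analytic ground truth without a scanner.

## The statistics at its core

**Local curvature (LC).** For each point, a plane is fitted by least
squares to its local neighbourhood (an `s × s` raster window on organized
clouds, the `s²` nearest neighbours otherwise), solving whichever of
`z = ax + by + c`, `y = ax + bz + c`, `x = ay + bz + c` is well conditioned
for the surface orientation; the plane's unit normal, oriented into the +z
hemisphere, is the point's normal **n** = (nx, ny, nz). Over a second,
larger window the dispersion of the normals gives

```
LC = sqrt(s_nx² + s_ny² + s_nz²) ,
```

the population standard deviations of the three components. For unit
vectors this equals `sqrt(1 − ‖mean n‖²)`, so LC ∈ [0, 1]: 0 on flat
lamina, large where the surface has peaks and valleys. Binning LC in 0.05
steps over [0, 1] gives the LC histogram; its centroid

```
LCg = Σ (midpoint × frequency) / Σ frequency
```

rises as blistering develops, and the **smooth fraction** — the share of
points with LC < 0.5 — shrinks as blisters grow.

**Volumes and dimensions.** Four volume estimators (axis-aligned bounding
box; exact 3D convex hull via compiled quickhull; columnar solid = box
height × vertical projected area; 0.5 mm voxel occupancy), plus

```
compactness = voxel volume / convex hull volume ,
```

which approaches 1 for a dense head and stays far below 1 for an open
rosette. Plant height, major diameter (projected-hull diameter) and minor
diameter (minimal projected-hull width) are ruler-equivalent, and
`estimate_region_angles()` reproduces the tilted-plate protocol used to
benchmark a scanner's angle accuracy per 1/5/10 mm cell.

## Worked example

```r
library(leafscan)

smooth  <- make_rosette(n_leaves = 8, leaf_extent = 60, amplitude = 0.5,
                        wavelength = 10, spacing = 0.75, noise_sd = 0.05,
                        seed = 7)
crinkly <- make_rosette(n_leaves = 8, leaf_extent = 60, amplitude = 4,
                        wavelength = 10, spacing = 0.75, noise_sd = 0.05,
                        seed = 7)

traits <- measure(list(smooth = smooth, crinkly = crinkly))
print(as.data.frame(traits[, c("id", "height", "major_diameter",
                               "projected_area", "voxel_volume",
                               "compactness", "lcg", "smooth_fraction")]),
      digits = 3)
#>        id height major_diameter projected_area voxel_volume compactness   lcg
#> 1  smooth   25.5            109           4851         2942      0.0312 0.183
#> 2 crinkly   25.5            109           4593         2947      0.0289 0.457
#>   smooth_fraction
#> 1           1.000
#> 2           0.537
```

The two mock rosettes share every gross dimension — same height, same
109 mm spread — but the strongly blistered one is cleanly separated by the
curvature summaries: LCg 0.457 vs 0.183, and only 54 % of its lamina
remains smooth (LC < 0.5) against 100 %. Compactness is tiny for both
because an open rosette of thin laminae fills almost none of its hull.

Single-leaf work mirrors the manual protocol: cut out the lamina with a
mask, then

```r
rep <- blister_report(leaf_cloud, mask = read_mask("lamina.txt"),
                      heatmap_path = "leaf_lc.ply")
rep$lcg; rep$smooth_percent    # blistering and size-of-blister metrics
autoplot(rep$histogram)        # LC histogram on the fixed blue-red ramp
```

I/O covers ascii/binary-little-endian PLY and XYZ, plus colour-mapped PLY
export (`write_colormapped()`): LC heatmaps on a fixed blue-green-yellow-
red ramp anchored at 0 and 1, or |normal| → RGB so upward-facing lamina
renders blue. A thin command-line front end with `measure`, `normals`,
`curvature`, `blister`, `volume`, `anglebench` and `synth` subcommands is
installed at `inst/cli/leafscan`.

See `vignettes/quantifying-leaf-blistering.Rmd` for the model, parameter
defaults (normal window 7, LC window 15, voxel 0.5 mm, bin width 0.05,
smooth threshold 0.5) and the design decisions behind them.

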