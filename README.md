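# invquant

Pixel-based quantification of multicellular-spheroid invasion into 3D
matrices.

Spheroids embedded in collagen or other hydrogels are a standard in vitro
model of 3D cell invasion (wound healing, cancer metastasis, tissue
engineering). Quantifying how far and how much a cell population invades is
surprisingly hard to do objectively: spheroids differ in initial size and
shape, invading cells change shape as they spread, and object-based
(per-cell) segmentation is sensitive to thresholding and cell clumping.
`invquant` implements a segmentation-free alternative for users of such
assays: all measurements are made at the level of nuclear **pixels**,
referenced to the initial boundary of each individual spheroid.

## Method

Given binarized maximum-projection images of Hoechst-stained nuclei for the
same spheroid at an initial (Day 0) and final (Day 2) timepoint:

1. The Day-0 spheroid body is segmented (largest 8-connected component,
   holes filled) and its outer boundary traced at sub-pixel resolution.
2. The boundary is registered onto the Day-2 image by centroid translation.
3. Every Day-2 foreground pixel outside the registered boundary (an "outer
   pixel") is assigned a radial distance *d* and angle *θ*: the distance is
   measured to the crossing of the boundary with the ray from the spheroid
   centroid (x₀, y₀) through the pixel (x_p, y_p),

   d = √((x_p − x_b)² + (y_p − y_b)²),  θ = atan2(y_p − y₀, x_p − x₀),

   where (x_b, y_b) is the boundary crossing.
4. Per-spheroid metrics are computed:
   - **area change** ΔA = A_final − A_initial (pixel counts × dA, the pixel
     area);
   - **mean / max invasion distance** over the outer pixels;
   - **radial area moment of inertia** I_r = Σᵢ dᵢ² dA, an integrative
     invasiveness metric that weights area invading farther from the
     boundary quadratically, by analogy with the second moment of area in
     mechanics;
   - **directionality**: PCA of the outer-pixel cloud gives the axes of
     maximum and minimum invasion; after rotating coordinates onto them,
     the directional moments I_x′ = Σ y′² dA and I_y′ = Σ x′² dA, the mean
     distances along each axis, and their max/min **fold changes** quantify
     anisotropic invasion (fold change ≈ 1 means isotropic).

A synthetic-data module generates disk/annulus pairs and anisotropic
point-cloud invasions whose metrics have closed forms, so the whole
pipeline can be validated without microscope data. Batch tools consolidate
per-spheroid results into one table with scaled-MAD outlier flags
(1.4826 × median absolute deviation; values beyond 3 scaled MADs from the
median are flagged, never silently dropped).

## Worked example

Synthetic isotropic invasion with known truth — Day 0 a disk of radius
1 mm, Day 2 a disk of radius 2 mm, at 10 µm/px:

```r
library(invquant)

pair <- make_annulus_pair(R0_mm = 1, R1_mm = 2, pixel_size_um = 10)
fit <- spheroid_invasion(pair$day0, pair$day2, pixel_size_um = 10)
fit
#> Pixel-based spheroid invasion quantification
#> Invasion metrics for 'spheroid':
#>   area change             9.421 mm^2
#>   mean distance          0.5554 mm
#>   max distance           0.9999 mm
#>   radial moment Ir        3.662 mm^4
#>   outer pixels            94212
#> Directional invasion metrics:
#>   principal angles   0.0 deg (max) / 90.0 deg (min) [isotropic]
#>   directional moments  11.77 / 11.77 mm^4  (1X)
#>   mean distances       0.9902 / 0.9902 mm  (1X)
```

The closed-form truth for this pair is ΔA = 3π ≈ 9.4248 mm², mean distance
≈ 0.5556 mm and I_r = 2π(1/4 + 1/3) ≈ 3.6652 mm⁴; the pipeline lands
within 0.1% of each. The `[isotropic]` flag and 1X fold changes correctly
report that this invasion pattern has no preferred direction.
`plot(fit)` draws the polar plot of the invaded pixels (distance from the
boundary vs angle, boundary at the center) with the principal axes
overlaid.

For real images, pass file paths instead (`spheroid_invasion("s1_d0.tif",
"s1_d2.tif", pixel_size_um = 0.76, threshold = 0.16)`), or process a whole
folder of `<id>_d0.tif` / `<id>_d2.tif` pairs:

```r
tab <- run_batch("images/", "results/", config = list(pixel_size_um = 0.76))
```

which writes `metrics.csv`, `directionality.csv`, per-spheroid pixel
tables and a JSON run manifest. The same pipeline is scriptable from a
shell via `inst/cli/invquant.R` (`quantify`, `binarize`, `consolidate`,
`simulate` subcommands).

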