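---
title: "Pixel-based quantification of spheroid invasion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-based quantification of spheroid invasion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invquant)
```

## The measurement problem

Multicellular spheroids embedded in 3D hydrogels are imaged at an initial
timepoint (just after embedding) and again after a culture period during
which cells invade the surrounding matrix. The question is how to turn the
two images into numbers that (a) do not depend on the initial size and
shape of the particular spheroid, (b) do not require segmenting individual
cells or nuclei — which is fragile when cells clump or change shape — and
(c) capture both *how much* material invaded and *how far* it went.

`invquant` answers this with a pixel-based scheme. Both images are reduced
to binary nuclear masks. The initial (Day-0) spheroid boundary is
segmented once per spheroid and becomes that spheroid's private reference
line; every final-timepoint (Day-2) foreground pixel outside it is a unit
of invaded area with a well-defined distance from the boundary. Because
distances are measured from each spheroid's own boundary, variation in
starting size largely cancels out.

## Pipeline and model

1. **Binarization.** A global threshold on the normalized [0, 1] intensity
   scale; a pixel is foreground iff its intensity strictly exceeds the
   threshold. Default 0.16, which suits typical Hoechst maximum
   projections; the right value is data-dependent and should be checked
   per batch. Optional pre-processing (both off by default): white top-hat
   background subtraction (structuring-element radius 50 px by default;
   removes smooth background larger than the element) and a linear
   contrast stretch of the 1st–99th intensity percentiles. The strict
   (`>`) comparison is a deliberate convention so that threshold 1.0
   yields an empty mask; monotonicity (raising the threshold never adds
   pixels) holds by construction.
2. **Field-of-view masking.** A rectangular frame admits more invasion
   along its diagonal and long axis than elsewhere. The inscribed circular
   mask — keep a pixel iff the Euclidean distance from its center to the
   image center ((H−1)/2, (W−1)/2) is ≤ min(H, W)/2 — equalizes the
   visible extent over all directions. The pixel-center membership rule is
   stated exactly because any discretization of a circle is otherwise
   ambiguous.
3. **Artifact correction.** Instead of interactive clean-up, an optional
   per-image *correction mask* (same shape, TRUE = keep) is ANDed with the
   binary image. This keeps runs reproducible and scriptable; a user can
   produce the mask in any external tool.
4. **Boundary segmentation.** The largest 8-connected foreground component
   of the Day-0 mask is kept (8-connectivity is the usual convention for
   binary foreground); interior holes are filled, since the boundary of
   interest is the outer envelope of the spheroid, and nuclear stains
   routinely leave small holes inside the body. The outer contour is then
   traced as the 0.5-level set of the mask (marching squares), giving
   vertices at sub-pixel positions halfway between foreground and
   background pixel centers. Sub-pixel tracing matters: a pixel-center
   trace of a disk of radius R underestimates its area with a relative
   error of order 1/R, while the 0.5-level contour stays well inside the
   2% bound the tests demand down to R = 30 px. Ties for the largest
   component are broken by the smallest top-left bounding-box corner (row,
   then column) — an arbitrary but deterministic rule.
5. **Registration.** The Day-0 boundary is translated so its centroid
   coincides with the centroid of the *largest connected component* of the
   Day-2 image. Using the spheroid core rather than all foreground pixels
   is deliberate: invading cells are spatially asymmetric, and a
   whole-image centroid would drag the boundary toward the invasion front.
   Registration is translation-only; the assay has no meaningful rotation
   between timepoints.
6. **Outer pixels and distances.** Day-2 foreground pixels strictly
   outside the registered polygon (even–odd rule; pixels whose centers lie
   exactly on the polygon are classified as inside, since they belong to
   the initial footprint) form the invasion cloud. Each pixel's distance
   is measured to the crossing of the polygon with the ray from the
   spheroid centroid through the pixel, computed by exact segment–segment
   intersection. A non-convex boundary can cross one ray several times;
   the crossing at the largest radius not exceeding the pixel's own radius
   is used, which guarantees d ≥ 0 and measures from the locally outermost
   spheroid edge. Angles are atan2(y_p − y₀, x_p − x₀) in [0°, 360°);
   with the image convention (y down) they advance clockwise on screen.
7. **Metrics.** ΔA (may legitimately be negative when a spheroid compacts;
   it is returned as-is with a shrinkage flag rather than clamped), mean
   and max distance, and I_r = Σ d² dA. Distances are reported in mm,
   areas in mm², moments in mm⁴.
8. **Directionality.** PCA of the outer-pixel (x, y) coordinates about
   their mean. Pixels are equal-area samples, so unweighted coordinate PCA
   *is* area-weighted PCA of the invasion pattern; this is also why PCA is
   run on coordinates rather than on (d, θ) values. The PCA origin
   defaults to the cloud mean (the spheroid centroid is available via an
   option). Coordinates are rotated onto the principal axes; I_x′ = Σ y′²
   dA, I_y′ = Σ x′² dA, directional mean distances are mean |x′| and mean
   |y′| (the natural "distance along an axis" from the origin), and fold
   changes are max/min ratios, hence always ≥ 1. Principal angles are
   reported modulo 180° because the axes are undirected; the −180° aliases
   are included in outputs for readability.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `threshold` | 0.16 | intensity in [0, 1] | global; strict comparison |
| `pixel_size_um` | 1 | µm/px | calibration; sets dA = (px/1000)² mm² |
| `bg_radius` | 50 | px | top-hat structuring element |
| `circular_mask` | TRUE | — | inscribed-circle field of view |
| `pca_origin` | "mean" | — | or "centroid" |
| `iso_tol` | 1e-8 | relative | eigenvalue gap below which a cloud is called isotropic and the angle is set to 0 |
| `registration_tol` | 0.5 | px | allowed centroid mismatch in `find_outer_pixels` |
| MAD `k` | 3 | scaled MADs | outlier flagging cut |

## The synthetic generators, and what passing tests mean

`make_annulus_pair()` builds concentric disks; for Day-0 radius R₀ and
Day-2 radius R₁ (W = R₁ − R₀) the truth is closed-form:

- ΔA = π(R₁² − R₀²)
- mean d = 2π(W³/3 + R₀W²/2) / [π(R₁² − R₀²)]
- I_r = 2π(W⁴/4 + R₀W³/3)

`make_anisotropic_pair()` adds point nuclei drawn from a rotated bivariate
Gaussian, rejection-sampled outside the disk; its orientation is the PCA
truth. Single-pixel nuclei keep that truth exact in expectation; a blob
variant (disk nuclei, e.g. radius 3 px) emulates realistic clustering.
`make_grayscale_from_binary()` renders masks as two-level grayscale with
optional Gaussian noise to exercise thresholding. In the test suite the
truth values are re-derived by numerical quadrature, so the closed forms
and the pipeline are checked against each other through an independent
route.

These generators emulate the *geometry* of invasion, not its biology:
real nuclei are extended, textured blobs of varying intensity; real
backgrounds have gradients and debris; real invasion fronts are neither
perfectly radial nor Gaussian. Passing the synthetic suite therefore
demonstrates that the geometric measurement machinery is correct and
convergent, not that a particular threshold or correction setting is right
for any given microscope and stain — those remain per-experiment choices.

## Numerical choices and degenerate inputs

- Grid-scale checks run at 10–20 µm/px (frames of roughly 200–450 px),
  where the annulus pipeline is within 0.1–2% of truth; a convergence test
  confirms the error shrinks as the pixel size halves.
- Point-in-polygon uses the even–odd crossing rule with edges bucketed by
  their y-span; ray crossings bucket edges by the angular arc they subtend
  at the centroid. Both are exact up to floating point; tolerances of
  1e-9 px absorb round-off at shared vertices.
- An empty outer cloud yields zero distances/moments and skips PCA
  (directionality needs ≥ 2 pixels). A perfectly isotropic cloud has equal
  covariance eigenvalues; its "principal angle" is reported as 0 with an
  `isotropic` flag rather than an arbitrary direction.
- Fold changes are undefined when the minimum-direction value is 0 (a
  degenerate, exactly collinear cloud); this errors rather than returning
  infinity.
- Batch runs are fail-soft: one broken image yields an error row, the
  rest of the batch completes. Outlier handling only flags by default
  (`drop_outliers` actually removes), because silent deletion harms
  auditability.

## Limitations

- Maximum projections only: distances are 2D projections of 3D invasion
  and underestimate true radial travel for cells moving out of plane.
- No per-cell information: the method deliberately avoids counting nuclei,
  so proliferation and migration are entangled in ΔA (the moment I_r is
  less sensitive to this, which is its purpose).
- Translation-only registration assumes the spheroid body does not rotate
  or deform grossly between timepoints.
- A single global threshold is applied per image; adaptive thresholding is
  intentionally out of scope.
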