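---
title: "Methods: multi-view fruit morphometry with fruitmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-view fruit morphometry with fruitmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitmorph)
```

# The measurement problem

Describing fruit appearance for breeding programs and germplasm
collections means characterizing shape, size, weight and peel color for a
modest number of fruit from each of many accessions. `fruitmorph`
implements the downstream analysis for an imaging protocol in which every
fruit is photographed by five fixed, calibrated RGB cameras — four side
views and one top view — inside a light-controlled box, with one image of
the empty box per camera as a background reference and the fruit mass
recorded at acquisition time.

The pipeline has four stages: per-image segmentation, per-image shape and
color descriptors, per-fruit record assembly, and per-cultivar statistics
including a resampling answer to "how many fruit do I need?".

# Segmentation

Each image is segmented by the union of two masks:

* **m1 (HSV threshold).** A pixel is fruit candidate when S/V > 0.2 and
  S > 0.19, with S and V the standard hue-saturation-value components in
  [0, 1]. Both inequalities are strict, and V = 0 pixels (undefined ratio)
  are background. This exploits the fact that the box background is
  nearly achromatic while fruit peel is saturated.
* **m2 (background difference + Otsu).** The per-pixel difference between
  the image and the matching empty-box reference is reduced to a single
  magnitude and thresholded with Otsu's method. The default magnitude is
  the per-channel maximum of the absolute differences, which stays
  sensitive when the fruit happens to match the background in one channel;
  `metric = "luminance"` and `"euclidean"` are available alternatives.

The Otsu threshold is computed by exhaustive maximization of the
between-class variance on a 256-bin histogram spanning the observed range
of the magnitude, with ties resolved toward the lowest threshold. An
identical image/background pair (zero difference everywhere) yields an
empty m2 with a warning rather than an error.

The final mask is the largest connected component of m1 ∪ m2 with holes
filled. This post-processing is deliberately minimal — it only selects and
fills, never adds distant pixels — and can be disabled
(`postprocess = FALSE`). An optional exclusion region per camera supports
real installations where a pedestal intrudes into the frame; none is
applied by default.

# Shape geometry

**Polar profiles.** The mask contour is converted to polar coordinates
about the mask centroid and interpolated to integer degrees: for each
degree the radius is the distance to the outer 0.5-crossing of the
bilinearly interpolated mask along that ray, so radii are sub-pixel. The
convention is mathematical: 0° along +x, counter-clockwise, image y-axis
flipped. For contours that are not star-shaped about the centroid, the
outermost crossing is taken. A profile's 360-gon area stays within 2% of
the pixel area for the shapes this pipeline targets, and the test suite
enforces that.

**Symmetry correction and asymmetry.** Apples are described after
registering each side view upright: the mask is rotated about its centroid
to the angle that minimizes the mirror-asymmetry index, searched on a
regular grid over ±20° in 0.25° steps (both configurable; the window
covers realistic fruit tilt at sub-degree resolution). Rotation uses
nearest-neighbour inverse mapping so masks stay binary. The asymmetry
index mirrors the mask across the vertical axis through its centroid and
divides the symmetric-difference area by twice the mask area: 0 for a
perfectly mirror-symmetric shape, at most 1. Mirroring is pixel-exact
(column c maps to round(2·cx − c)), so a pixel-symmetric mask scores
exactly 0; rotated/resampled shapes are considered symmetric below about
0.005. Ties in the angle search resolve to the smallest |angle|, negative
first. The per-fruit asymmetry is the mean of the four per-view minima
(the mean was chosen where the per-fruit aggregation was open; the four
per-view angles are all retained in the record).

**Dimensions and top circles.** Width and height are the horizontal and
vertical pixel extents (max − min + 1) of the symmetrized mask scaled by
the per-camera calibration in cm/px. The top view yields circle metrics
about the centroid: circumcircle radius (largest boundary radius),
incircle radius (smallest), mean radius, and the standard deviation of
radii after normalizing the mean radius to 1 (a unitless roundness
measure). These are centroid-based by construction — deliberately not the
geometric minimum enclosing circle, which has a different center.

# Shape classification

Side shapes are assigned to one of 13 pomological categories by Pearson
correlation between the candidate's mean-1-normalized 360-degree radius
profile and each reference outline; the highest correlation wins, ties go
to the lowest class id. Correlation of mean-normalized profiles makes the
match scale-free. Profiles are assumed rotation-registered by the symmetry
correction; `register = "lag"` maximizes over all 360 circular shifts for
unregistered inputs.

The numeric radii of the classical reference outlines are not available as
data, so the shipped library is a **parametric stand-in**: a superellipse
family (aspect ratio, squareness exponent, linear taper, equatorial waist,
stem/calyx dips) spanning 13 named categories (spherical, flattened
spherical, ellipsoid, oblong, ovoid, obovoid, conical, truncate conical,
rectangular, rectangular conical, cylindrical, cylindrical waisted,
globose conical). The parameters were fixed once so that every profile is
mean-1, all pairwise correlations stay below 0.995, and each class is
recovered at least 95% of the time under 3% multiplicative radial noise.
Any library with the same file contract (class_id, name, 360 radii)
replaces it via `load_reference_library()`. Because Pearson correlation is
amplitude-invariant, outline sets that differ only in the amplitude of one
harmonic cannot be told apart — this is why the small built-in top-view
library gives its "strongly ribbed" entry an extra higher harmonic rather
than just a larger ribbing amplitude, and it is one reason users
replicating published classifications should load the original reference
radii.

Per-fruit classification uses the average of the four side profiles
(averaging reduces view noise; per-view correlations remain available).
`cluster_shapes()` complements the fixed library with k-means on
normalized profiles (3–8 clusters, default 6, ≥10 restarts, fixed seed);
labels are canonicalized by ordering cluster centers lexicographically so
they do not depend on input order.

# Color

The pooled fruit pixels of the four segmented side views feed density
histograms of hue and saturation over 64 uniform bins on [0, 1], each
integrating to 1. Hue is the angular HSV coordinate normalized so 0–1
spans 0–360°; pixels with zero saturation have no defined hue and
contribute only to the saturation histogram. 64 bins balance the
resolution of cultivar color signatures against stability at the ~10^5
fruit pixels a typical acquisition yields, and the count is configurable.
Factsheets and plots restrict hue to [0, 0.5] — yellow, red and green, the
relevant peel colors — but the full range is always stored. Per-cultivar
histograms are per-bin means with sample SDs across fruit.

# Records and cultivar statistics

`build_fruit_record()` assembles the per-fruit row: shape class and
winning correlation (side and top), weight, top-view circle metrics,
per-view and mean widths/heights, mean asymmetry, the four symmetry
angles, shape index, and the flattened color histograms. The shape index
is mean height / mean width — a unitless elongation measure (an
occasionally seen "height/weight" formulation is dimensionally
inconsistent for a shape descriptor and is not used). A missing weight is
flagged, never fatal; a missing view is an error naming the camera.

Cultivar comparisons use one-way fixed-effects ANOVA per trait with Tukey
HSD post-hoc tests at α = 0.05, summarized as a compact letter display
built by the standard insert-and-absorb algorithm directly from the
Tukey-adjusted pairwise p matrix — two cultivars share a letter exactly
when their adjusted p ≥ α, and the test suite checks that equivalence
exhaustively. P-values below 2e-16 are labelled "<2e-16".

# Sample size by quantile resampling

For each cultivar, trait and candidate sample size n, `margin_of_error()`
draws 200 subsets of size n **without replacement** from the full sample
(a with-replacement bootstrap is available behind `replace = TRUE` for
comparison), takes each subset's mean, and computes

rel_moe = (q0.975 − q0.025) / (2 × full-sample mean),

i.e. half the central 95% range of subset means relative to the
full-sample mean. Quantiles use linear interpolation between order
statistics (type 7); at 200 replicates the quantile definition visibly
shifts the estimate, which is why it is pinned down here. Without
replacement, rel_moe necessarily reaches exactly 0 at n = N.
`moe_curve()` evaluates the grid n = 5…50 and aggregates across cultivars
by the arithmetic mean (per-cultivar curves are retained), recommending
the smallest n whose cross-cultivar mean margin meets a target (default
5%). Every cell derives its own seed from the base seed, so results are
reproducible and independent of evaluation order. Weight margins run
roughly three times the width margins at any n because weight follows
volume, which varies cubically with linear size — the reason a sample
adequate for calibre description can still be marginal for weight.

# The synthetic renderer

`render_fruit()` draws a known star-shaped outline into the same
five-camera frame geometry (1296 × 1080, 16 bit/channel by default),
returning images, empty-background references and ground-truth masks. It
emulates what the downstream contracts depend on: a uniform low-saturation
background (S ≈ 0.05, V ≈ 0.9, failing both m1 thresholds with margin —
the real box's white panels under LED light are not being claimed), peel
color drawn per pixel from a seeded HSV mixture, an antialiasing band of
at most 1 px (excluded from IoU scoring, since sub-pixel edges are not
part of the segmentation contract), 16-bit quantization, and a
view-dependent shear (multipliers 1, 0.5, −0.5, −1 across the four side
cameras) that turns one skew parameter into a known asymmetry. It does
**not** emulate lighting gradients, specular highlights, shadows, lens
distortion, the pedestal, or multi-modal real peel texture — so passing
tests demonstrate the correctness of the algorithms on their stated
contracts, not robustness to real-world nuisance effects. Note that a
sheared ellipse is again an ellipse and hence symmetric after rotation;
asymmetry validation therefore uses a tapered (ovoid) outline on which
shear is not removable by rotation.

`simulate_study()` complements the renderer at the record level: it draws
per-fruit trait values for programmed per-cultivar means without images,
for statistical validation at full study scale. Default CVs (width 5.5%,
height 6.5%, weight 15.5%) were fixed once to be consistent with margins
of error around 2–3% for the linear traits and 6% for weight at n = 20
under the finite-population normal approximation, with mean weights
following a spheroid volume model (0.8 g/cm³ × π/6 × width² × height).

# Numerical choices and degenerate inputs

* Strict inequalities at both HSV thresholds; V = 0 treated as
  ratio-false.
* Otsu: 256 bins over the observed range; tie → lowest threshold;
  constant difference → empty mask + warning.
* Polar conversion: 0.25 px ray sampling with linear interpolation at the
  0.5 iso-level; empty masks and rays that never hit the mask are errors.
* Correlation with a constant profile on exactly one side is defined as 0;
  constant-vs-constant is 1 on equality (with a warning), else 0.
* `average_shape()` uses the sample SD (n − 1); SD is 0 at n = 1.
* 16-bit TIFF encoding snaps to the 65535-step grid and compensates the
  writer's truncation so read-back is bit-identical.
* Weight precedence: TIFF description field over manifest sidecar, with a
  warning when both exist and disagree.

# Problem sizes used by the test suite

The suite validates the imaging chain at reduced frames chosen by the
package (e.g. 648 × 540 px at 0.02 cm/px for the 20-fruit segmentation
sweep, 324 × 270 at 0.04 for per-module checks, 200 × 160 at 0.05 for the
rendered end-to-end subset), with one full-frame render exercised in the
synthetic-fruit tests; geometry tolerances are resolution-scaled contracts
(e.g. ellipse radii within 1 px), so the reduced frames test the same
invariants. Statistical claims run at full study scale (15 cultivars ×
100 fruit) on the record-level generator.

# Known limitations

* The shipped reference outlines are a documented parametric stand-in, not
  the classical manual's radii; classifications against it are internally
  consistent but not comparable to published class assignments until the
  original library is loaded.
* Correlation-based classification cannot separate outline families that
  differ only in the amplitude of a single harmonic after mean
  normalization.
* One fruit per frame is assumed; multi-fruit scenes, shadow modelling and
  specular-highlight repair are out of scope.
* Circle metrics are centroid-based, not minimum enclosing circles.
* The asymmetry search is a grid search; its resolution is the step size,
  and the reported angle inherits that granularity.
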