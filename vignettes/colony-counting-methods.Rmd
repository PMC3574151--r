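---
title: "Counting colonies by recursive thresholding: methods and design notes"
author: "cfuCounter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting colonies by recursive thresholding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfuCounter)
```

# The problem

Counting colony-forming units (CFU) on agar plates is routine in
microbiology but error-prone to automate. Direct thresholding of a
grey-scale image followed by morphological segmentation tends to mistake
high-contrast artefacts — Petri-dish rims, bubbles in the agar, cracks,
dust — for colonies, because at *some* threshold a portion of an artefact
happens to look circular. cfuCounter implements a detection strategy built
around the opposite idea: instead of committing to one threshold, sweep
essentially all of them, and keep only regions that are *recurrently*
circular across the sweep. Artefacts are circular by accident at isolated
thresholds; colonies are circular at every threshold below their contrast.

# The procedure

## Preprocessing

Each of the three colour channels is handled independently:

1. **Background estimation.** A local median filter (radius
   `medianRadius`, default `min(rMax, 20)` px so the largest expected
   colony cannot be absorbed into the background) estimates the smooth
   background, which is subtracted. This removes gradual illumination
   changes without any reference image.
2. **Polarity.** Colonies may be brighter or darker than the agar. The
   dominant deviation sign across the ROI decides the polarity
   (`polarity = "auto"`), and only deviations in the colony direction are
   kept. A config override is available for mixed material.
3. **Contrast enhancement.** The positive part of the
   Laplacian-of-Gaussian of the foreground (`logSigma` = 2 px, 9 × 9
   kernel) is subtracted from the foreground and the result clipped at
   zero. This erodes the skirts of edges and thin, high-curvature
   structures (cracks, rim fragments) while leaving wide flat plateaus —
   colony interiors — essentially unchanged.
4. **Normalisation and merging.** Channels are normalised to [0, 255]
   over the ROI and averaged. The normalisation gain is capped at
   `255 / max(range, minContrast)` with `minContrast = 60` grey levels:
   a plain min–max stretch would amplify the sensor noise of a
   *featureless* plate about 25-fold and turn noise blobs into fake
   signal, whereas the cap keeps the normalisation a unit standardisation
   of exposure. Images whose true contrast exceeds 60 grey levels are
   stretched exactly as a min–max rule would.

## The score map

The merged grey image is binarised at every integer grey level between its
minimum and maximum (`thresholdStride = 1`; a larger stride trades
fidelity for speed). At each threshold, every 8-connected component is
screened by the reject stage of the particle filter (below); each pixel of
every surviving component receives one vote. The resulting *score map*
counts, per pixel, how recurrently that pixel belonged to a plausibly
circular region. A cut at `scoreThreshold` votes (default 12, the
high-definition setting; 7 is appropriate for low-quality webcam images)
produces the detection mask. An automatic cut (Otsu's method on the
non-zero vote histogram) is available but implementation-defined.

## The morphological particle filter

Each connected component is described by: area, outer-contour perimeter
(Moore tracing, diagonal steps weighted $\sqrt2$, which stabilises
circularity across radii), convex hull area over boundary pixel centres,
convexity $A/A_{hull}$, moment-ellipse aspect ratio (with a 1/12 px²
pixel-extent term so thin components stay finite), hollowness
$A_{holes}/A$, equivalent radius $\sqrt{A/\pi}$ and circularity
$4\pi A/P^2$.

The decision cascade has the structure *reject → single evidence → single
confirmation → cluster confirmation*:

* **Reject** (all must hold to survive): equivalent radius ≥ `rMin`;
  aspect ratio ≤ `screenAspectMax` (3.5); hollowness ≤ `screenHollowMax`
  (0.15). This removes specks, elongated fragments (cracks, rim arcs) and
  rings (bubbles).
* **Single evidence** (any): circularity ≥ `singleCircMin` (0.95); or
  convexity ≥ `singleConvMin` (0.92) with aspect ratio ≤
  `singleAspectMax` (1.3); or equivalent radius ≤
  `smallRadiusFactor · rMin`.
* **Single confirmation** (all): equivalent radius ≤ `rMax`; convexity ≥
  `confirmConvMin` (0.85); aspect ratio ≤ `confirmAspectMax` (2.2).
  Evidence without confirmation is invalid.
* **Cluster** (all, for components without single evidence): hollowness ≤
  `multiHollowMax` (0.2); aspect ratio ≤ `multiAspectMax` (6); area ≥
  $2\pi\,r_{min}^2$ (at least two minimal objects); convexity ≥
  `multiConvMin` (0.5). Anything else is invalid.

The numeric constants are this implementation's calibration on the
synthetic suite, with two targets: zero accepts on bubble / crack / rim /
dust / blank fixtures, and acceptance of clean discs across the whole
radius range. Two measurements anchored the most delicate constant:
digital discs score circularity 0.90–1.4 but *always* pass through the
convexity-plus-aspect route (convexity 1.0, aspect 1.0), while fused
colony pairs reach circularity 0.90 at the smallest radii — hence
`singleCircMin = 0.95`, above every fused pair and below no disc that
needs the circularity route.

## Splitting merged colonies

Components classified as multiple objects are segmented on their own
cropped mask:

* **Chamfer distance transform** on a 5 × 5 neighbourhood with step
  weights a = 1 (orthogonal), b = 1.4 (diagonal), c = 2.1969 (knight
  move), computed by the standard forward/backward two-pass sweep. On
  every tested fixture it equals the brute-force shortest chamfer path.
* **Markers** are the local maxima of the distance map. Equal-valued
  plateaus merge into one marker at the plateau pixel nearest the
  centroid, with one exception: a plateau whose spatial extent exceeds
  1.2 × its peak value is a flat ridge spanning two fused centres and
  seeds a marker at each extremal pixel. A candidate maximum closer
  (chamfer point metric) than `max(2, 0.9 · peak)` to an accepted
  higher-or-equal marker is suppressed: a genuine second colony of that
  presumptive radius would put its centre at least about one radius away,
  so anything closer is a digitisation plateau or a ridge saddle point.
* **Constrained watershed.** Regions grow from the markers
  downhill-or-flat only; a region may neither exceed
  `kappaArea · π · peak²` pixels (`kappaArea = 1.3`) nor claim pixels
  farther than `kappaDist · peak` (`kappaDist = 1.5`, chamfer point
  metric) from its original marker. The peak value is the presumptive
  radius, so both limits scale with the colony the marker presumes.
  Growth is scheduled by a priority queue keyed on descending distance
  value, with ties broken first by chamfer distance to the claiming
  marker and then by (row, column) order — the first tie-break keeps the
  boundary between equal twins in the neck, the second makes the result
  deterministic and independent of marker order.
* **Reassessment.** Every fragment runs through the particle filter
  again. Fragments confirming as single objects are accepted; invalid
  fragments are dropped; a fragment that still classifies as multiple
  objects (a truncated pair inside a larger cluster) is split again by
  the same procedure, to a recursion depth of 3 and only while it
  shrinks. Accepted objects record how many siblings were accepted from
  the same original cluster (`cluster_size`).

## Colour postfilter

Optionally, a per-channel normal distribution is fitted to the *relative
colour intensities* of unsplit objects (channel medians divided by their
sum, making the model invariant to illumination scale; unsplit objects
are used because they are less often false positives; at least 3 are
required or the filter passes everything). An object's likelihood is the
product of the channel densities; the user cutoff has quantile semantics:
an object is excluded when the tail probability of its squared-deviation
statistic (χ² with 3 degrees of freedom, a monotone transform of the
likelihood) falls below the cutoff. Cutoff 0 excludes nothing; raising
the cutoff never un-excludes; excluded objects are flagged in the
detailed output, not deleted.

## Region of interest

`detectDish()` finds the dish rim by a gradient-guided Hough circle
transform: edge pixels (gradient magnitude ≥ max(15, 0.3 × its 99.9 %
quantile) — a fixed high quantile fails on crowded plates, where colony
edges push it above the rim gradient) vote along their gradient direction
over radii 0.25–0.55 × min(dimension). The best accumulator cells are
refined by a least-squares circle fit restricted to radially-aligned
inliers and scored by the radially-aligned fraction of the circumference
they support; clutter pixels that merely happen to sit on the annulus
have random gradient orientation and barely count. A final snap moves the
radius onto the ring of extremal mean intensity (the rim centreline),
which is stable to a few tenths of a pixel even when the rim is partly
out of frame. The ROI is the fitted disc adjusted by `margin` (default
−25 px, shrinking inward). If no circle gathers enough support the full
frame is used, with a warning. Objects are kept when their centre lies
inside the ROI; one dish per image is assumed.

# The synthetic plate generator

`randomPlateSpec()` + `renderScene()` define the validation conditions
used throughout the tests:

* 640 × 640 px scenes; background level 175 with a bilinear gradient of
  ±8 grey levels and Gaussian noise σ = 2 — the gentle, gradual
  background variation of a trans-illuminated plate;
* a dark dish rim of radius 0.48 × min(dimension), 3 px wide, 60 grey
  levels of contrast;
* colonies as anti-aliased discs (1 px area-coverage rim, so the
  threshold sweep sees a soft edge as in photographs), radius U(3, 5) px,
  contrast U(60, 85) grey levels, cream-coloured (channel weights 1,
  0.93, 0.68), with an optional red minority (1, 0.35, 0.30);
* 20 % of colonies fused into pairs or collinear triples at centre
  distance 1.5 × mean radius (a compact triangular triple is
  morphologically indistinguishable from one large round colony, so
  chains are used);
* bubbles (bright 2 px ring, radius U(6, 14), darkened interior), cracks
  (thin dark random-walk polylines, hidden where an opaque colony sits on
  top), dust (3–8 px irregular high-contrast specks).

Placement combines dart throwing for clusters with a jittered grid for
singles, so ground-truth counts are exact by construction even at 1000
colonies per plate. The seed fully determines the raster; re-rendering is
bit-identical.

What the generator does **not** emulate: lens distortion and vignetting,
specular highlights, condensation, colony morphology beyond discs
(rough-edged, concentric or swarming colonies), colony-size–dependent
colour, and writing on the dish. Passing the synthetic suite therefore
demonstrates the algorithmic properties (artefact rejection, splitting,
translation invariance, determinism) but is not a substitute for
calibration on real photographs; on real material the radius range and
score threshold remain the two parameters a user should expect to adjust.

# Numerical choices and degenerate inputs

* Threshold sweep: every integer level between the image minimum and
  maximum; an image with fewer than ~3 grey levels of range (a blank,
  uniform frame) is answered with an empty result rather than an error.
* Chamfer distances are measured to in-image background; cluster masks
  are cropped with a 2 px background rim before the transform.
* The closed-form chamfer point metric
  ($c\,y + a\,(x-2y)$ if $x \ge 2y$, else $c\,(x-y) + b\,(2y-x)$,
  for $x \ge y \ge 0$) is used both in the watershed growth rule and in
  the post-hoc constraint assertions, so the two cannot drift apart.
* Moore tracing uses Jacob's stopping criterion (stop when the first
  transition out of the start pixel repeats); an isolated pixel gets
  perimeter 1 by convention.
* The colour model floors each channel standard deviation at 0.01
  relative-intensity units so identical-colour plates do not divide by
  zero.
* All computations are deterministic: identical input and configuration
  give bit-identical outputs, which the test suite asserts at the CSV
  level.

# Known limitations

* A fused pair of the smallest colonies can produce a score-map blob
  round enough to classify as a single object, or a distance map with a
  single compact plateau; such a pair counts as one object. On the
  validation conditions this affects roughly one plate in sixty at the
  10-colony load.
* Chains of many deeply fused colonies are split only as far as distance
  peaks support; the area and distance limits prevent one marker from
  swallowing a chain, but fragments beyond the recursion depth are
  dropped rather than guessed.
* One dish per image; multiple regions of interest are out of scope.
* The score threshold (12 votes) assumes the exhaustive integer sweep; if
  a stride is used the threshold should be scaled down accordingly.

# Problem sizes used in validation

The packaged tests render 320 px plates for module-level checks and the
full 640 px study conditions for the end-to-end suite: 20 plates spanning
10–1000 colonies for accuracy and bias, translated copies for ROI
robustness, 18 bubble-only plates, artefact-only and blank plates, fused
dumbbells of 2 and 3 discs, and a 22-colony two-colour plate for the
colour filter. Oracle comparisons (brute-force chamfer paths, a naive
per-threshold score map) run on fixtures of at most 64 × 64 px, where
exhaustive recomputation is cheap.
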