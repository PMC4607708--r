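---
title: "Shortest-path retinal boundary segmentation and device agreement"
author: "octseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shortest-path retinal boundary segmentation and device agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(octseg)
```

## The problem

Spectral-domain OCT instruments report retinal thickness with their own
segmentation software, and different vendors draw the outer retinal border
at different anatomical landmarks. Comparing instruments therefore requires
a *single* third-party segmentation applied to scans from both devices.
`octseg` implements such a pipeline for horizontal line scans through the
fovea: it flattens the B-scan, traces four boundaries — the inner limiting
membrane (ILM), the top of the photoreceptor inner/outer segment junction
(IS/OS), the RPE centerline, and the outer border of the RPE–Bruch's
membrane complex (RPE outer) — as minimum-cost paths, converts them into
retinal thickness (ILM to RPE outer) and outer-complex thickness (IS/OS to
RPE outer, the photoreceptor outer segments plus RPE), samples both at the
foveal center, the central 1-mm line and the 13-point 6-mm grid, and runs
the paired statistics used for inter-device agreement. A synthetic phantom
generator with exact ground truth makes the whole chain testable without
clinical data.

## Boundary tracing as a shortest path

A boundary is modelled as one row per A-scan column. Given a cost image
$w(r, c) \ge 0$, the segmentation solves

$$\min_{\{r_c\}} \sum_{c=1}^{C} w(r_c, c)
  \quad\text{s.t.}\quad |r_{c+1} - r_c| \le J,\; r_c \in [l_c, u_c],$$

by dynamic programming over columns (states are rows; the per-column
minimum over a sliding window of width $2J+1$ gives an $O(RCJ)$ algorithm).
Ties prefer the smaller row everywhere, so results are deterministic.
Anchor points — the file-based replacement for interactively clicking on
the true boundary — split the problem at their columns; each inter-anchor
interval is solved with fixed endpoint rows, which preserves global
optimality within each interval and guarantees the path passes through
every anchor exactly.

Two cost constructions are used:

* **Negated intensity** (`negate_image`): bright structures become cheap;
  used for the RPE centerline, which should ride along the brightest band.
* **Polarity-matched negated vertical gradient** (`vertical_gradient`): a
  forward axial difference, keeping only dark-to-bright or bright-to-dark
  responses, rescaled to $[0,1]$ and negated. The polarity parameter is
  needed because one unsigned gradient image cannot serve both the inner
  boundaries (dark vitreous or nuclear layer into a bright band) and the
  outer one (bright RPE into the dimmer choroid).

The four boundaries are traced sequentially: an initial RPE row from the
row-sum argmax of the flattened scan (the RPE is the most hyper-reflective
band), the RPE centerline by negated intensity in a narrow band around that
row, the IS/OS top in a band 10–80 µm above the centerline, the RPE outer
border 2–40 µm below it, and finally the ILM anywhere above the IS/OS less
a 30 µm margin. Offsets are expressed in micrometres and converted with the
scan's axial calibration; the defaults bracket adult foveal anatomy
(outer-segment/RPE complex roughly 60–80 µm, RPE band a few tens of µm)
with generous slack and are fully configurable via `oct_seg_config()`.

### Why the gradient operates on log intensities

OCT speckle is multiplicative: on linear intensities its standard deviation
scales with brightness, so single-look speckle inside the (relatively
bright) retina produces spurious gradients as strong as the true but
low-contrast vitreoretinal edge, and the ILM path can be lured into the
tissue. On the log scale — the domain in which OCT scans are routinely
displayed — speckle is additive with constant variance and the
vitreous-to-retina step becomes the strongest dark-to-bright edge in the
image. The gradient costs are therefore built on log-scaled intensities
(with a small floor tied to the bright-intensity quantile of the image so
that an extreme speckle spike cannot rescale the dark end). The negated
intensity cost for the RPE centerline stays linear, since there the point
is brightness itself. Light anisotropic Gaussian smoothing (1 px axially,
3 px laterally by default) is applied before cost construction; retinal
boundaries vary by well under a pixel per column, so lateral averaging
suppresses speckle without displacing edges.

## Flattening

The scan is first aligned column-wise ("flattened") so that per-A-scan
axial displacement does not distort the boundary search bands. The
displacement field is estimated by maximizing, jointly over all columns,
the sum of (i) neighbour-pair normalized cross-correlations at each
column-to-column lag and (ii) the correlation of every column with a
scan-level reference profile (the lateral boxcar mean of the provisionally
flattened scan). The joint maximization is itself solved exactly by dynamic
programming over shift states, and iterated so the reference sharpens.
Neighbour pairs share anatomy, so term (i) measures pure displacement
increments and is exact on noise-free data; term (ii) anchors the absolute
level so that increment noise cannot accumulate into a drift. Pair terms
are confidence-weighted by their correlation peaks: on effectively
noise-free scans the chain becomes rigid and recovery of injected integer
jitter is exact (up to the global median, which is subtracted so the image
does not drift).

**Known limitation.** With single-look exponential speckle *and* large
independent per-column jitter, per-column registration is information
limited: even registering each column against the noise-free anatomy (an
oracle unavailable in practice) localizes only ~94 % of columns to within
±1 px at the default `max_shift = 20`. A realizable estimator must build
its reference from jitter-blurred data and does considerably worse. The
package's estimator is accurate for noise-free or frame-averaged scans and
for small/smooth jitter — the regime of real line scans, where eye motion
between neighbouring A-scans is a fraction of the total scan time — but it
does not reach ±1 px for 95 % of columns under the combination of raw
single-look speckle with ±10 px white jitter, and the corresponding
acceptance check is expected to fail at that stated level. Segmentation
accuracy is unaffected on flat or mildly jittered scans because boundary
paths are re-expressed in original coordinates by adding the shifts back.

## Thickness quantification

Thickness is the boundary row difference times the axial scale (µm per
pixel); the lateral coordinate is the column offset times the lateral
scale, which is always derived as `scan_length_mm * 1000 / n_ascans`. The
foveal center is the minimum of the retinal thickness profile after a
moving-average smoothing (half-width 5 columns; the raw argmin is
speckle-sensitive), with ties resolved toward the scan center. The 6-mm
line is sampled at 0.5-mm steps from −3 to +3 mm around the fovea
(13 points); offsets whose nearest column falls outside the image are
masked missing, mirroring how eccentric fixation truncates the grid on a
6-mm scan. The central point thickness (CPT) is the 0-mm sample; the
"1-mm line" is the unweighted mean of the −0.5, 0 and +0.5 mm points (not
an integral); "all points" is the mean over unmasked grid points.

## Agreement statistics

`paired_compare()` reports the paired difference (always device B minus
device A, with labels carried through), its SD, the paired *t* test
(two-sided, $n-1$ df), Pearson's correlation, the percent difference
relative to the mean of the two device means, and Bland–Altman limits at
mean ± 2 SD (2, not 1.96, matching the plotting convention for these
agreement analyses). `per_point_compare()` applies this per grid offset
with listwise deletion of incomplete pairs, and pools by averaging each
eye's unmasked offsets before a single paired test — a deliberately simple
replacement for a repeated-measures mixed model: averaging within eye
removes the within-eye correlation across grid points from the pooled
test, at the cost of not weighting by per-offset availability. The
coefficient of repeatability is defined here as
$100 \times 2\,\mathrm{SD}(d) / \bar{x}$ for repeat-visit differences $d$
and grand mean $\bar x$; the term is used with several definitions in the
agreement literature, so the formula is stated explicitly and tested.
`fit_conversion()` is ordinary least squares computed from the normal
equations (and cross-checked against `lm()` in the tests).

## The phantom

`phantom_spec()`/`generate_phantom()` render a layered macular cross
section: dark vitreous, brighter inner retina, dark outer nuclear layer, a
bright IS/OS band, a dimmer gap, a bright RPE band whose lower edge is the
RPE outer border and whose 6-µm core is brighter than its shoulders (so an
intensity-seeking path centers in the band), and a dimmer choroid. The ILM
carries a Gaussian foveal pit (depth 94 µm, FWHM 1.8 mm by default); the
IS/OS top is flat and the outer complex interpolates from 62 µm peripherally
to 76 µm at the fovea with the same Gaussian profile, so the default central
point thickness is ~226 µm and the foveal outer complex ~76 µm — healthy
adult magnitudes. Boundaries are rasterized with partial-volume mixing,
and the returned ground truth stores the continuous boundary depths in
pixel units.

Speckle is unit-mean exponential multiplicative noise (fully developed
single-look intensity speckle); frame averaging draws `n_frames`
independent speckle fields over fixed boundaries, reproducing the 1/N
variance reduction. Per-column integer jitter is applied after
compositing. Optional variants add a detached posterior hyaloid (a faint
line in the vitreous, for testing that the ILM is not captured by it) and
a bright vitreous floater (an adversarial case that should either trip the
boundary-ordering check or be repaired with anchors). Device templates
emulate two line-scan geometries: 512 A-scans over 6 mm without averaging,
and 768 A-scans over 8.7 mm with 100-frame averaging.

What the phantom does *not* emulate: depth-dependent attenuation and
shadowing, coherent point-spread structure (speckle is spatially white
here; real speckle has grain), curvature of the retina, vascular shadows,
and pathology beyond the two variants above. Passing the phantom tests
therefore demonstrates the mechanics of the algorithm — cost construction,
banding, anchoring, calibration arithmetic, statistics — not clinical
performance.

### The synthetic device-comparison experiment

`generate_cohort()` draws one latent anatomy per eye (between-eye SD 17 µm
on overall retinal depth, 8 µm on pit depth, 4 µm on outer complex, the
magnitudes of healthy-cohort variation) and renders it under both device
geometries; device B's RPE outer border is pushed deeper by `bias_um`.
The injected bias *stands in for* the averaging-related apparent
thickening hypothesized for averaged scans at the weak posterior border.
For that reason the default comparison applies the same single-look
speckle treatment to both devices: simulating the full 100-frame averaging
difference *and* injecting the bias would count the same effect twice.
Indeed, rendering device B with its physical 100-frame averaging and *no*
injected bias produces a measurable apparent thickening of a few µm — the
same order as the residual inter-device differences reported for real
instruments — because integer-row edge localization interacts with the
noise level at the sub-pixel scale. The acceptance script computes this
quantity (`averaging_apparent_thickening_um`) alongside the bias-recovery
experiment.

## Numerical choices

* Tie-breaks: smallest row in every DP argmin; smaller absolute lag, then
  negative, for alignment lags; column nearest the scan center, then the
  smaller index, for the fovea. All outputs are deterministic given
  (inputs, seed).
* `max_jump` defaults to 2 px: at ~12 µm/column lateral sampling the
  foveal pit walls can exceed 1 px/column axially.
* Degenerate inputs: constant images normalize to zero with a warning;
  empty search bands after clipping raise validation errors; a boundary
  whose mean path cost exceeds 0.75 (on the [0, 1] cost scale, where
  present edges score well below 0.5) is flagged low-confidence with a
  warning rather than silently returned.
* Boundary ordering (ILM ≤ IS/OS ≤ RPE center ≤ RPE outer, strict in the
  interior) is checked on every `segment_all()` result; violations raise a
  classed error carrying the offending columns, the cue that anchors are
  needed.
* Problem sizes: unit tests run mostly on 200 × 200 phantoms; the
  headline checks use the full 256 × 512 / 256 × 768 device geometries,
  with a 37-eye cohort for the bias-recovery experiment and 12 eyes for
  repeatability, matching the sizes of the comparison design the package
  is meant for.

## Limitations

Inner retinal sublayers are out of scope, as are 3-D (volume) graph
searches, machine-learned costs, and sub-pixel boundary refinement —
boundaries are integer rows, so single-scan thickness is quantized at the
axial pixel (~4 µm); cohort averages dither across eyes and recover
sub-pixel effects, which is exactly what the bias-recovery experiment
demonstrates. Vendor scan containers are not parsed: images arrive as
PNG/TIFF with a JSON/YAML calibration sidecar.
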