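---
title: "Quantifying hand-hygiene skin coverage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hand-hygiene skin coverage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handcover)
```

## The measurement problem

Fluorescent ("UV") testing is the standard way to check how completely a
person covers their skin with alcohol-based handrub: a fluorescent
concentrate is mixed into the rub, the hands are photographed under a UV
lamp, and treated skin glows green. `handcover` turns pairs of
photographs — one under white light, one under UV, taken in the same
pose — into quantitative, spatially resolved coverage estimates:

1. **Hand segmentation.** The white-light image is converted to the YUV
   colour system (BT.601 full range) and the V (red-difference chroma)
   channel is thresholded with Otsu's method; skin is redder than the
   dark photographic background, so the upper class is the hand. The
   largest connected component is kept and its boundary polygon traced.
   The wrist line — the line through landmark 0 perpendicular to the
   segment from landmark 0 (wrist) to landmark 9 (middle-finger base) —
   cuts off the forearm; its two contour crossings are the wrist
   points, and the hand region above them is the region of interest
   (ROI).
2. **Fluorescence extraction.** The UV image is converted to
   hue-saturation-brightness. Covered skin is green:
   $25 \le H \le 97$ on the 0-179 half-degree hue scale. A brightness
   filter rejects pixels with $0 \le B \le 60$ (0-255 scale), which
   removes residual fluorescence left over from earlier tasks — it
   glows in the same hue band but only dimly.
3. **Template mapping.** Hands differ in shape, pose and perspective,
   so coverage is compared in the frame of a *standard hand template*
   (one per hand side: dorsal/palmar left/right). Both the observed
   hand and the template are split into 18 labelled segments derived
   from the 21 hand landmarks, the wrist points and the four finger-web
   points (valleys between fingers, found as convexity defects of the
   contour). Each observation segment is warped onto its template
   segment by the exact 4-point homography of its corners.
4. **Aggregation.** Mapped observations of the same task and hand side
   are pooled: the coverage probability of a template pixel is the
   fraction of observations that saw it covered among those that saw it
   at all. For display the probabilities are quantized into the four
   categories [0, 0.25], (0.25, 0.5], (0.5, 0.75], (0.75, 1].
5. **Coverage loss.** The coverage of a set of steps of the six-step
   hand-hygiene technique is estimated per pixel as the maximum
   probability over the included steps. Excluding a step and
   subtracting the two combined maps highlights the area only that step
   reaches; the mean of this *exclusive map* over the hand outline is
   the step's scalar coverage-loss fraction.

## The 18-segment layout

The number of segments is fixed at 18, but their exact construction is
this package's own design (the decomposition must only be *identical*
between observation and template for the homographies to be defined):

* three phalanx segments per long finger, split at the MCP/PIP/DIP/tip
  landmarks, with lateral corners cast perpendicular to the local
  finger axis out to the hand contour (capped at 1.5 finger widths,
  falling back to a half-width offset). The finger width is estimated
  as twice the median distance from the joint landmarks to the contour.
  At the fingertip the last station is pushed 0.45 width towards the
  cap apex and given fixed half-width corners, so the rounded tip stays
  inside the distal quadrilateral;
* two thumb segments (CMC-IP and IP-tip; starting at the CMC makes the
  proximal segment cover the thenar junction with the palm);
* four palm (or dorsum) quadrants fanning from the wrist chord (wrist
  point - midpoint - wrist landmark - midpoint - wrist point) up to a
  top chain made of the outer knuckle corners and the three inter-digit
  web points.

The base corners of the long fingers are *snapped to the flanking web
points*, which are also the palm quadrants' top corners: finger and
palm segments share edges exactly and tile the hand without seams. On
the synthetic hand the 18 segments cover about 97.5% of the ROI with
about 3% pairwise overlap (overlaps are resolved covered-wins /
valid-wins when compositing).

Corner order is canonical per segment (named rows such as `base_left`,
`tip_right`), which is the 1:1 correspondence key the per-segment
homographies use.

## Numerical choices

* Pixel coordinates are 0-based `(x, y)` with the origin at the
  top-left pixel centre; rasters are stored column-major
  (`matrix[x + 1, y + 1]`), the EBImage convention.
* Warping uses inverse mapping with nearest-neighbour sampling —
  coverage masks are binary and interpolation would manufacture
  fractional coverage before aggregation. Target-side quads are
  rasterized with a 0.75 px outward expansion so adjacent segments
  leave no one-pixel seams.
* The 4-point homography is solved by the direct linear system (8
  unknowns, normalized `H[3,3] = 1`); quads with three near-collinear
  corners are rejected as degenerate.
* Otsu thresholding fails loudly on a constant channel (a photograph of
  nothing). Foreground is the class with the higher mean chroma.
* Morphological cleanup before contour extraction is available but
  **off by default**: at desk-scale resolutions a 3x3 closing seals the
  raster-thin tips of the finger-web valleys and displaces the detected
  webs by several pixels, while the chroma threshold is already
  speckle-free at realistic noise levels.
* Web points: convexity defects are computed per convex-hull edge, with
  the contour arc split wherever it returns to touch the hull chord
  (several collinear fingertips can share one hull edge). The deepest
  raster point of a V-notch is ambiguous by a few pixels when one
  notch wall runs nearly parallel to the hull chord, so the apex is
  refined as the intersection of straight lines fitted to the two
  walls, with a fallback to the raw deepest pixel when the walls are
  nearly parallel or the intersection is implausibly far away.
* Category boundaries: the quantization intervals are lower-closed on
  the first interval and upper-closed elsewhere, so boundary
  probabilities such as 0.25 have exactly one category.
* Aggregation divides by the *per-pixel* number of valid observations,
  not the total number of observations: error correction removes
  template points without coverage information, and those points must
  not drag probabilities down.
* In step combination, pixels missing from some steps use the maximum
  over the steps where they are defined; in the loss subtraction an
  undefined "without" combination counts as zero. Negative subtraction
  values are clipped at zero (max-combination guarantees non-negativity
  analytically; the clip guards floating-point noise).
* The scalar loss statistic is reported in two variants: the primary
  probability-weighted mean of the exclusive map over the template
  outline (no-data pixels counting as zero), and a thresholded variant
  (fraction of outline pixels with exclusive probability above 0.5).
  The probability-weighted variant is the headline number; the
  inverted *display* map (`1 - exclusive`) is kept separate from the
  scalar statistic because they answer different questions (where is
  loss likely vs. how much area is lost).

## The synthetic study

No photographs ship with the package; a fully ground-truthed generator
stands in for them.

**Hand model.** A parametric hand: a superelliptical palm (exponent 10,
nearly straight-sided), five finger capsules and a forearm capsule, in
a canonical frame with one hand length as the unit. Adjacent finger
capsules converge towards their in-palm anchors and splay about 11
degrees apart at the tips, so each inter-digit gap closes at a sharp,
analytically known crossing of the two facing capsule sides. A V-shaped
notch (half-angle 20 degrees, radius 0.055 hand lengths; 25 degrees
and the thumb-palm crossing for the thumb) is carved at each valley so
the web is a raster-stable concavity whose deepest point is exactly the
stored analytic ground truth — the raw capsule gaps close at an angle
far too shallow for any raster to resolve. Everything the pipeline
later estimates (masks, ROI, landmarks, webs, wrist crossings, covered
fractions) has a closed-form or root-found counterpart in this frame.

**Appearance.** White-light renders are a skin-toned silhouette on a
near-black background with additive Gaussian noise (default sd 3 of
255). UV renders colour covered pixels bright green (hue ~63,
brightness 215), uncovered skin dark blue-grey (brightness 42, inside
the rejection band), and a configurable fraction of remaining pixels as
dim green residue (brightness 48) that the brightness filter must
remove. Rendered images default to 756x1008 px, a quarter of a typical
12-megapixel capture.

**Study design.** Thirty participants perform 22 tasks (9
individual-step tasks and 2 complete-technique repeats per photographed
side), each with both hands — 1,320 image pairs. Coverage is drawn per
step from a region model on the 18-segment layout, so per-segment
expectations are exact. The default model encodes the mechanics of the
six-step technique: step 1 covers the palmar surfaces reliably
(probability 1) except the thumb (0.5); 2R/2L cover the opposite dorsum
(palm quadrants 1.0, proximal fingers 0.9); step 3 re-covers palmar
regions step 1 already covers, and 6R/6L palmar fingertip regions
inside step 1's coverage — these three steps are therefore *redundant
by construction* and their true coverage loss is zero; step 4 covers
the backs of the fingers; 5R/5L the thumbs (0.9). A per-participant
diligence factor `d ~ U(-1, 1)` shifts every fractional probability by
`0.5 * d * min(p, 1 - p)`, creating between-participant variance (and
hence non-degenerate side correlations) without changing population
means; analytic task probabilities integrate it out numerically.

Simulated study images are rendered at 240x300 px and analysed on
360 px templates; these sizes keep a full 1,320-observation study
within minutes on a single core while leaving every pixel tolerance
used in the tests comfortably coarse relative to the raster. The
generator's own default render (756x1008) is used for the
geometry-recovery checks.

**What the generator does not emulate.** Real photographs add texture,
shading, specular highlights, partial rub gradients, imperfect
white-light/UV registration, and landmark-detector failure modes far
richer than Gaussian jitter. Passing the synthetic recovery tests shows
the geometry and accounting of the pipeline are right; it does not
validate the colour thresholds against real skin and real fluorescent
gel, which is inherently an instrument-calibration question.

## What the tests establish

* The raster rules (fluorescence thresholding, mask intersection,
  aggregation ratios, quantization, max-combination) are bit-identical
  to independent per-pixel loop oracles.
* Segment homographies map corners with residuals below 1e-6 px and
  round-trip below 0.5 px.
* From rendered fixtures across random poses and chirality:
  segmentation IoU at least 0.95 against the analytic silhouette,
  wrist points within 2 px, all four web points within 3 px of their
  analytic positions.
* End to end, with 30 simulated participants, every step's recovered
  coverage-loss fraction lies within 0.03 of the design's analytic
  value, the redundant steps (3, 6R, 6L) show less than 1% loss, and
  the max-combination of the nine individual-step maps agrees with the
  complete-technique aggregate in at least 90% of pixels after
  four-category quantization.
* Re-running the analysis with the same seed and configuration
  reproduces the report byte for byte.

## Known limitations

* The 18-segment layout is one defensible reading of "18 segments from
  landmarks and web points"; other layouts would warp slightly
  differently near segment borders.
* Piecewise homographies are exact per segment but only continuous, not
  smooth, across segment edges; coverage that straddles an edge can
  shift by a pixel or two in template space.
* The quality gate (valid-area floor 0.80, no dead segments) is an
  automated surrogate for a human screen of grossly misaligned
  mappings; it does not detect subtle pose mismatch.
* Left/right hands are mapped to their own templates; no mirroring is
  applied, so the four hand sides remain strictly separate populations.
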