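---
title: "Methods: vocal-tract segmentation and outlining from rtMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vocal-tract segmentation and outlining from rtMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtshape)
```

This vignette documents the models and procedures implemented in
`vtshape`, the assumptions they rest on, the tunable parameters and their
defaults, the design decisions taken where the design was genuinely open,
and the known limitations — in particular, what the synthetic phantom does
and does not establish about real scanner data.

## The measurement problem

Real-time MRI of speech yields a dynamic sequence of one mid-sagittal
slice. On T1-weighted images, hydrogen-rich soft tissue is bright and air
is dark, so the vocal tract is the dark corridor between the tongue,
palate, pharyngeal wall and lips. The quantity of interest is the closed
outline of that corridor in each frame.

Two structural assumptions drive the whole design:

* **The tract moves, but does not travel.** The head is stabilised in the
  scanner, so although articulators reshape the tract from frame to frame,
  the set of pixels that could *ever* be tract is fixed for a run. This is
  what licenses a single region of interest (ROI), a single intensity
  threshold, and a single exclusion mask per run, each defined once and
  applied to every frame.
* **Within the ROI, intensity is bimodal.** The ROI contains air and soft
  tissue and little else, so the pooled intensity histogram has a dark air
  mode and a bright tissue mode, and the valley between them is a natural
  classification threshold. Everything that threatens this bimodality
  (intensity inhomogeneity, partial-volume blur, an over-generous ROI)
  threatens the classification, which is why the pipeline flags
  non-bimodal fits instead of guessing.

## Stage 1: variance seeding, threshold fit, classification

`compute_variance_map` uses the population variance (divisor `n`) of each
pixel's time series. Static anatomy scores zero; pixels alternating
between air and labile tissue score high, so the high-variance set traces
the tract's course. `seed_roi` keeps pixels strictly above the
`quantile`-th variance quantile (default **0.75**; the original
interactive workflow leaves the cutoff to the analyst, so the default was
chosen to over-seed mildly and let polygon edits trim). Seeding alone is
deliberately not trusted: it overreaches into other moving structures and
misses static tissue that forms part of the outline (the palate), which is
exactly why `edit_roi` exists. On the phantom, where only the tube
boundary moves, variance seeding recovers just that boundary band — a
useful reminder that the seed is a starting point, not a segmentation.

`fit_threshold` pools ROI intensities across **all frames** of the run
(one histogram, one threshold per run; pooling maximises the sample and
matches the run-level workflow). The density is a Gaussian KDE with
Silverman's rule-of-thumb bandwidth on a **512-point grid** spanning the
observed range. Local maxima count as modes when their density reaches
**5%** of the global maximum — low enough to keep the air mode, which is
usually much smaller than the tissue mode, high enough to suppress noise
wiggles. The threshold is the minimum density between the two most
prominent modes; when several grid points tie, the midpoint of the
minimal-density plateau is used (deterministic). Fewer than two
qualifying modes sets `bimodality_ok = FALSE`, leaves the threshold `NA`,
and warns; classification then requires an explicit threshold from the
analyst. Air is *strictly below* the threshold; a pixel exactly at the
threshold is tissue. The fit is affine-equivariant up to grid resolution:
rescaling intensities `a·I + b` moves the threshold to `a·t + b`.

## Stages 2–3: selection, QA, exclusions

Logged segments are 1-based inclusive frame intervals; overlaps are
unioned silently. TextGrid interval times convert to frames as
`onset = floor(t_min · fps) + 1`, `offset = ceiling(t_max · fps)`,
clamped to the run — a rule that can only over-include at segment edges,
never drop audible material. All internal indices in this package are
1-based inclusive (the natural R convention); the time-to-frame
conversion happens exactly once, in `read_logfile`.

The QA map is the per-pixel mean of the boolean mask series. Exclusions
act on the classified masks, not on the ROI, so stage-1 outputs remain
reproducible; the alternative route — editing the ROI and re-running
stage 1 — is equally available through `edit_roi`. Applying an exclusion
is idempotent.

## Stage 4: A* bridging and outline tracing

Closures (stop consonants, for instance) split the tract mask into
disconnected cavities, and those are often precisely the frames of
interest. The bridge is the minimum-cost 8-connected path from the larynx
anchor to the lips anchor, where stepping into pixel `p` costs

```
(ε + Î(p)) · step_length,     step_length ∈ {1, √2}
```

with `Î` the intensity min–max normalized over the search region and
`ε = 0.01` a positive floor. Penalising *bright* pixels realises the
intent of weighting by the inverse of the T1 signal — the path follows
dim, if not dark, pixels through the constriction — while keeping costs
finite in zero-intensity air (a literal `1/I` would make dark pixels
expensive, the opposite behaviour). The heuristic `ε ×` Euclidean distance
never exceeds the true remaining cost, so the search is admissible and the
returned path globally optimal; the test suite checks exact agreement
with an independent Dijkstra implementation and with exhaustive
enumeration on small grids. Ties are broken by a fixed neighbour
expansion order (N, NE, E, SE, S, SW, W, NW) and an insertion-stable
priority queue, making paths bit-reproducible.

The search region is the **ROI**, not the mask: constrictions are by
definition not in the mask, and the path must cross them through dim
tissue. Anchors are supplied per run; the fallback derives them from the
first non-empty frame (most inferior mask pixel for the larynx, most
anterior for the lips), but explicit anchors are recommended since no
universal rule exists.

`bridge_cavities` is exactly `mask ∪ path` — it never removes pixels, and
the added set is exactly the path minus the mask. `trace_outline` then
extracts the 0.5 iso-level contour of the binary grid (marching squares),
a sub-pixel polygon suited to arc-length resampling. Two raster
pathologies are handled first: interior holes are filled (only the outer
boundary is meaningful), and 2×2 blocks whose true pixels touch only
diagonally — unavoidable along a one-pixel connector — receive one
deterministic filler pixel, since marching squares would otherwise split
the component into several loops. Outlines are oriented clockwise in the
`(y, z)` convention (`y` = column = anterior→posterior, `z` = row =
superior→inferior; clockwise means positive shoelace area with z pointing
down) and rotated to start at the boundary point nearest the lips anchor,
the upper lip-aperture margin. Both conventions matter downstream: equal
arc-length resampling from a shared start site is what puts analysts'
site 37 at comparable anatomy.

## Stage 5: edit scripts

Interactive erase/redraw is replaced by pure functions over outlines and
a JSON edit-script format. Scripts are validated in full before anything
is applied (a half-applied correction session is worse than none), the
audit log records before/after point counts per edit, and an erase
followed by insertion of the same points restores the original outline
exactly. Orientation is re-checked after insertions and restored by
reversal if a splice flipped the signed area.

## Bias-field correction

Scanner shim imperfections leave a smooth multiplicative gain across the
image; local contrast survives but a single global threshold may not. The
corrector is homomorphic: the log of a reference image (temporal mean by
default) is smoothed at a large scale and the exponential of the smooth
trend, normalized to mean 1, is the estimated field. Two details matter:

* Pixels below the **10th intensity percentile** are excluded from the
  fit (bias is a tissue-signal phenomenon; the log of near-zero air is
  unstable noise).
* The smoother is a Gaussian-weighted **local linear regression**
  (first-order 2-D Savitzky–Golay with validity weights), not a plain
  normalized convolution. A local-mean smoother attenuates linear trends
  near image borders and masked gaps, leaving several percent of residual
  ramp; the local-linear form reproduces linear log-fields exactly
  everywhere, which is what makes the estimator idempotent in effect
  (re-estimating on a corrected run gives a field within 2% of flat).

`smoothing_scale` (Gaussian sigma, default **15 px**) sets the shortest
scale the field may vary on; anything anatomical is faster than that,
anything shim-related slower. An order-2 polynomial surface is available
as the alternative `model` tag. Correction is never applied implicitly —
whether pre-processing helps is a per-dataset decision.

## Validation metrics

`dice_score` is `2|X∩Y| / (|X|+|Y|)` on pixel sets (mask series compare
whole runs at once); two empty sets are an error, not a silent 0 or 1.
`resample_contour` places `n_sites` points at arc positions `k·L/n`
along the closed polyline from the start site; correspondence across
analysts comes from the shared start convention plus equal arc length —
no elastic registration is attempted, so a residual component of
"disagreement" is really parameterisation difference. The default common
site count is the largest outline's point count. The contours are
sampled directly as polylines; no functional-data smoothing is applied
before sampling, so site coordinates can differ sub-pixel from a
basis-expansion treatment of the same outlines.
`disagreement_profile` reports, per site, the mean Euclidean distance of
each analyst's coordinate to the group mean, in pixels and in mm
(per-axis scaling first when row/col spacings differ).

## The phantom: what it emulates, and what it does not

`generate_phantom` rasterises a dark tube (air level 0.15, tissue level
1.0, arbitrary units) around a spline centreline shaped like a vocal
tract — inferior-posterior larynx, vertical pharynx, bend, horizontal
oral cavity to anterior lips — in a 64 × 64 frame. Width follows a
per-control-point profile (4–6 px) modulated ±12% sinusoidally over time
(period 25 frames) to mimic articulation; closures interrupt the tube
with tissue at 85% of full contrast (constriction tissue images slightly
dim, which is what the A* connector exploits); noise is additive
Gaussian, seeded per frame as `seed + frame` so frame *k* never depends
on how many frames follow; an optional linear ramp (the bias model)
multiplies last. Intensities are clamped at zero, as in any magnitude
image.

The standard battery (`default_validation_suite`, 64 × 64 × 50) holds
five runs: clean; noisy (σ = 10% of the air–tissue contrast); closure
(frames 15–30 bisected); bias (30% ramp **plus** the default noise); and
combined. The bias run includes noise deliberately: at realistic
air/tissue contrast a smooth gain alone cannot defeat a global threshold
— even at the ramp's bright end, air (≈ 0.15 × 1.3) stays far below any
between-modes threshold — so uncorrected classification on a noise-free
ramp is already perfect and would demonstrate nothing. The failure mode
worth guarding against is the interaction: bias rescales the noise and
slides both modes, eroding the classification margin. Even with noise,
the 30% ramp leaves enough margin that uncorrected Dice stays high on
this phantom; the tests therefore assert that correction achieves
Dice ≥ 0.95, never harms classification, and recovers the true gain
field (correlation > 0.99), rather than asserting a degradation the
geometry cannot produce.

What the phantom does **not** model, and what passing therefore does not
show: anatomy (velum, epiglottis, laryngeal vestibule — the structures
real analysts disagree about), partial-volume blur at tissue boundaries,
Rician noise statistics at low SNR, motion artefacts and k-space
undersampling, or non-linear shim patterns. Phantom results validate the
signal-processing chain — thresholding, bridging, tracing, metrics — not
anatomical judgement; real data still need stages 3 and 5.

Ground truth on closure frames deserves a note: the "true" outline is
defined as the tube bridged along its centreline through the closure,
mirroring what an ideal connector restores. Traced outlines on those
frames follow the A* path instead, so the sub-0.1-px mean errors reported
by the tests include that small, intended difference.

## Numerical and reproducibility choices

* Frames, rows, columns are 1-based; the frame axis is first in memory
  and last on disk (the natural NIfTI/TIFF layout), converted exactly
  once in the I/O layer.
* Outline CSVs store coordinates with 6 decimals (round-trips exact to
  1e-6 px). NIfTI and raw dumps round-trip bit-exactly; the TIFF
  writer's 32-bit storage is integer-scaled, exact only to one part in
  2³¹ per write, so TIFF is the interchange format, NIfTI the archival
  one. Mask TIFFs (8-bit) are bit-exact.
* Pipeline artifacts are written as uncompressed `.nii`: gzip headers
  may embed timestamps, which would break the bit-identical-manifest
  guarantee (`run_pipeline` hashes every artifact with MD5; identical
  config and inputs give identical manifests).
* The tests and the acceptance script run the battery at 64 × 64 × 50 —
  the package's chosen desk-scale problem size, large enough for the
  KDE, the closures and the bridging to behave as on real matrices,
  small enough to iterate on freely.

## Known limitations

* One threshold per run assumes stationarity of the intensity
  distribution; drifting gain within a run needs the bias corrector or
  per-segment runs.
* The A* connector is "biologically plausible", not guaranteed: it
  follows dim pixels, which can hug the wrong wall of a wide
  constriction. Bridged frames are flagged in the status table for
  review.
* Site correspondence across analysts is purely arc-length-based;
  differences in where analysts terminate the tract (lip aperture,
  laryngeal vestibule) shift all downstream sites and inflate apparent
  disagreement there.
* The bias model (log-domain smooth multiplicative field) does not cover
  coil-array sensitivity patterns with sharp spatial structure; those
  need scanner-side correction.
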