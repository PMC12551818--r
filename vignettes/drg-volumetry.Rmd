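---
title: "Measuring mouse DRG size from axial MRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mouse DRG size from axial MRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgvol)
```

## The measurement problem

In mice, lumbar dorsal root ganglia (DRGs) sit directly against the
ventral-lateral surface of the spinal cord, and on T2-weighted axial images
there is no usable intensity contrast between ganglion and cord. A ganglion
therefore cannot be segmented directly; what can be exploited is that the
cord's cross-section changes very little over a millimetre of its length,
while the ganglion spans only ~0.9 mm rostro-caudally. The pipeline in this
package turns that observation into a measurement:

1. **Align** all slices in the dorso-ventral direction (integer-pixel shifts
   maximizing cord overlap with the first reference slice), compensating for
   a cord not perfectly parallel to the magnet axis.
2. **Average** the two cord-only slices immediately rostral to the ganglion
   into a low-noise reference image of the bare cord.
3. **Detect the cord edge** on that reference (3x3 smoothed-gradient
   magnitude, auto threshold 4x the mean gradient, per-component 3x3 closing
   to seal 1-px gaps, innermost closed contour around the cord).
4. **Project** the ganglion-bearing slices by pixelwise maximum (MIP).
5. **Zero** the cord region on the projection and **delineate** the
   remaining hyperintense structure per side.

The delineated pixels are summed: cross-sectional area
`CSA = pixel_count x pixel_area`, the maximal axial cross-section, is the
scalar surrogate for DRG volume. At the default geometry (FOV 2 x 1.5 cm,
matrix 256 x 192) the pixel area is `(20/256) x (15/192)` = 0.0061035 mm^2.
We compute pixel sizes exactly from FOV/matrix rather than from rounded
"78 um" figures: only the exact value makes every reported CSA an integer
multiple of the pixel area, which the I/O layer enforces as an invariant and
the reliability statistics rely on.

Two reading choices deserve mention because the procedure they formalize is
usually described loosely:

* **Only the two rostral (proximal) reference slices are averaged**, never
  distal ones: averaging slices more than ~1 mm apart blurs the cord
  boundary when the cross-section assumption starts to fail, and a blurred
  gradient degrades edge detection.
* **The CSA is the pixel sum of the MIP delineation** (one number per
  ganglion), not a per-slice sum. Phrases like "the delineated pixels were
  added together as the maximal CSA" are ambiguous between the two; the MIP
  reading is the one consistent with a single maximal axial cross-section
  and is what this package implements.

## Replacing manual delineation

The final manual step of the workflow this package automates — outlining the
bright residue "based on higher signal intensity" — is replaced in `auto`
mode by a parameterized rule: pixels above `rel_threshold` (default 1.10)
times the mean projection intensity inside the cord mask, grouped by
8-connectivity; per side, the cord-adjacent component with the largest
overlap of the ventral-lateral quadrant is selected (components further than
`adjacency_px` = 10 px from the cord are considered only if no adjacent one
exists). Components under `min_px` = 5 are rejected as speckle; components
over `max_px` = 200 are kept but flagged as anatomically implausible. A
`manual_roi` mode restricts the same thresholding to user-supplied
per-side rectangles, mirroring the interactive rectangle-ROI workflow.
An absent ganglion on a side is a legal outcome (reported, not an error).

Slice selection (`auto` mode) also had to be formalized. Because ganglion
and cord merge into one foreground component, each slice's cord core is
recovered by a morphological opening (disc of `cord_brush_px` = 11 px —
larger than any ganglion cross-section here, smaller than the cord) after
healing noise holes; the slice score is the summed intensity of
above-threshold pixels outside that core and ventral of its centroid. The
DRG run is the maximal contiguous run of slices scoring more than 1.25x the
minimum-scoring slice plus a tenth of the score range; the additive floor
guards against isolated noise pixels qualifying a cord-only slice when the
minimum score is near zero. The foreground threshold everywhere is
`max(Otsu, median + 5 MAD)`: plain Otsu fails on these images because
background pixels outnumber cord pixels ~100:1, so under noise Otsu splits
the background mode. Both guard terms scale with receiver gain, keeping the
rule invariant to global intensity scaling.

## The phantom: what it emulates, what it does not

The synthetic generator replaces the live animals. It renders analytic
anatomy on the true acquisition grid: an elliptic cord constant across
slices; per-side DRG ellipsoids tangent to the ventral-lateral cord surface
at 45 degrees, spanning 0.9 mm so they occupy the last three of five
0.29-mm slices (the two rostral slices are cord-only); a partially
suppressed peri-ganglion fat ring (spectral fat saturation leaves a
residual rim, and a bright rim is exactly what stresses delineation); and
Rician noise, the magnitude of complex Gaussian noise, which reduces to
Gaussian at high SNR so closed-form checks stay available. Intensities are
arbitrary units (background 100, cord 400, DRG 650, fat 900 suppressed by
0.85, noise sigma 40, i.e. cord SNR 10); no per-animal intensity statistics
are available for the real scans, so these are the package's own choices.

Everything is rasterized by one rule — a pixel belongs to a region when its
centre is inside the analytic ellipse — so the generator can emit *exact*
ground truth: the true pixel count of each ganglion's maximal cross-section
(cord pixels excluded, since the pipeline measures the ganglion outside the
zeroed cord) and its boundary perimeter, which bounds how much any
whole-pixel re-rasterization can change the count. Recovery tests assert
against that band, not against hand-tuned tolerances.

Repositioning between test and retest is modelled as a rigid integer
dorso-ventral shift plus a global intensity scale (gain/coil loading),
with fresh noise, and optionally a per-scan log-normal size factor
(`size_cv`) for physiological and partial-volume variation in the apparent
cross-section. Longitudinal cohorts draw a persistent log-normal
between-animal factor (default CV 0.10) and per-scan within-animal factors
(default CV 0.06, consistent with the ~12% SD of test-retest differences
divided by sqrt(2)); group means follow piecewise-linear trajectories
(wild-type flat at 0.28 mm^2; untreated Fabry rising from 0.30 at week 8 to
0.35 mm^2 at week 24; treated Fabry returning to the wild-type level after
treatment at week 8). Log-normal factors are mean-corrected so group means
land on the trajectory.

The phantom deliberately omits: vertebrae and ribs, B1 inhomogeneity of the
surface coil, respiratory motion, nerve roots and vessels, partial-volume
blur in the slice direction (sections are evaluated at slice centres), and
any Bloch-equation signal physics. Passing recovery tests therefore shows
the pipeline's geometric and statistical machinery is correct under the
stated noise model — not that it is robust to every artifact of real
small-animal imaging.

## Statistics

**Test-retest reliability.** Units are single DRGs (left and right of one
animal kept separate — a documented simplification: the ten units include
two per animal, which are not strictly independent). The intraclass
correlation uses the one-way random-effects, single-measure form: with
`k = 2`, `ICC = (MSB - MSW) / (MSB + MSW)`, mean squares from the one-way
ANOVA of measurement on unit. Bland-Altman limits of agreement are
`bias +/- 1.96 x SD` of the differences, with the n-1 SD and the normal
1.96 multiplier (not a t quantile) — the conventional form, and the one
that reproduces the recorded summary cells exactly. The per-unit relative
difference is `100 x (test_px - retest_px) / pair mean of the counts`,
computed on *integer pixel counts*: the recorded per-unit percentages
(e.g. 19.355 = 100 x 9/46.5) are reproducible only from the counts, not
from the 3-decimal areas, so the package treats the pixel-count form as the
definition and the area form as its rounding.

**Longitudinal comparison.** The two untreated Fabry groups are pooled
(their trajectories do not differ), then compared against wild type by
two-sided pooled-variance Student's t-tests under a closed testing
procedure: test at the pre-specified endpoint (the week of maximal
predicted difference, by default the last); only if significant at alpha,
step backwards while significance holds, and report the earliest week of
the unbroken run. "Earliest time point with a significant difference" is
read literally as that stepwise rule; a scan-all-weeks variant exists for
sensitivity analysis but does not change the reported week. The endpoint
gate keeps the procedure's type-I error at alpha with no further
multiplicity correction (none is applied, matching the analysis it
formalizes). By default the two DRGs of an animal are averaged so each
animal contributes one value per week; whether the original analysis did so
is not stated, so the per-DRG option is exposed (`unit = "drg"`). The
Student (equal-variance) form is the default to match the named test;
Welch is behind a flag.

## Numerical choices and degenerate inputs

* Alignment uses integer shifts only, ties toward zero: sub-pixel
  interpolation would destroy the pixel-count quantization that the
  downstream statistics depend on. A shift landing on the +/-10 px search
  boundary is an error (gross misalignment), not a result.
* The ICC is flagged `undefined` (not returned as a number) when total
  variance is zero; constant data carry no agreement information.
* Two constant, equal samples give `p = 1` with a `degenerate` flag in
  `student_t()`.
* A cord mask that is not a single hole-free component within 200-3000 px,
  an open cord contour, or a DRG placed against the image border all stop
  the pipeline with the stage name attached — silent degradation is worse
  than an error in a measurement tool.
* Slice indices are 1-based everywhere in the R interface, matching the
  "slice No. 1-5" convention of scanner print-outs.
* NIfTI-1 is the primary stack format (voxel sizes in the header, checked
  against any declared geometry within 1%); float TIFF is a fallback whose
  [0,1] storage requires a JSON sidecar carrying the intensity scale and
  geometry. Negative intensities are rejected on read: magnitude MRI is
  non-negative by construction.

## Validation scale

The shipped validation (tests and `analysis/` scripts) uses: exact
reproduction of all derived cells of the ten-unit repeatability table;
noiseless phantom recovery within the perimeter band; 50 noisy phantoms at
cord SNR 10 for the 10% mean-absolute-relative-error budget; 30 trials for
noisy shift recovery; 200 simulated reliability studies for ICC parameter
recovery; and 1000 null cohorts for the closed test's endpoint type-I
error. These sizes give stable Monte-Carlo envelopes at desk scale; they
are the package's chosen problem sizes, stated here so that anyone
re-running the validation knows what the numbers were computed from.

## Known limitations

* The CSA is a single maximal cross-section, not a volume; thinner slices
  or slice-by-slice segmentation would measure volume directly but need
  higher SNR than the emulated acquisition provides.
* The cord mask includes the detected edge band, so it slightly
  over-covers the cord and bites ~1 px into a ganglion's contact strip;
  the resulting small negative bias (visible in the noiseless recovery:
  44 px measured vs 49 px truth, well inside the 20 px perimeter band) is
  the price of the conservative "zero everything within the edge" rule.
* Auto slice selection assumes at least one clearly DRG-free slice in the
  stack; a noisy stack with no ganglion at all may still yield a spurious
  run (the noiseless case errors out cleanly). Config mode exists for
  exactly that situation.
* The reliability analysis treats two DRGs of one animal as independent
  units; a hierarchical model would be more faithful but is not what the
  summary statistics being reproduced assume.
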