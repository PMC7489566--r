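---
title: "Methods: geometric and texture measurements from wrist radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric and texture measurements from wrist radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collesmetrics)
```

## The problem

Dorsally displaced fractures of the distal radius (Colles' fractures) are
routinely treated in emergency departments by closed reduction under
anaesthesia.  A fraction of reductions fail and the patient returns for
surgical fixation.  Whether plain posterior-anterior (PA) wrist radiographs
carry geometric or textural signals that distinguish outcomes is a natural
question, but the standard radiographic measurements are taken by hand and
are slow and observer-dependent.

`collesmetrics` implements a semi-automatic alternative: a user supplies
three landmarks per radiograph — the base of the lunate, the tip of the
radial styloid and the centre of the middle-finger metacarpal — and the
package derives 32 named measurements automatically, then compares them
across a five-group study design (healthy controls, plus fracture cases
split by pre-/post-reduction and successful/unsuccessful outcome) with
per-measurement two-sample tests over seven group contrasts.

## Pipeline

### Preprocessing

Radiographs arrive with variable arm positioning and collimation artefacts.
Preprocessing makes the forearm vertical and removes the collimator frame:

1. **Collimator removal.** On digital radiographs the area outside the
   collimated field is stored as exactly zero, while even the darkest
   exposed tissue stays positive.  Connected components of exactly-zero
   pixels touching the image border are taken as the collimator region,
   dilated by a disc (default radius 5 px) to also swallow the bright field
   edge, and zeroed.
2. **Orientation.** The central third of the image (both axes) is where the
   long bones dominate.  Canny edges are computed there (Gaussian
   smoothing sigma = 2 px; hysteresis thresholds derived from the gradient
   magnitude distribution by Otsu's criterion, low = 0.55 x high) and a
   line Hough transform (angular resolution 0.5 deg) votes over line
   orientations.  The median angle-from-vertical of the strongest peaks (up
   to 5, minimum separation 5 deg / 20 px) is the forearm angle.  Because
   PA positioning keeps the forearm roughly vertical, peaks more than 45
   deg from vertical (collimation edges, joint spaces) are excluded from
   the median.  If no peak reaches the vote threshold the image is assumed
   vertical and a warning is raised.
3. **Rotation.** The image is rotated by the negative of the detected angle
   about its centre with bilinear interpolation onto an enlarged canvas
   (fill 0).  Landmarks given on the original image are mapped through the
   same transform, so users can pick them before or after preprocessing.

All coordinates in the package are 1-based `(row, col)` pairs with row 1 at
the top, matching R matrix indexing; a single convention is used everywhere
to avoid off-by-one drift between modules.

### Forearm widths (measurements 1-10)

Below the lunate the outer forearm boundary (soft tissue, or the cast — no
attempt is made to tell them apart, since swelling under a cast is part of
the signal of interest) is traced per row as the outermost Canny edge pair,
median-smoothed over 11 rows, with missing rows linearly interpolated
(failure if more than 30% are missing).  Eight horizontal width lines are
placed: line 1 at 5 mm below the lunate row (the figure geometry puts the
first line just proximal to the wrist; the offset is configurable), then
one every 10 mm.  W1 is the most distal line.  The ten reported
measurements are ratios (`Wi/W4`, min/max, and two paired sums), so pixel
spacing cancels; spacing enters only through the 1 cm line placement.

### Finger metrics (measurements 11-12)

A square ROI (side 30 mm) around the finger landmark is aligned to the
finger's own axis (strongest Hough line inside the ROI; the global
preprocessing fixes the forearm, not the fingers), and mean intensity per
column is projected.  On this profile, the bone edges are the outermost
crossings of the level halfway between the background (median of the outer
10% of columns) and each cortical peak; the two cortical peaks are the
highest pair of local maxima (prominence at least 5% of the dynamic range)
separated by a genuine valley; the trabecular interval lies between the
crossings of the midpoint between each peak and the central minimum.
Because cortical and trabecular compartments share the ROI height, the
trabecular-to-total *area* ratio reduces to a ratio of interval lengths on
the projection.  The valley requirement exists because a plateau-topped
peak yields local maxima at both plateau ends; without it the "two largest
maxima" could select one band twice.

### LBP texture (measurements 13-22)

A square ROI (side 15 mm) is placed from the two wrist landmarks: from the
styloid, 10 mm along the unit vector toward the lunate and 10 mm
proximally, landing in trabecular bone of the distal radius.  Each interior
pixel's 8 neighbours are compared with the centre (`>=` counts as 1 — ties
must be fixed for determinism; with this rule a constant ROI maps entirely
to the all-ones pattern), in circular order starting east, counterclockwise.
Patterns with at most two circular 0/1 transitions ("uniform") map to their
count of ones; the rest to a tenth catch-all class.  This rotation-invariant
uniform (riu2) mapping with 8 neighbours is the standard LBP variant that
produces exactly 10 coefficients; the normalised 10-bin histogram is
reported.  Only order relations enter, so the histogram is invariant to any
strictly order-preserving intensity change.

### Intensity profiles (measurements 23-32)

Two lines are traced from the styloid at 30 and 45 degrees from the
styloid-to-lunate baseline.  Of the two possible rotation senses, the one
whose first 10 samples are brighter is chosen, so the line crosses the
distal radius rather than leaving the bone.  Sampling is bilinear at 1 px
steps.  The trace ends at the edge of the radius: the first sample below
0.5 x the median of the first quarter of the full-length trace (the sharp
drop into the dark radio-ulnar space).  The early-trace median must itself
exceed 1.2 x the median exposed-field intensity, which rejects profile
lines seeded on dark background.  Per line, five statistics are reported:
least-squares slope over the whole trace, slope over the leading half
("short segment" — the source material does not pin this down; a leading
fraction of 0.5 is used and is configurable), standard deviation raw and
after detrending (subtracting the least-squares line, so slope-driven
brightening does not inflate dispersion), and the trace length in pixels.

### Group statistics

For each measurement, seven contrasts are tested: control vs all fracture
cases, pre vs post, successful vs unsuccessful, the two within-time
outcome contrasts, and the two within-outcome time contrasts.  The default
test is Welch's two-sample t-test: the groups are unequal in size with no
case pairing available, so a paired test is not well defined here (Student
and paired variants are selectable for data where they apply).  Raw
p-values are reported with a significance flag at 0.05 and no
multiple-testing correction, mirroring the usual presentation of this kind
of exploratory table; a Benjamini-Hochberg adjusted matrix can be attached
on request.

## The phantom generator

Clinical radiographs cannot be redistributed, so every stage is validated
on synthetic phantoms with known ground truth (`generate_phantom()`).  The
phantom renders, on a 900 x 700 grid at 0.2 mm/px: a vertical forearm
(soft-tissue band of prescribed width profile) containing two bone bands
(ulna and radius) with bright cortical margins and textured trabecular
interiors; a dark radio-ulnar gap flush against the radius' medial cortex;
a hand region with a finger metacarpal of configurable cortical/trabecular
widths; a bright lunate; landmarks placed on the rendered anatomy; and an
exactly-zero collimator frame.  Trabecular texture is Gaussian-smoothed
white noise (correlation length 3 px, amplitude 15) plus global white noise
(sd 2) on intensity levels background 30 / soft tissue 90 / trabecular
150 / cortical 220 — chosen as plausible relative attenuation levels, not
calibrated to any detector.  Anatomy is rendered upright and rotated with
the same bilinear operator the preprocessing uses, so recovery error in
tests measures detection, not rendering.  Generation is bit-reproducible
under a fixed seed, and the caller's RNG stream is left untouched.

What the phantom does *not* emulate: beam hardening, scatter, the heel
effect, overlapping carpal anatomy, fracture displacement itself, casts,
and annotation markers.  Passing recovery tests therefore show the
geometric machinery is correct under idealised contrast, not that the
measurements are accurate on clinical film; the published clinical
p-values depend on data that is not distributed and are out of scope.

`generate_cohort()` complements this with purely statistical synthesis:
measurement vectors drawn from per-measurement normal baselines with
optional group-level mean shifts, used to verify the testing stage's type-I
error and power without rendering images.

## Numerical choices and degenerate inputs

* Canny/Hough parameters are not published for this pipeline; the defaults
  above are declared in `default_config()` and every stage takes the config
  so a run is fully described by one object.
* Hough peak ties are broken toward the smaller absolute angle; the
  central-third region uses floor for the start index and ceiling for the
  length so the three thirds tile the image exactly.
* Rotation by exactly 0 degrees is an identity fast path (bit-exact).
* Flat images: orientation falls back to 0 with a warning; the finger ROI
  is used unrotated with a warning; boundary tracing and profile tracing
  error with stage-specific messages.
* A failed measurement family yields `NA` for its measurements and a logged
  diagnostic; the case survives, and `compare_groups()` drops non-finite
  values pairwise with a count.
* Anisotropic DICOM pixel spacing is rejected beyond 1% disparity
  (isotropy is assumed by the centimetre geometry); `MONOCHROME1` images
  are re-inverted so bone is bright; integer payloads pass through
  bit-exactly.

## Problem sizes

The test-suite and acceptance workloads use the default 900 x 700 phantom
(about 2 s per full pipeline run on one core), 20 phantoms for the
orientation-recovery error, 20 random ROIs for the LBP oracle equivalence,
and 1000 simulated null datasets for the type-I error of the testing
stage; the complete suite runs in about a minute.

## Limitations

* Landmarks are consumed from files; no interactive picker is bundled.
* Widths measure the outer boundary, cast included, by design.
* The LBP analysis is single-scale (3 x 3, 8 neighbours); no multi-radius
  or frequency-domain texture measures.
* No effect sizes, power analysis, or classification — the package stops
  at the per-measurement contrast table.
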