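# collesmetrics

Semi-automatic geometric and texture analysis of posterior-anterior wrist
radiographs, built for studies of dorsally displaced distal-radius
(Colles') fractures treated by closed reduction.  Given a radiograph and
three manually placed landmarks — base of the lunate, tip of the radial
styloid, centre of the middle-finger metacarpal — the package preprocesses
the image automatically and extracts **32 named measurements**, then
compares them across a five-group study design (control, pre-successful,
pre-unsuccessful, post-successful, post-unsuccessful) with per-measurement
two-sample tests over seven group contrasts.

## What it computes

**Preprocessing.** The forearm is made vertical by detecting Canny edges in
the central third of the image, voting over line orientations with a Hough
transform, and rotating by the median angle θ of the strongest
near-vertical peaks; the exactly-zero region outside the collimator is
detected as border-connected zero components, dilated and removed.

**Measurements.** With pixel spacing *s* (mm/px):

* *Forearm widths (1–10).* Outer boundary columns L(r), R(r) traced below
  the lunate; eight width lines W₁…W₈ at 10 mm spacing (first 5 mm below
  the lunate), Wᵢ = R(rᵢ) − L(rᵢ); reported as the ratios Wᵢ/W₄
  (i ≠ 4), min W/max W, (W₁+W₈)/(W₄+W₅), (W₁+W₂)/(W₇+W₈) — a swelling
  signature.
* *Finger (11–12).* Column-mean projection p(c) of a locally aligned
  metacarpal ROI; bone edges at half-rise crossings, cortical peaks, and a
  trabecular interval between peak-to-valley midpoint crossings give the
  finger width and the trabecular/total area ratio — an osteoporosis-style
  radiogrammetry signature.
* *LBP texture (13–22).* Rotation-invariant uniform local binary patterns
  over 3×3 neighbourhoods in a radius ROI placed from the two wrist
  landmarks: LBP(riu2, P=8) has exactly 10 pattern classes; the normalised
  histogram is reported.
* *Intensity profiles (23–32).* Two lines traced from the styloid at 30°
  and 45° from the styloid→lunate baseline up to the edge of the radius
  (intensity dropping below half the early-trace median); per line:
  least-squares slope (full and leading half), standard deviation (raw and
  detrended), and length.

**Statistics.** For each measurement, Welch two-sample t-tests (Student /
paired selectable) over the seven contrasts: control v patient, pre v
post, successful v unsuccessful, and the four pairwise time/outcome
contrasts; raw two-sided p-values with significance flags at 0.05.

A synthetic phantom generator (`generate_phantom()`) renders wrist-like
radiographs with known rotation, width profile, finger compartments,
radius mask and landmark positions, so the whole pipeline is testable
without clinical data.

## Worked example

```r
library(collesmetrics)

ph  <- generate_phantom(phantom_params(rotation_deg = 12, seed = 5))
pre <- preprocess_radiograph(ph$radiograph, ph$landmarks)
pre
#> <wrist_preprocess> rotation 12.00 deg, 5 Hough line(s), 295086 collimator px

vec <- run_case(ph$radiograph, ph$landmarks)
round(vec[c("W1 / W4", "Min width / Max width", "Trabecular Area / Total Area",
            "Width Finger", "LBP 4", "Slope profile 1 (full line)",
            "Std profile 1 adjusted", "Distance profile 1")], 3)
#>                      W1 / W4        Min width / Max width
#>                        1.000                        1.000
#> Trabecular Area / Total Area                 Width Finger
#>                        0.603                       40.997
#>                        LBP 4  Slope profile 1 (full line)
#>                        0.195                       -0.021
#>       Std profile 1 adjusted           Distance profile 1
#>                       22.668                      118.000
```

The phantom was rotated by 12° and the pipeline recovered 12.00°; its
forearm has constant width, so all width ratios are 1; the finger was
rendered with 8 px cortical bands around a 24 px trabecular core, true
ratio 24/40 = 0.6, recovered 0.603; the first profile line crossed 118 px
of radius before hitting the dark radio-ulnar gap (ground truth 117 px).

Group comparison on a synthetic cohort with a planted post-reduction shift
in one texture coefficient:

```r
eff <- list("LBP 4" = c("post-successful" = 2, "post-unsuccessful" = 2))
cmp <- compare_groups(generate_cohort(12, effect_spec = eff, seed = 9))
round(cmp[cmp$measurement == "LBP 4", -(1:2)], 4)
#>    Control v Patient Pre- v Post- Successful v Unsuccessful
#> 16            0.0626            0                    0.1466
#>    Pre-Successful v Pre-Unsuccessful Post-Successful v Post-Unsuccessful
#> 16                            0.1103                              0.1392
#>    Pre-Successful v Post-Successful Pre-Unsuccessful v Post-Unsuccessful
#> 16                                0                                    0
```

Only the contrasts that cross the pre/post divide light up, as planted.

A command-line front end over the same functions is provided in
`inst/cli/collesmetrics.R` (`phantom`, `preprocess`, `measure`, `study`
subcommands); see `vignettes/methods.Rmd` for the full account of the
method, its parameters and its limitations.

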