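Package: collesmetrics
Title: Geometric and Texture Measurements from Wrist Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic analysis of posterior-anterior wrist radiographs.
    Radiographs are automatically rotated so that the forearm is vertical
    (Canny edges followed by a Hough-transform vote over line orientations)
    and collimator border artefacts are removed.  Anchored on three manually
    supplied landmarks (base of the lunate, tip of the radial styloid and the
    centre of the middle-finger metacarpal), the package extracts 32 named
    geometric and texture measurements per radiograph: ten forearm-width
    ratios from eight width lines spaced 1 cm apart, finger width and the
    trabecular-to-total area ratio from a projected intensity profile, ten
    rotation-invariant uniform local binary pattern coefficients from a
    radius texture region, and ten statistics from two intensity-profile
    lines traced at 30 and 45 degrees from the lunate-styloid baseline.
    Group differences across a five-group study design (control and four
    fracture groups) are summarised with per-measurement two-sample tests.
    A synthetic phantom generator with known ground truth supports
    validation of every stage without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
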