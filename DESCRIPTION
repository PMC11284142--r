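Package: torsionCT
Title: Tibial Torsion Measurement from Axial CT Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes pediatric tibial torsion from labeled 2D landmarks
    traced on two axial CT slices per tibia. Implements the four axial
    angle measures used in clinical practice and research -- the proximal
    transtibial angle (PTTA), the posterior margin tibial plateau angle
    (PMTPA), the intermalleolar angle (IMA), and the talar angle (TA,
    built from the perpendicular to the bisector of the talar facet
    tangents) -- together with the derived torsion angles TTA1 and TTA2.
    Includes a synthetic landmark cohort simulator with known ground-truth
    angles, fibular positional variability and rater placement noise, and
    the accompanying statistical pipeline: normality-gated summaries,
    paired method comparisons, Pearson correlation with Fisher-z
    confidence intervals, and two-way ANOVA intraclass correlation
    coefficients with reliability banding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
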