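---
title: "Measuring tibial torsion from axial CT landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tibial torsion from axial CT landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsionCT)
```

## The measurement problem

Tibial torsion is the axial rotation of the distal tibia relative to the
proximal tibia. In children it is normally external and its disorders are a
common reason for pediatric orthopedic consultation, because torsion drives
the foot progression angle during gait. On CT the torsion angle is obtained
by drawing one reference axis on a proximal axial slice (at the level of
the growth plate) and one on an ankle slice (the first axial section
through the talar body, distal fibular epiphysis and medial malleolus), and
subtracting their angles to the image horizontal.

This package computes four such axes from labeled 2D landmark point sets,
in millimetres, one set per slice per tibia:

* **PTTA** (proximal transtibial angle): a circle is fitted to each tibial
  plateau arc (medial and lateral); the transtibial axis joins the two
  fitted centers.
* **PMTPA** (posterior margin tibial plateau angle): the total
  least-squares line through the posterior-margin points of the plateau.
* **IMA** (intermalleolar angle): the line through the centroids of the
  medial (tibial) and lateral (fibular) malleolus point sets.
* **TA** (talar angle): tangent lines are fitted to the medial and lateral
  talar facets; the talar axis is the perpendicular to the anteroposterior
  bisector of the two tangents. It approximates the geometric axis of the
  tibiotalar joint and, unlike the IMA, is independent of the highly
  variable position and ossification of the distal fibula.

Each axis angle is taken to the image horizontal, folded into
(&minus;90, 90] degrees, and signed anatomically: internal rotation
negative, external positive. The torsion angles are differences,
distal minus proximal, so external torsion is positive:

* `TTA1 = IMA - PMTPA`
* `TTA2 = TA - PMTPA`

## Conventions and their rationale

**Coordinates.** x grows to image-right, y grows anteriorly, angles are
counterclockwise from +x. Clinical workstations differ here; the package
fixes one self-consistent convention and exposes it, because every
invariant below is testable only once the frame is pinned down.

**Axes are undirected.** A direction and its negation name the same drawn
line, so all angle arithmetic is modulo 180 degrees with the canonical
representative in (&minus;90, 90].

**Laterality.** Published protocols rarely state how left and right limbs
map onto signs. Here a right-sided raw angle is kept as measured (anterior
up, image-right = patient-left) and a left-sided one is negated. The
consequence, enforced by tests, is that mirroring a landmark set about any
vertical line while swapping the recorded side leaves every anatomical
angle unchanged — both limbs of one patient are directly comparable. The
`side` field is an explicit input, never guessed from the image.

**Bisector disambiguation for the talar axis.** Two bisectors of the facet
tangents exist, 90 degrees apart: the talus' anteroposterior axis and its
mediolateral axis. For a near-sagittal talus the anteroposterior bisector
is simply the one closer to vertical, and `bisector_direction()` implements
exactly that rule for generic use. `measure_ta()`, however, must stay
correct for strongly rotated taluses (reference cohorts contain talar
angles beyond 45 degrees, where a closest-to-vertical rule flips the
answer by 90 degrees), so it identifies the anteroposterior bisector from
the structure labels: the talar axis is the bisector representative better
aligned with the medial-to-lateral facet direction. That choice is
rotation-equivariant at any talar orientation and coincides with the
closest-to-vertical rule whenever the talus is near neutral.

## Numerical choices

* **Circle fit**: algebraic (Kåsa) least squares — closed-form,
  deterministic, exact on points from a true circle. At landmark noise
  scales (tenths of a millimetre on ~12 mm plateau arcs) it agrees with
  the geometric orthogonal-distance fit to well under the placement noise;
  the test suite checks both exactness on perfect arcs and agreement with
  an independent geometric optimiser in the small-noise regime. On short
  arcs with large noise the algebraic fit has a known inward bias; at the
  noise levels this package targets that bias is negligible.
* **Line fit**: total least squares (principal direction of the centred
  scatter), not regression of y on x, because facet tangents and
  near-vertical margins would break an ordinary regression.
* **Malleolar centers**: centroids of the marked point sets. A circle fit
  per malleolus was rejected: malleolar arcs are short and a three-point
  circle through a short arc is numerically unstable.
* **Degenerate input** (collinear "arcs", coincident centroids, too few
  points) raises an error naming the structure label and tibia, and batch
  measurement (`measure_cohort()`) converts per-tibia errors into reported
  exclusions rather than aborting the cohort.

## What the simulator emulates

`simulate_cohort()` generates landmark files with known ground truth so
that the whole pipeline — geometry, batching, statistics — can be validated
against a recovery target. Per tibia it draws three independent truths:

| parameter | default | meaning |
|---|---|---|
| `proximal_mean`, `proximal_sd` | &minus;7.6, 14.2 deg | true PMTPA (= PTTA) distribution |
| `distal_mean`, `distal_sd` | 17.2, 16.9 deg | true talar angle distribution |
| `fibular_offset_mean`, `fibular_offset_sd` | 5.8, 4 deg | fibular contribution to IMA &minus; TA |
| `rater_noise_sd` | 0.5 mm | isotropic landmark jitter per rater &times; session |
| `raters`, `sessions` | 2, 2 | measurement replicates |
| `proximal_skew` | 0 | skew-normal shape for proximal truths |

The angle means and SDs are the published summary values for a 200-tibia
pediatric reference cohort (see `reference_angle_summary()`); the fibular
offset mean is that cohort's IMA&minus;TA difference, and its SD is chosen
so that the implied IMA&ndash;TA correlation
$\sigma_t/\sqrt{\sigma_t^2+\sigma_f^2} \approx 0.97$ sits in the
excellent range reported for the two distal methods. The rater noise of
0.5 mm is a calibration, not a published fact: it places simulated ICCs in
the 0.92&ndash;0.999 band reported for trained raters, and it is an exposed
parameter precisely because it is a modeling choice.

Geometrically, each tibia is a rigid rotation of a canonical zero-angle
template: the proximal slice is rotated by the proximal truth (making
PTTA = PMTPA exact by construction, which turns the observed equivalence
of the two proximal methods into a testable identity); on the ankle slice
the talus and medial malleolus rotate by the talar truth while the fibular
malleolus rotates by the talar truth plus *twice* the fibular offset.
Because both malleolar centroids lie on the same 25 mm circle about the
talar center, the chord through them then makes exactly
`distal_talar + fibular_offset` with the horizontal — so the simulated IMA
equals TA plus the fibular offset identically, reproducing the mechanism
(fibular positional variability) believed to drive the discrepancy between
the two distal methods. Rater noise is applied to landmark *coordinates*,
not to angles, so reliability statistics reflect geometry-propagated error
as in the manual protocol.

What the simulator does **not** emulate: realistic bone contours (arcs and
segments stand in for traced cortices), correlation between proximal and
distal truths within a limb (truths are independent, so simulated TTA
variances are the sums of the component variances — larger than in real
cohorts, where whole-limb positioning induces positive correlation),
within-patient correlation of the two sides, slice-selection error, and
pathology. Passing recovery tests therefore demonstrates correctness of
the geometry and statistics, not clinical equivalence on real tracings.

## The statistical pipeline

The analysis layer mirrors a standard method-feasibility workflow:

* **Summaries** (`summarize_angles()`, `angle_summary_table()`): the full
  row (n, missing, mean, median, SD, range) is always computed; a
  Shapiro&ndash;Wilk gate at &alpha; = 0.05 marks whether mean &plusmn; SD
  or median [range] is the appropriate display.
* **Paired comparisons** (`paired_compare()`): paired Student t when the
  differences pass the same normality gate, Wilcoxon signed-rank
  otherwise (zero differences dropped, normal approximation). The branch
  can be forced for calibration studies. All-zero differences are reported
  as a degenerate case with no test statistic.
* **Correlation** (`pearson_with_ci()`): product-moment r with the
  Fisher-z 95% interval.
* **ICC** (`icc()`): single-measure intraclass correlation from the
  two-way ANOVA mean squares. The default is two-way random effects with
  absolute agreement, ICC(A,1) — the conservative form for feasibility
  claims, since systematic rater offsets count against it; the two-way
  mixed consistency form ICC(C,1) is selectable. Confidence bounds use the
  standard F constructions (Satterthwaite degrees of freedom for the
  agreement form). Reliability bands: poor &lt; 0.5, moderate
  0.5&ndash;0.75, good &gt; 0.75&ndash;0.9, excellent &gt; 0.9.
* **Reliability designs** (`reliability_study()`): the intra-observer arm
  uses one rater's two sessions on a 22-image subset, the inter-observer
  arm two raters' first sessions on a 44-image subset, drawn
  deterministically from a seed. Published feasibility reports are
  ambiguous about whether an "image" is a tibia or a patient; here an
  image is a tibia, and both subset sizes are parameters.
* **No multiplicity correction** is applied: p-values are reported
  unadjusted, matching the descriptive use of these comparisons; this is a
  documented choice, not an oversight.

Torsion is computed per tibia and then summarized (never as a difference
of cohort means) — the only order compatible with reporting an SD for the
torsion angle itself. Tibias, not patients, are the analysis unit;
side-within-patient clustering is a documented limitation.

## Problem sizes and determinism

The test suite validates geometry against independent oracles (a geometric
circle optimiser, the scatter-matrix eigenvector, a `stats::aov` ANOVA
decomposition), runs recovery and symmetry sweeps on simulated cohorts of
200 tibias and 1,000 randomized templates, and calibrates the paired tests
on 1,000 null replicates per branch — sizes chosen so the full suite runs
in well under a minute while keeping Monte-Carlo error far below the
tolerances being asserted. Every stochastic step (cohort truths, landmark
jitter, reliability subsets) is driven by explicit seeds; identical specs
and seeds produce byte-identical landmark files.

## Limitations

* 2D only: slice selection and perpendicularity to the bone axis are the
  caller's responsibility, as in the manual protocol.
* No image processing: the package starts from labeled points exported by
  any upstream tool (the CSV/JSON schema is the documented extension
  point); it does not read DICOM volumes or segment bone.
* The talar-axis disambiguation relies on correct medial/lateral facet
  labels; with swapped labels the axis is still a valid bisector but the
  anatomical interpretation is the caller's error to avoid.
* The simulator's independence assumptions (see above) make simulated
  torsion SDs conservative upper bounds on real-cohort SDs.
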