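# torsionCT

Tibial torsion measurement from labeled 2D landmarks on axial CT slices,
for pediatric orthopedic research and for validating torsion-measurement
protocols in simulation.

Tibial torsion — the axial rotation of the distal tibia relative to the
proximal tibia — is assessed on CT by drawing one reference axis on a
proximal axial slice (at the growth-plate level) and one on an ankle
slice, each measured against the image horizontal with internal rotation
negative, and subtracting: torsion = distal − proximal. The package
implements the four axis constructions in use:

| angle | axis construction |
|---|---|
| PTTA | line through the least-squares circle centers of the medial and lateral tibial plateau arcs |
| PMTPA | total-least-squares line along the posterior margin of the tibial plateau |
| IMA | line through the centroids of the medial (tibial) and lateral (fibular) malleolus point sets |
| TA | perpendicular to the anteroposterior bisector of the tangents to the medial and lateral talar facets |

and the derived torsion angles `TTA1 = IMA − PMTPA` and
`TTA2 = TA − PMTPA`. The talar angle is the interesting one: it tracks the
geometric axis of the tibiotalar joint and is immune to the distal
fibula's positional and ossification variability, which systematically
inflates the IMA.

Around the geometry sit (i) a synthetic cohort simulator that generates
landmark files with known true angles, a controlled fibular IMA−TA offset
and per-rater landmark placement noise, and (ii) the statistical pipeline
used in method-feasibility studies: normality-gated summaries, paired
t / Wilcoxon comparisons, Pearson correlation with Fisher-z intervals, and
two-way ANOVA intraclass correlation coefficients with the usual
poor / moderate / good / excellent banding.

## Worked example

A single synthetic tibia with known truth, measured back:

```r
library(torsionCT)
tib <- synthesize_tibia(proximal = -8.8, distal_talar = 18.3,
                        fibular_offset = 5.8, side = "right",
                        subject_id = "demo")
measure_pmtpa(tib$proximal)
#> PMTPA = -8.800 deg  (demo / right, rater NA, session NA)
measure_ta(tib$ankle)
#> TA = 18.300 deg  (demo / right, rater NA, session NA)
measure_ima(tib$ankle)
#> IMA = 24.100 deg  (demo / right, rater NA, session NA)
compute_torsion(measure_pmtpa(tib$proximal), measure_ta(tib$ankle))
#> [1] 27.1
```

The proximal slice reads −8.8° (internally rotated plateau), the talus
18.3° externally rotated, and the intermalleolar axis 24.1° — the talar
truth plus the 5.8° fibular offset. The TTA2 torsion is
18.3 − (−8.8) = 27.1° of external torsion.

A full simulated cohort (100 subjects = 200 tibias, two raters × two
sessions, 0.5 mm landmark noise) and its statistics:

```r
co  <- simulate_cohort(cohort_spec(n_subjects = 100, seed = 7))
rec <- measure_cohort(cohort_replicate(co, rater = 1, session = 1))$records
angle_summary_table(rec)
#>   method   n missing  mean median   sd   min  max shapiro_p display
#> 1   PTTA 200       0 -5.67  -4.23 13.5 -40.3 30.1     0.272 mean_sd
#> 2  PMTPA 200       0 -5.73  -4.43 13.5 -40.3 31.3     0.314 mean_sd
#> 3    IMA 200       0 22.38  21.09 18.2 -20.1 71.1     0.730 mean_sd
#> 4     TA 200       0 16.43  16.47 17.8 -30.9 63.7     0.924 mean_sd
paired_compare(rec$ima, rec$ta)
#> paired-t: mean difference 5.946 deg, statistic 20.27, p = 2.729e-50 (n = 200)
pearson_with_ci(rec$ima, rec$ta)
#> r = 0.9736 [95% CI 0.9652, 0.9800], p = 5.679e-129 (n = 200)
reliability_study(co, "intra", seed = 7)
#> <reliability_study> intra-observer, 22 tibias
#>   PTTA  ICC = 0.9983 [95% CI 0.9959, 0.9993], excellent (two-way-random-absolute; 22 x 2)
#>   PMTPA ICC = 0.9936 [95% CI 0.9836, 0.9974], excellent (two-way-random-absolute; 22 x 2)
#>   IMA   ICC = 0.9995 [95% CI 0.9988, 0.9998], excellent (two-way-random-absolute; 22 x 2)
#>   TA    ICC = 0.9923 [95% CI 0.9815, 0.9968], excellent (two-way-random-absolute; 22 x 2)
```

The paired comparison recovers the simulated fibular offset (5.9° vs the
generating 5.8°) with the same excellent IMA–TA correlation and ICC regime
reported for trained raters on real CTs.

Real data enter through the documented landmark CSV/JSON schema
(`read_landmarks()`, one labeled point per row; see `?slice_structures`)
exported by any tracing tool, and a thin command-line wrapper is included:

```sh
Rscript inst/cli/torsionct.R simulate --n 20 --seed 1 --out cohort/
Rscript inst/cli/torsionct.R measure cohort/landmarks.csv --out records.csv --skip-bad
Rscript inst/cli/torsionct.R stats records.csv --design compare --out report
```

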