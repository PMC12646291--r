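# pdscore

Preoperative risk scoring and outcome validation for pilonidal disease.

Pilonidal disease is a chronic sinus-tract condition of the natal cleft with
recurrence rates of 5–30% after excision, and no widely accepted staging
system to match operative technique to disease severity. The
**Hazem-Talaat score** addresses this with a simple additive chart over nine
preoperative factors; `pdscore` implements that chart as a configurable
scoring engine, together with the full statistical pipeline a surgical team
would use to validate such a score on a cohort: descriptive summaries,
normality-gated two-group tests, ROC analysis and diagnostic metrics, plus
synthetic-cohort generators for testing the pipeline without patient data.

## The score

For a patient with factor levels \(x_1,\dots,x_9\), the score is the plain sum
\(S=\sum_{j=1}^{9} w_j(x_j)\) with chart weights:

| factor | levels → points |
|---|---|
| BMI (kg/m²) | ≥ 30 → 2, < 30 → 1 |
| sex | male → 2, female → 1 |
| hairy back (hard-textured) | yes → 2, no → 1 |
| diabetes mellitus | yes → 3, no → 1 |
| previous surgery with recurrence | yes → 3, no → 1 |
| number of midline pits | < 5 → 2, 5–10 → 4, > 10 → 6 |
| pits lateral to the midline | yes → 3, no → 1 |
| nearest pit to anal verge | > 5 cm → 1, ≤ 5 cm → 3 |
| previous abscess | yes → 3, no → 1 |

Totals range from 10 to 27; patients with \(S \ge 21\) are classified high
risk for recurrence. Two chart boundaries (BMI exactly 30, distance exactly
5 cm) are resolved toward the higher-risk level by default and are
configurable predicates (see the methods vignette).

The validation battery follows the original study design: Pearson χ²
(no continuity correction) with Fisher-exact / Monte-Carlo (Patefield
fixed-margin sampling) fallbacks when > 20% of expected counts fall below 5;
Shapiro–Wilk gating into pooled-variance *t* or Mann-Whitney *U* (midranks,
tie-corrected variance, `U = min(U1, U2)`); trapezoidal AUC (≡ concordance
probability) with Hanley–McNeil or DeLong intervals; Youden-optimal cutoff;
sensitivity/specificity/PPV/NPV at a cutoff.

## Worked example

Score one patient (obese hairy-backed man, 7 midline pits, prior recurrence
and abscess, pits 4 cm from the anus, no diabetes or lateral pits):

```r
library(pdscore)
r <- list(sex = "male", bmi = 34, hairy_back = TRUE, diabetes = FALSE,
          prior_recurrence = TRUE, n_midline_pits = 7L, lateral_pits = FALSE,
          distance_to_anus_cm = 4, prior_abscess = TRUE)
compute_score(r)
#> Hazem-Talaat score breakdown
#>   bmi                    2
#>   sex                    2
#>   hairy_back             2
#>   diabetes               1
#>   prior_recurrence       3
#>   n_midline_pits         4
#>   lateral_pits           1
#>   distance_to_anus_cm    3
#>   prior_abscess          3
#>   total                  21
classify_risk(21)
#> [1] "high"
```

The total of 21 sits exactly at the high-risk threshold: this patient would
be a candidate for a flap-based repair rather than simple off-midline
closure.

Validate the score on the built-in deterministic reconstruction cohort
(156 patients whose group-conditional counts equal the published validation
tables exactly):

```r
scored <- score_cohort(reconstruct_fixture())
rep <- compare_groups(scored)          # one row per variable
head(as.data.frame(rep)[c("variable", "test_name", "statistic", "p_value")])
#>             variable    test_name statistic   p_value
#> 1                sex   chi_square     6.607 1.016e-02
#> 2                age mann_whitney  1267.000 8.536e-01
#> 3                bmi    student_t    -3.812 1.986e-04
#> 4 operative_time_min    student_t    -4.164 5.196e-05
#> 5           diabetes fisher_exact    28.495 9.670e-06
#> 6   prior_recurrence fisher_exact    26.477 1.113e-05

roc_report(scored$score, scored$recurrence, cutoff = 21)[
  c("auc", "youden_cutoff", "sensitivity", "specificity", "ppv", "npv")]
#> $auc           0.9068383
#> $youden_cutoff 21
#> $sensitivity   63.16
#> $specificity   98.54
#> $ppv           85.7
#> $npv           95.1
```

The χ² column reproduces the published statistics (6.607 for sex, 28.495
for diabetes, …) because the fixture's cell counts are exact; sensitivity
63.16% and specificity 98.54% at the ≥ 21 cutoff are the published
performance row, and Youden's J selects 21 itself.

A command-line surface wraps the same pipeline:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pdscore", package = "pdscore"))')
Rscript $CLI fixture  --out cohort.csv
Rscript $CLI score    --input cohort.csv --out scored.csv
Rscript $CLI validate --input cohort.csv --out report     # TSV + JSON bundle
Rscript $CLI simulate --out sim.csv --mode prospective --n 500 --seed 7
```

## Scope notes

No weight re-fitting (the chart is expert-defined), no multivariable
modelling, no multiple-testing correction, and apparent (resubstitution) ROC
performance only — each mirrors the validated design; report footers say so.
See `vignettes/pdscore-methods.Rmd` for modelling assumptions, boundary
conventions, simulator limitations and design decisions.
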