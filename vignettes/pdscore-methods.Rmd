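---
title: "Methods and design notes for pdscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for pdscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdscore)
```

## The model

The Hazem-Talaat score is a purely additive expert-weighted point system
over nine preoperative factors: weight status (BMI), sex, back-hair
character, diabetes, prior surgery with recurrence, midline pit count,
lateral pits, distance of the nearest pit to the anal verge, and prior
abscess. For a patient record $x$ the total is
$S(x) = \sum_{j=1}^{9} w_j(x_j)$, ranging from 10 (every factor at its
lowest level) to 27 (every factor maximal), with $S \ge 21$ labelling a
patient high-risk for post-excision recurrence. Additivity means factors
contribute independently; there are no interaction terms, and the bounds of
$S$ are simply the sums of per-factor minima and maxima (verified in the
tests against exhaustive enumeration of all $3 \cdot 2^8 = 768$ level
combinations).

The score is strictly preoperative: `compute_score()` never reads outcome
fields, and the comparison layer (`compare_groups()`) conversely never
touches a weight table — the `score` row of a report uses a pre-computed
column.

### Boundary conventions

The published chart leaves three edges undefined, which we resolve once and
expose as configurable predicates:

* **BMI exactly 30** scores 2 (the WHO obesity convention `BMI >= 30`);
  `at_boundary = "below"` flips it.
* **Distance exactly 5 cm** scores 3, the higher-risk side (conservative:
  a pit at 5 cm is treated as near the anus).
* **Pit bins** follow the non-overlapping convention of the cohort
  descriptive table: $[0,5) \to 2$, $[5,10] \to 4$, $(10,\infty) \to 6$.
  (The chart's printed "0–5 / 5–10 / >10" overlaps at 5; the descriptive
  table's "less than 5 / 5–10 / more than 10" does not, so we follow it.)

Default weights are positive integers; custom tables accept any
non-negative reals (the bounds logic is unchanged), and are loaded from a
one-factor-per-block DCF file validated on load.

## The statistical battery

All tests are two-sided with significance judged at $\alpha = 0.05$, and no
multiplicity correction is applied (the reproduced design applies none; the
report footer states this).

* **Categorical variables** are cross-tabulated against the outcome and
  tested with the uncorrected Pearson statistic
  $X^2 = \sum (O-E)^2/E$, $E = \text{row} \times \text{col} / N$. *No Yates
  continuity correction is applied anywhere*: on 2×2 tables the uncorrected
  statistic equals $N(ad-bc)^2/((a{+}b)(c{+}d)(a{+}c)(b{+}d))$, and this
  closed form reproduces all nine published comparison statistics to three
  decimals, which it would not with the correction — that identity is the
  empirical proof of the convention, and it is asserted in the tests.
* **The 20% expected-count rule**: when more than 20% of cells have
  $E < 5$, the asymptotic p is replaced by Fisher's exact test (2×2) or a
  Monte-Carlo p (larger tables). The reported *statistic* remains the
  Pearson $X^2$ in all cases, matching the convention of the published
  table, which prints $X^2$ next to a Fisher-flagged p.
* **Fisher's exact test** uses the probability-mass two-sided rule (sum of
  hypergeometric probabilities no larger than the observed table's), the
  dominant software convention; the doubling rule would differ and is not
  offered.
* **Monte-Carlo p** simulates tables with both margins fixed (Patefield
  sampling via `r2dtable`) and uses the add-one estimator
  $(1 + \#\{X^2_{sim} \ge X^2_{obs}\})/(R+1)$, which cannot return 0.
  Default $R = 10{,}000$ with a caller seed; the caller's RNG state is
  restored. One numerical note: the sampler draws from the *exact*
  conditional null, whose tail differs from the continuous $\chi^2$ tail by
  the mass of the observed atom. For multi-df tables with large expected
  counts the two agree to Monte-Carlo precision (tested at 3 MC standard
  errors), but for 2×2 tables the lattice is so coarse that the asymptotic
  tail is the wrong reference at any practical size; the tests therefore
  validate the 2×2 case against the exactly enumerated conditional tail
  instead — a stronger check, not a looser one.
* **Continuous variables** are gated by a Shapiro-Wilk test on pooled
  within-group mean-centred residuals (the source design does not say
  whether gating was per-group or pooled; residual-pooled gating is our
  stated assumption, and it uses all $n$ without multiplying tests).
  Normal: pooled-variance two-sample $t$ with $n_1+n_2-2$ df. Non-normal:
  Mann-Whitney $U$ with midranks, reported as $U = \min(U_1, U_2)$ (the
  scale the published table uses), exact null distribution for tie-free
  data with $n_1 n_2 \le 400$, otherwise a normal approximation with
  tie-corrected variance and a 0.5 continuity correction.
* **Descriptives** use the sample SD ($n-1$) and type-7 linear-interpolation
  quantiles for median/IQR — the common statistical-package default, stated
  here because the source never defines its convention.
* A curiosity the implementation deliberately does not copy: the published
  comparison table labels its BMI, age and operative-time statistics
  "$\chi^2$", yet the BMI and age values match pooled-variance $t$
  statistics computed from the printed summaries, and operative time is
  printed on a $U$ scale. We follow the stated methods (t / Mann-Whitney
  for continuous data), not the labels.

## ROC analysis

`roc_curve()` sweeps every distinct score value as a threshold under the
rule *score ≥ threshold ⇒ predicted positive* (higher score means
recurrence), yielding a monotone staircase from (0,0) to (1,1). The
trapezoidal area equals the Mann-Whitney concordance probability
(concordant pairs plus half-ties over $n_+ n_-$) — asserted to $10^{-9}$
against brute-force pair counting — and is invariant under strictly
increasing transforms of the score.

The AUC interval uses the Hanley-McNeil standard error by default (DeLong's
structural-components variance behind a flag), normal approximation,
clipped to $[0,1]$; the p-value tests AUC = 0.5. The published interval's
method is unstated, so neither method is asserted to reproduce it — with
only the printed summary data the patient-level AUC is not recomputable at
all, which is why the acceptance battery substitutes property checks for
it.

The optimal cutoff maximizes Youden's $J = \text{sens} + \text{spec} - 1$
(the standard reading of "optimal threshold"; closest-to-corner is
available behind a flag), with ties broken toward higher specificity, then
higher threshold. Diagnostic metrics keep exact ratios internally and are
rounded half-up only at the reporting layer, to the published precision
(2 decimals for sensitivity/specificity, 1 for PPV/NPV). PPV/NPV are
reported as undefined — not zero — when no positive (negative) call is
made. All reported performance is apparent (resubstitution); there is no
cross-validation, and the JSON report says so.

## Synthetic cohorts

### What the generators emulate

The **reconstruction fixture** (`reconstruct_fixture()`) is a deterministic
156-patient cohort that reproduces, *exactly*, every group-conditional
categorical cell of the published comparison (137/19 outcome split, sex
90/47 vs 18/1, diabetes 11 vs 10, prior recurrence 15 vs 11, infection 0 vs
3, pit bins 79/47/11 vs 4/3/12, lateral pits 27 vs 15, hairy back 48 vs 16,
near-anus 23 vs 15, abscess 35 vs 14) and the confusion matrix implied by
the published sensitivity/specificity at the ≥ 21 cutoff (TP 12, FP 2,
FN 7, TN 135). Because the joint covariate distribution is not published,
the fixture is *one admissible completion* of those margins, built by a
capacitated exact-fill allocation: twelve recurrent "high" patients carry
the base set {male, >10 pits, lateral pits, ≤5 cm, abscess} (21 points)
with remaining attributes stacked so that exactly one of them scores
exactly 21; two non-recurrent patients carry every maximal attribute; all
other patients have frozen point targets ≤ 20 that absorb the remaining
attribute counts exactly. The targets deliberately give the non-recurrent
group a heavy upper tail (4 patients at 20, 4 at 19, …): without it,
Youden's J is not uniquely maximized at 21 — thresholds 17–23 tie or win —
so cutoff selection on the fixture would not reproduce the published
choice. With it, J peaks uniquely at 21 and the resubstitution AUC is
0.907, close to the published 0.912.

Continuous fields are deterministic mid-probability normal quantiles with
the printed group means/SDs, clipped to the printed ranges; the BMI ≥ 30
indicator is kept consistent with the continuous values (rounding is
guarded at the 30 boundary). Group score means come out 14.01 / 22.21
against the printed 13.96 / 22.11; the recurrent SD (2.9 vs printed 4.5)
and the non-recurrent maximum (27 vs printed 25, forced by the all-maximal
spec of the two false positives) are known, accepted discrepancies —
best-effort, not invariants. Hospital stay, drain-removal day and wound
dehiscence match the whole-cohort marginals only (the source conditions
none of them on recurrence). The construction has no randomness; repeated
calls are byte-identical.

The **conditional simulator** draws each covariate independently given the
outcome from the transcribed group-conditional prevalences and moments
(clipped normals for continuous fields). The **prospective simulator**
draws covariates from whole-cohort marginals and generates recurrence from
$\text{Bernoulli}(\text{logit}^{-1}(\beta_0 + \beta_1 S))$. The packaged
slope $\beta_1 = 0.35$ is a moderate per-point log-odds chosen to give
realistic discrimination; $\beta_0 = -7.5047$ was calibrated once (by
`calibrate_intercept()`, 50,000-score sample) so the marginal recurrence
rate is the published 12.2%, and then frozen.

### What they do not emulate

Variables are independent given the outcome (conditional) or mutually
independent (prospective): the source prints only marginals, so no joint
dependence (e.g. BMI–diabetes correlation) is modelled. A green test
therefore establishes that the pipeline recovers the stated marginal
structure and effect direction — not that the generators mimic real
patients' covariance. The fixture likewise fixes only margins; statistics
that depend on the unpublished joint structure (the published $U$
statistics 229.5/632.5, the AUC CI 0.831–0.993) are *not* reproduced, and
the acceptance battery replaces them with oracle-equivalence and
calibration properties.

## Numerical choices and degenerate inputs

* Fisher probability comparisons use a $(1 + 10^{-7})$ relative slack so
  that floating-point noise cannot drop the observed table from its own
  tail.
* Both-SDs-zero with equal means returns $t = 0, p = 1$ by convention;
  with unequal means it is an error (infinite statistic).
* A constant variable in a comparison yields statistic 0 / p 1 with a
  degenerate-variable warning rather than an error; a constant vector at
  the normality gate is surfaced as non-normal (W is undefined).
* An all-tied ROC input produces the two trivial endpoints, $J = 0$ and a
  warning; PPV/NPV are `NA` when undefined.
* Monte-Carlo and simulator seeds go through an RNG-state-restoring
  wrapper, so library calls never clobber a caller's random stream.
* CSV round-trips are locale-fixed: comma-separated, UTF-8, booleans 0/1,
  missing as empty fields.

## Known limitations

* The weight chart is expert-defined; no re-fitting from data is offered by
  design, and the package takes no position on the chart's external
  validity.
* Monte-Carlo p-values target the conditional (fixed-margins) null; see the
  note above on comparing them with asymptotic tails.
* Hanley-McNeil intervals undercover for very small positive groups; DeLong
  is available but both are normal approximations.
* The fixture's continuous fields are quantile-spaced, so within-group
  rank-based statistics on them are smoother than real data would give.
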