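---
title: "Validating the Swiss staging model of accidental hypothermia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating the Swiss staging model of accidental hypothermia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypostage)
```

## The problem

Accidental hypothermia — an unintentional drop of core body temperature
below 35 °C — is staged at the bedside with the Swiss model: four clinical
stages defined by the level of consciousness and the presence of vital
signs, each linked to a typical core-temperature range (32–35, 28–32, 24–28,
< 24 °C). Treatment decisions (withholding defibrillation, transport to an
ECLS centre, estimating cardiac-arrest risk) hinge on temperature, but a
reliable low-reading thermometer is often unavailable in the field, so the
clinical stage is used as a temperature proxy. `hypostage` implements the
statistical machinery for asking how good that proxy is: concordance between
stage and measured temperature, per-stage temperature distributions, and the
temperature thresholds that best separate adjacent stages.

## Stage assignment

`assign_clinical_stage()` encodes the rules: stage 4 requires the absence of
all three vital signs (respiratory rate 0, no measurable blood pressure, no
palpable pulse) together with GCS 3 or AVPU 'U'; otherwise stage follows
consciousness (GCS 15 → 1, 9–14 → 2, 3–8 → 3; AVPU A → 1, V → 2, P/U → 3).
Three design points deserve notice, because the prose definitions alone do
not make the four rules mutually exclusive:

- **The vital-signs check runs first.** GCS 3 or AVPU 'U' with vital signs
  present is stage 3; without them, stage 4. Under any other ordering the
  stage-3 and stage-4 definitions overlap.
- **GCS takes precedence over AVPU** when both are recorded, because it is
  the finer-grained scale. Permuting the AVPU value of a case with a
  recorded GCS never changes the assigned stage (property-tested).
- **Absence of evidence is not evidence of absence.** "No measurable blood
  pressure" is a recorded zero; a missing value never contributes to the
  stage-4 criterion. Records claiming absent vital signs with GCS > 3 are
  inconsistent and raise an error rather than being silently staged
  (`stage_cohort(on_error = "skip")` drops and logs them instead).

Shivering is deliberately *not* an input: it is documented too rarely to
stage on, and mixing it with consciousness can put one patient in two
stages. The package only tallies it (`shivering_summary()`).

Temperature bins are half-open, lower-inclusive: bin 1 = [32, 35), bin 2 =
[28, 32), bin 3 = [24, 28), bin 4 = (−∞, 24). The four bins partition
(−∞, 35) exactly, which is property-tested on a 10,000-point grid.

## Concordance analysis

`correspondence_table()` cross-tabulates clinical stage against temperature
bin. A case on the diagonal is correctly classified; above the diagonal the
measured temperature is *colder* than the stage's range, i.e. the stage
**overestimates** the patient's temperature (the dangerous direction —
potential under-triage); below the diagonal it **underestimates** it. This
direction convention is fixed by arithmetic: in the packaged published
counts the above-diagonal sum equals the published overestimation count
(55 of 305).

The proportion correct gets a binomial CI. The default is the Wald interval,
which reproduces the published rounding for 185/305 — (55%, 66%) — and the
Wilson score interval (via `prop.test(correct = FALSE)`) is available and
rounds identically there; both are exercised in the tests.

Per-stage summaries (`stage_summary()`) report mean ± sample SD, range, a
Student-t 95% CI for the mean (t rather than normal multiplier, since stage
groups can be as small as n = 8), and a 90% prediction interval as the
empirical 5% and 95% quantiles, so that an individual new patient falls
below or above the interval with 5% probability each. Quantiles use linear
interpolation between order statistics with plotting position
(k − 1)/(n − 1) (`stats::quantile` type 7), exposed as `quantile_type` for
sensitivity analyses; with n = 5 values {20, 22, 24, 26, 28} this gives
(20.4, 27.6), a hand-checkable case frozen in the tests.

## Adjacent-stage ROC and optimal thresholds

For two adjacent stage groups, sensitivity at threshold *t* is the fraction
of the *higher* (colder) stage group with temperature strictly below *t*,
and specificity the fraction of the *lower* group at or above *t*. The
optimal threshold maximises sensitivity + specificity (equivalently the
Youden index J). Candidate thresholds are the distinct observed temperatures
(clinical temperatures are recorded to 0.1 °C) plus one value 0.1 above the
maximum so the curve reaches specificity 0; an exhaustive 0.01 °C grid
search is used as an oracle in the tests, never as the implementation. Ties
in J are reported in full, and the largest tied threshold is selected by
default — the clinically conservative end, since a higher threshold flags
more patients as possibly colder; `tie_rule = "smallest"` inverts this.

AUC is computed from the rank (Mann-Whitney) statistic with midranks, i.e.
the probability that a random higher-stage case is colder than a random
lower-stage case with ties credited ½ — grid-independent by construction,
and verified against an all-pairs brute-force count in the tests.

`adjacent_thresholds()` also evaluates sensitivity + specificity (on the
percent scale, so the sums are comparable to published "160 vs 161"-style
figures) at the historical cutoffs 32/28/24 °C.

## The synthetic cohort generator

No patient-level data are distributable, so the package ships a generator
(`generate_cohort()`) whose defaults encode the study conditions:

- 305 cases, 122 hospital / 183 literature; stage mixes per source from the
  published stage-by-source counts (hospital 79/23/12/8, literature
  10/24/68/81) — hospital cases concentrate in stages 1–2, literature cases
  in 3–4.
- Per-stage core temperature: a truncated normal **moment-matched** to the
  published per-stage mean ± SD (33.2 ± 1.6, 29.4 ± 3.0, 26.0 ± 3.4,
  22.8 ± 4.3 °C), truncated at the published observed ranges for stages 2–4.
- Consciousness uniform over the stage's admissible GCS set with a
  consistent AVPU value; stage-4 cases get absent vital signs; stages 1–3
  get stage-ordered plausible vitals. Re-staging a generated case always
  recovers its generating stage, and every generated case passes the
  eligibility filter (both property-tested).
- Shivering documented with probability 19/122 for hospital cases (present
  in 14/19 of documented ones) and undocumented in literature cases, whose
  source reports essentially never documented it.
- Age, sex, cause, survival and CPC are flavour fields with source-indexed
  frequencies; they make the comparison report exercise realistic code
  paths but are *not* calibrated beyond their marginal frequencies.

### Moment matching

`moment_matched_truncnorm()` finds parent parameters (μ, σ) whose truncation
to [a, b] has exactly the requested mean and SD, by nested one-dimensional
root finding: the truncated mean is strictly increasing in μ at fixed σ, and
the mean-matched truncated SD is increasing in σ, so two nested `uniroot`
calls converge reliably where a joint Newton iteration can escape into
regions where the normalising constant underflows. Truncated moments use
tail-switched CDF differences so strongly one-sided truncations stay
numerically stable. Residuals are required to be below 10⁻⁶ in both moments,
and an independent quadrature oracle (`integrate` on the renormalised
density) confirms the matched moments to 10⁻⁴ in the tests.

**Feasibility is not automatic.** With the mean pinned, the SD attainable by
a truncated normal on [a, b] is bounded above by the SD of the family's
tilted-exponential limit — often far below the naive (b − a)/2 bound. The
published stage-1 moments (mean 33.2, SD 1.6) are *infeasible* under
truncation at the observed stage-1 range (28.1–34.9 °C): the attainable SD
there is below 1.50 (the error message reports the bound, and a test pins
it). The default configuration therefore truncates stage 1 at the physical
plausibility floor of 10 °C instead of the observed minimum, keeping the
observed maximum 34.9 as upper bound. The resulting stage-1 density is the
unique member of the family with those moments: monotone increasing towards
34.9 with a long thin left tail (about 1% of draws below 28.1) — a
reasonable shape for mild hypothermia, where cases cluster just under the
35 °C threshold. Stages 2–4 reproduce their published mean, SD *and* range
simultaneously.

Generated temperatures are rounded to 0.1 °C, as clinical thermometers
record them. A fixed seed yields bit-identical cohorts (`withr::with_seed`
around a single draw sequence).

## Comparison tests

The hospital-versus-literature report (`build_table2_report()`) uses
Pearson's chi-square without continuity correction, switching to Fisher's
exact test when any expected cell count is below 5 (the conventional rule;
the choice had to be fixed here since "accordingly" does not define one);
pooled-variance Student t (Welch by flag); and the Wilcoxon rank-sum test.
All p-values are two-sided. The small-sample Wilcoxon (smaller group ≤ 8)
computes an exact p by complete enumeration of rank assignments — midranks
included, so exactness survives ties, which `wilcox.test` cannot offer —
with the two-sided p as twice the smaller tail, capped at 1; larger samples
use the tie-corrected normal approximation. Fisher's two-sided p is the
probability-mass convention (sum of tables at most as probable as the one
observed). Degenerate inputs (constant groups, all-missing variables) yield
flagged rows, never crashes. Each test's type-I error is checked by
simulation (10,000 replicates under its null at n = 20–100 per group, fixed
seed) to lie in [0.03, 0.07] at nominal 0.05.

## Pipeline and problem sizes

`run_pipeline()` sequences eligibility → staging → concordance (by stratum)
→ per-stage summaries → adjacent-stage ROC → comparison, skipping (with a
recorded reason) any block whose preconditions fail — counts-only input runs
just the concordance block; a single-source cohort skips the comparison.
Reports carry a provenance block (package version, seed, configuration
hash) and contain no timestamps, so identical inputs give byte-identical
JSON. `render_report()` writes JSON (lossless), CSV per tabular block, and a
markdown summary rounded to 0.1 °C / whole percent.

The test suite sizes its simulations to stay quick while keeping Monte Carlo
error well inside the asserted tolerances: moment-recovery checks use
40,000-case cohorts (per-stage standard errors ≤ 0.05 °C), threshold
recovery uses ~5,000 cases per stage, type-I error checks 10,000 replicates,
and the enumeration batteries for Fisher/Wilcoxon cover every input with
total n ≤ 10.

## Known limitations

- The generator reproduces *marginal* per-stage temperature moments and the
  stage-by-source mix, not any within-source temperature heterogeneity
  (published stage-1 means differ between hospital and literature cases),
  joint correlations with vitals, or outcome processes. Passing pipeline
  tests on synthetic cohorts demonstrates correctness of the computations,
  not the clinical accuracy of the staging model on new data.
- The empirical Youden threshold is an argmax over a flat criterion: where
  two adjacent generating densities cross at a shallow angle (stages 2|3
  here), its sampling spread at a few thousand cases per stage is of the
  same order as a few tenths of a degree, so recovered thresholds should be
  read with that granularity in mind.
- Published per-stage prediction intervals cannot be recomputed from the
  packaged counts (they need the individual temperatures); the package
  recomputes them for any patient-level or synthetic cohort instead.
- The eligibility filter implements the screening funnel (age ≥ 18,
  temperature < 35 °C, no confounder, stageable) with first-failing-reason
  accounting; the original chart-review ordering of criteria is not
  documented, so exclusion *counts per reason* depend on this package's
  fixed order when a case fails several criteria.
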