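---
title: "Phenotyping advanced CKD from routine hospital records: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping advanced CKD from routine hospital records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdphen)
```

## The problem

Healthcare-integrated biobanking collects surplus routine samples
(serum, urine) from hospitalised patients for disease-specific research
cohorts. For a CKD biobank this requires deciding — quickly, and from
the electronic health record alone — whether an admitted patient has
advanced chronic kidney disease, here operationalised as an estimated
glomerular filtration rate (eGFR) persistently below 60 mL/min/1.73 m².
The decision is hard for two reasons: a single admission creatinine is a
noisy snapshot (laboratory variability, and transient acute kidney
injury can depress eGFR in a kidney-healthy patient), and the
documentation sources that retrospective studies lean on — ICD-10
billing codes and discharge summaries — miscode CKD at appreciable
rates.

`ckdphen` implements the resulting pipeline end to end: feature
extraction from longitudinal records, rule-based and model-based
classifiers, and a validation harness in which a *gold standard* (chart
review; in the synthetic world, generator truth) and a *silver standard*
(labels assigned by a strong automated classifier) can be compared.

## eGFR and its inversion

All kidney-function estimates use the CKD-EPI 2009 creatinine equation
without the race factor:

$$\mathrm{eGFR} = 141 \cdot \min(S_{cr}/\kappa, 1)^{\alpha} \cdot
\max(S_{cr}/\kappa, 1)^{-1.209} \cdot 0.993^{\mathrm{age}} \cdot
1.018\,[\text{female}]$$

with $\kappa$ = 0.7 (women) / 0.9 (men) and $\alpha$ = −0.329 / −0.411.
The equation is continuous and strictly decreasing in creatinine, so it
has a closed-form piecewise inverse (`invert_egfr_to_creatinine()`),
which the synthetic-data generator uses to place patients at exact
target eGFR values. The round trip is tested to 10⁻⁶ relative error;
creatinine is handled in mg/dL throughout (µmol/L inputs are divided by
88.4 at ingestion), and eGFR values are carried at full precision — any
rounding happens only at report rendering.

Non-positive or non-finite inversion targets raise an error rather than
being clamped: a generator configuration that asks for an impossible
eGFR should fail loudly.

## AKI conventions

Two detectors run on each stay's creatinine series:

* **KDIGO creatinine criteria** (`detect_aki_kdigo()`): a rise of at
  least 0.3 mg/dL within 48 h, or a value at least 1.5 × baseline within
  7 days. KDIGO leaves the baseline operationalisation open; we use the
  *rolling minimum over the 7 days preceding the candidate elevation*, a
  common choice that needs no pre-admission baseline. Urine-output
  criteria are out of scope (no urine data in the record model).
* **Reverted AKI** (`detect_reverted_aki()`): a value below 66 % of the
  maximum over the preceding 7 days — the recovery signature that
  distinguishes transient injury from chronic disease. This is a pure
  ratio rule and therefore scale-invariant, which the property tests
  exploit; the absolute-rise arm of KDIGO deliberately is not.

Both detectors sort by timestamp first, so they are invariant to record
order, and return `FALSE` on singleton series.

## Predictor profiles

Three nested profiles feed the classifiers, ordered by when their
inputs become available:

| profile | features | available |
|---|---|---|
| `admissionHIB` | age, sex, admission eGFR | at admission |
| `historyHIB` | + mean eGFR over previous stays (+ missing-history indicator) | at admission |
| `historyCKD` | + length of stay, discharge/mean eGFR, eGFR counts (total, < 60), KDIGO AKI, reverted AKI, three utilisation ratios, max-eGFR < 60 index classifier (15 features) | at discharge |

Conventions the tables do not decide for us, fixed here once:

* *Admission eGFR* is the first non-missing creatinine of the index
  stay (ties broken by stable input order), with no time cap.
* *Thresholds are strict*: an eGFR of exactly 60 is not "< 60".
* *Zero denominators*: the three history ratios are 0 when a patient
  has no previous (or no measured) stays; `mean_egfr_history` falls back
  to the admission eGFR with a `history_missing` indicator, keeping
  admission information dominant for history-free patients rather than
  dropping them. (A creatinine-based history mean instead of eGFR would
  be a defensible alternative; eGFR was chosen because it is the
  age/sex-normalised quantity every other feature uses.)
* Intervals are half-open [admission, discharge); "minimum stay of
  three days" means ≥ 72 h; "age > 18" is strict at index admission.
* The index stay is the first stay inside the evaluation window by
  default; a longest-stay policy is available because multiple in-window
  stays have no canonical resolution.
* Exclusion rules run in a fixed order (age → minimum stay → ED
  discharge → missing eGFR) and each excluded patient is logged once
  with the first failing rule, so selection flowcharts sum exactly.
  The gold cohort profile applies all four rules; the silver profile
  applies only age and missing eGFR.

## Classifiers

The *rule-based* classifiers mirror what registries typically use: an
index-stay eGFR threshold (default aggregation `max_lt`, i.e. even the
best value of the stay is below 60 — `any_lt` and `all_lt` are shipped
because published wordings are ambiguous), ICD-10 prefixes (default
N18.3/N18.4/N18.5/N18.9, targeting advanced stages; fully configurable
since no canonical set exists), and the binary discharge-summary CKD
mention.

The *model-based* classifiers are unpenalised maximum-likelihood
logistic regressions — with 3–5 predictors, regularisation buys nothing
and costs interpretability. Complete separation is detected and flagged
(optionally resolved by a light ridge refit via glmnet, recorded in the
model metadata). Decision cutoffs are calibrated on training scores
only, by maximising the Youden index J = sensitivity + specificity − 1
over the midpoints between consecutive distinct scores plus the lowest
score; ties resolve to the lowest threshold, and a score exactly at the
cutoff classifies positive. The published reference cutoffs (0.586 for
historyHIB, 0.478 for admissionHIB) ship as annotated constants
(`reference_cutoffs()`) for workflow parity; all executable models are
refit because the original development data are not redistributable.

The silver-standard labeler is a seeded probability forest (ranger, 500
trees) on the full `historyCKD` profile — deterministic given its seed,
as a labeler that defines a cohort must be.

## Evaluation harness

`classification_metrics()` reports the six standard metrics with Wilson
score intervals (Clopper–Pearson optional; the interval method is
always tagged in the output). The F1 interval treats
2tp/(2tp + fp + fn) as a count ratio — an approximation, carried with
the same tag. Metrics with zero denominators are flagged `undefined`
and reported as `NA`, never coerced to 0; this protects the degenerate
all-negative cohort.

AUROC is the trapezoidal area over the threshold-annotated ROC
polyline, which equals the Mann–Whitney probability of correct ranking
with ties counted ½ — the test suite verifies this identity against an
O(n²) pairwise oracle, and against pROC as an independent
implementation. The AUROC interval is DeLong's (via pROC). AUPRC uses
the step-wise area without linear interpolation between PR points
(linear PR interpolation is optimistically biased); its interval is a
seeded stratified bootstrap. `reconstruct_matrix_from_rates()` bridges
published rate tables back to integer confusion matrices
(tp = round(sens · n₊), tn = round(spec · n₋)) and reports the
round-trip drift, so rate grids that are not integer-consistent with
the stated class sizes are visible instead of silently accepted.

## The synthetic EHR generator

Real inpatient records of this kind are access-restricted, so the
package ships a generator (`generate_cohort()`) whose defaults *are*
the study conditions of the package's experiments:

* **Cohort structure**: ~63 ± 15 years, 58 % male; CKD prevalence 0.12
  (validation-style; 0.48 for development-style cohorts), with an
  age-dependent CKD logit (0.09 log-odds/year, intercept re-calibrated
  internally to hold the marginal prevalence) yielding an age–CKD
  point-biserial correlation around 0.35–0.40 — the band reported for
  real hospital CKD cohorts.
* **Kidney function**: baseline eGFR uniform on [15, 50] for CKD and
  [65, 110] for non-CKD (medians ≈ 33 and ≈ 88, matching published
  admission-eGFR quartiles of such cohorts); creatinine by exact
  inversion, then multiplicative lognormal noise with configurable CV
  (mean exactly 1) and optional AKI excursions — piecewise-linear
  multipliers rising to a peak (default 2.5×) over 2 days and recovering
  over 3, which by construction produce both KDIGO-positive and
  reverted-AKI-positive patterns.
* **Documentation errors**: ICD-10 coding at sensitivity 0.93 /
  specificity 0.87 and discharge summaries at 0.86 / 0.68 — the error
  profile published for these sources; comorbidity codes
  (cardiovascular, diabetes, liver, malignancy) at class-conditional
  rates mirroring the published cohort tables.
* **Structure**: one index stay inside the 2018-01 … 2020-04 window
  plus a Poisson number of previous stays (history since 2011); stay
  lengths uniform 3–14 days so the three-day rule only bites where
  configured; a 5 % fraction of patients becomes a single short (1–5
  day) emergency-department stay to exercise the ED exclusion.
* **Reproducibility**: every patient draws from an own sub-stream
  derived from (seed, patient index), so generation is
  order-independent and byte-identical across runs.

What the generator does *not* emulate — and what passing tests
therefore cannot show about real data: assay or inter-laboratory drift,
informative missingness (sicker patients measured more often),
non-stationary disease progression between stays, medications,
urine-based AKI evidence, and free-text summaries (the flag is binary
by construction). Synthetic results demonstrate that the pipeline's
machinery is correct and well-calibrated, not that the published
real-data performance transfers.

## Experiment design and problem sizes

`run_training_experiment()` wires the stages together (simulate → link
→ include → features → 80/20 split → fit → Youden on training only →
test metrics). The "informative history" configuration used in the
experiments — noise CV 0.2, per-stay AKI probability 0.25 for non-CKD
patients, ~2.5 previous stays per patient — encodes the mechanism that
motivates history-aware phenotyping: a single admission eGFR is blurred
by noise and admission-overlapping AKI, while the mean over many
pre-index values is not. Under it, the history-aware model dominates
the admission-only model in test F1 in a clear majority of seeds, the
qualitative pattern reported for the real development cohort (91.2 %
vs 85.5 % F1 there; exact values are not reproducible without the
restricted data).

`run_silver_validation_experiment()` is the gold-versus-silver
analogue: models and the forest labeler are trained on a
development-style cohort (prevalence 0.48) and validated on an
independent low-prevalence cohort, where each HIB model is scored both
against truth and against the forest's silver labels. At the defaults
the labeler's held-out F1 is ≈ 0.95–0.99, gold-vs-silver kappa ≈ 0.9,
and the silver-vs-truth F1 drift a few points — the behaviour that
justifies silver-standard validation in the first place.

Cohorts of 350–400 patients and 20-seed replications are used
throughout the tests and the acceptance script; they are large enough
that the Monte-Carlo bounds asserted (binomial prevalence recovery,
coding-rate recovery, dominance majorities) are comfortably informative,
and small enough that the full suite re-runs in minutes on a laptop.

## Known limitations

* The historyHIB history mean uses eGFR, not creatinine; both appear in
  the literature and the package exposes the eGFR variant only.
* The KDIGO baseline convention (rolling 7-day minimum) is one of
  several in use; absolute agreement with other operationalisations is
  not asserted.
* The F1 confidence interval is a count-ratio approximation, not an
  exact interval.
* Gold labels in the synthetic world are generator truth; an optional
  label-noise knob can model imperfect chart review but defaults off.
* Cohort matching on comorbidity profiles (used to assemble some
  published gold cohorts) is not implemented.
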