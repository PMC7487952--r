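---
title: "Validating claims-based BMI phenotyping algorithms for bariatric surgery cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating claims-based BMI phenotyping algorithms for bariatric surgery cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bariclaims)
```

## The problem

Administrative claims databases rarely contain measured body mass index
(BMI), which has historically made them a poor substrate for obesity
research. Bariatric surgery is a special case: insurer prior-authorization
rules require documented BMI thresholds (>= 40 kg/m^2, or >= 35 kg/m^2
with comorbidity), and those thresholds are routinely converted into
weight-related diagnosis codes on reimbursement claims. ICD-9-CM V85.x
codes and, from 1 October 2015, ICD-10-CM Z68.x codes denote narrow BMI
bands ("granular" codes, e.g. Z68.41 = BMI 40.0-44.9), while codes such
as 278.01/E66.01 ("morbid obesity") denote obesity status without a band
("nonspecific" codes).

`bariclaims` implements, as a reusable and fully tested pipeline, the two
claims-based phenotyping algorithms this setting supports, the nested
cohort design used to validate them against EHR-measured BMI, the
validation statistics, and a synthetic linked claims+EHR data generator
so that every stage is testable without access to any proprietary data.

## The algorithms

**Severe obesity classification.** A patient is classified as severely
obese if they carry at least one weight-related diagnosis code indicating
BMI >= 35 kg/m^2 at *any time* during the 182-day preoperative window
(index operation day included). The sensitivity variant uses a 40 kg/m^2
cutoff. Nonspecific codes never qualify under the base algorithm; the
expanded variant also accepts the morbid-obesity codes 278.01/E66.01.

**BMI categorization.** The *last available* weight-related diagnosis
code in a window is mapped to one of ten ordered BMI categories
(boundaries at 20, 25, 30, 35, 40, 45, 50, 60 and 70 kg/m^2), or to the
five-level / four-level coarsenings. All intervals are half-open
`[lower, upper)`, so the printed label "30.0-34.9" means
30.0 <= BMI < 35.0 and the labels tile the axis without gaps.

**Reference standard.** EHR BMI vitals. Severe obesity: any measurement
>= threshold in the window. Categorization: preoperatively, the
measurement most proximate to the last claims code (within +/- 30 days);
postoperatively, the last available measurement in the window. This
asymmetry is deliberate and mirrors how the two windows are used in
practice (baseline confounder vs. weight outcome), and it is preserved
here because validation results are only interpretable against the
design that produced them.

## Nested cohorts

* **Cohort 1** (availability): adults (>= 18 y) with a first qualifying
  AGB, RYGB or SG operation between 2011-01-01 and 2018-06-30,
  continuously enrolled through the 182-day preoperative window;
  excluded are patients with bariatric/revisional surgery or
  gastrointestinal malignancy in the preoperative period, an emergency
  department encounter or gastrointestinal ulcer diagnosis on the index
  day, or conflicting same-day bariatric procedure codes. Every
  exclusion is logged with a reason and tabulated in an attrition table.
* **Cohort 2** (preoperative validation): Cohort 1 members whose last
  preoperative weight code is granular, with an EHR BMI within +/- 30
  days of it.
* **Cohort 3** (postoperative validation): Cohort 2 members whose last
  postoperative weight code is granular, with an EHR BMI both within
  +/- 30 days of the code and inside the 365-day postoperative window.

Windows are fixed-day ("6 months" = 182 d, "1 year" = 365 d), the
preoperative window includes the index day, and the postoperative window
is `(index, index + 365]`. Two tie-breaks are needed that the design
leaves open, and both are resolved deterministically: among same-day
codes at the last date a granular code beats a nonspecific one and the
highest category wins (up-coding pressure makes the higher code the one
that drives authorization); among equidistant measurements the earlier
one wins (vitals precede coding in clinical workflow). Both choices are
flagged in the outputs so their frequency can be audited.

## Validation statistics

Per level, the k-level agreement table is collapsed one-vs-rest and
sensitivity, specificity, PPV and NPV are computed from the 2x2 counts;
a metric with an empty denominator is reported as flagged-missing, never
as 0 or 1. Overall concordance is the weighted Cohen's kappa

kappa_w = (sum(W * O)/N - sum(W * E)/N) / (1 - sum(W * E)/N),

with linear (Cicchetti-Allison) weights `1 - |i-j|/(k-1)` by default and
quadratic (Fleiss-Cohen) weights selectable; for k = 2 both reduce to
the unweighted kappa. Linear weights are the default because they are
the common choice for ordinal scales when the source analysis does not
name its scheme. Confidence intervals use the Fleiss-Cohen-Everitt
large-sample variance by default (the default in the era's statistical
software), truncated to [-1, 1], with a multinomial percentile bootstrap
as a cross-check; the two agree within 0.02 on simulated 10-level tables
with N = 3000 (this is exercised in the test suite). Kappa interpretation
bands use the conventional 0.40 / 0.75 cutpoints. Reported counts of 10
or fewer are masked at reporting time (never during computation), and a
rate whose numerator or complement is masked is reported as a one-sided
bound ("> 91") derived from the unmasked count and the threshold.

## The synthetic world

The generator emulates the data structure of a linked claims+EHR
warehouse. Per patient: an index operation (AGB/RYGB/SG with mix
10.0/32.2/57.8%), an accrual-window index date, a log-normal baseline
BMI (mean 46.1, SD 9.0 kg/m^2), encounters as Poisson counts with
uniform dates in the two windows, and a latent BMI trajectory that is
constant preoperatively and declines linearly to `(1 - loss) x baseline`
at day 365 (mean loss fraction 0.14/0.30/0.25 for AGB/RYGB/SG, SD 0.05
across patients — ordinary one-year results for these operations; the
linear-to-one-year shape is the simplest consistent with last-available
BMI semantics). At each encounter a weight code is emitted with a
window-specific probability, granular with another; a granular code's
category is drawn from a row-stochastic 10x10 *fidelity kernel* applied
to the contemporaneous true category, with additional near-threshold
up-coding: a preoperative encounter whose true category is 30.0-34.9 is
coded 35.0-39.9 with probability 0.35, which makes roughly 70% of
borderline patients carry a >= 35 code somewhere in their preoperative
window. Nonspecific emissions use the morbid-obesity code when the true
BMI is >= 35 and the unspecified-obesity code otherwise. Coding system
follows the service date (ICD-9-CM before 2015-10-01). A patient is
EHR-linked with probability 0.15; a linked patient's encounter records a
BMI vital (true BMI plus Gaussian noise, SD 0.5 kg/m^2) with
probability 0.7.

Default emission probabilities were chosen so that patient-level code
availability in a default world approximates the availability pattern
reported for real bariatric claims: ~98% of patients with any
preoperative weight code and ~93% with granular ones, but far lower
postoperative availability (~45% granular, ~34% nonspecific-only, ~21%
none among patients with granular preoperative codes). The default
kernel is tridiagonal with 0.75 on the diagonal; under the full model
(noise, up-coding, postoperative trajectory) this implies encounter-level
weighted kappas of about 0.81 preoperatively and 0.84 postoperatively,
the range reported for these codes in validation studies. A heavier
diagonal (0.85) would push the implied kappas to 0.86-0.88, which is why
0.75 is the shipped default; both are plain configuration values.

One master seed drives everything; per-patient substreams are derived by
a counter-based scheme so that enlarging `n_patients` extends the
population without reshuffling earlier patients.

**What the generator does and does not emulate.** It reproduces the
coding *process* (granularity mix, era switch, fidelity, up-coding,
partial linkage, proximity structure) but not comorbidity co-occurrence,
care-seeking correlated with weight regain, differential postoperative
coding by health status, costs, or pharmacy claims. Passing tests
therefore demonstrate that the pipeline measures coding fidelity
correctly when the generating process is known — not that any particular
real database has that fidelity.

## The analytic oracle

`expected_agreement_matrix()` returns the exact joint distribution of
(claims category, reference category) for a coding encounter that
emitted a granular code alongside a same-encounter vital, by quadrature
on the quantile grid of the latent BMI distribution (preoperatively) and
additionally over operation type, the per-patient loss fraction and
uniform encounter time (postoperatively). Because code emission and
linkage are independent of the BMI category, conditioning on emission
does not change the joint, so the matrix is the exact target of the
empirical encounter-level frequencies. The test suite verifies, at
n = 50,000 patients, that the empirical joint is within total-variation
distance 0.02 of the oracle and that the empirical weighted kappa
recovers the oracle-implied kappa within three replicate-seed Monte
Carlo standard errors. The cohort-level *postoperative* pipeline kappa is
systematically below the encounter-level value because the last code and
the last measurement are separated in time while the true BMI is still
falling; that gap is a property of the validation design, not an error.

## Numerical choices and degenerate inputs

* Quadrature: 4,000 quantile nodes preoperatively (600 x 3 operations x
  8 loss nodes x 40 time nodes postoperatively); accurate to ~1e-4
  relative in all but the extreme-tail cells, verified against
  per-cell adaptive integration in the tests.
* Code normalization accepts dotted and undotted, case-insensitive
  forms; malformed strings (empty, illegal characters) are input errors,
  while unknown well-formed codes are simply "not weight related".
* EHR BMI values outside 10-120 kg/m^2 are flagged non-physiologic and
  excluded from comparisons.
* Patients with no reference data never enter validation denominators
  (they cannot reach Cohorts 2/3); they are not counted as negatives.
* A kappa on a table with all mass in one cell is flagged undefined,
  not forced to 0 or 1; perfect-agreement tables give the degenerate
  interval [1, 1] with a flag. Asymptotic intervals warn below N = 30.
* With the expanded (nonspecific) algorithm at ten or five levels, a
  nonspecific last code yields a flagged missing category — no
  principled level assignment exists — while at four levels it maps to
  "obese >= 30.0". The flag keeps denominators auditable.
* `n_patients = 0` yields a valid empty world; empty cohorts yield empty
  summaries rather than errors.

## Problem sizes used in the shipped checks

The test suite exercises the perfect-coder identity at n = 10,000
patients, oracle recovery at n = 50,000 with four replicate seeds, and
oracle equivalence of the kappa implementation against a naive
double-loop reference on 1,000 random tables. `scripts/acceptance.R`
runs the full pipeline at n = 20,000. These sizes give Monte-Carlo noise
well inside the asserted bounds while keeping a full run on one CPU to a
few minutes.

## Known limitations

* The shipped exclusion screens for gastrointestinal malignancy and
  ulcers are compact ICD prefix sets (151/230.2/C16; 531-534/K25-K28)
  and are pluggable; production use against real claims requires
  locally validated code lists, and procedure identification there needs
  CPT-4/HCPCS dictionaries that are licensed and out of scope (the
  synthetic schema carries an explicit operation-type column instead).
* The nonspecific dictionary is the six printed code pairs; supplementary
  local variants (e.g. 278.02) can be added through
  `weight_code_table(extra = ...)`.
* Pediatric BMI-percentile codes (V85.5x/Z68.5x) are out of scope.
* No imputation of missing BMI and no reconstruction from weight/height.
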