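---
title: "Antenatal care data sources, effective-coverage cascades and a simplified lives-saved engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antenatal care data sources, effective-coverage cascades and a simplified lives-saved engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anccover)
```

## The problem

Deterministic lives-saved models project the mortality and morbidity
consequences of changing health-intervention coverage. Their inputs are
*effective-coverage* indicators: the proportion of women who truly needed an
intervention and received it correctly. Few data sources measure that
directly. Routine facility reports count referrals without knowing the true
number of cases; household surveys measure contact, not content, of care;
clinical records — paper-based or electronic — carry the longitudinal detail
needed to decide, woman by woman, whether screening happened at the right
time and whether a positive case was correctly managed. `anccover`
operationalizes that comparison for antenatal care: one pipeline from
records (or aggregates) to indicators to scenario projections, so that the
effect of the *data source* on the policy conclusion can be isolated.

## The cascade model

Every management indicator follows the same two-stage decomposition:

$$\mathrm{coverage} \;=\;
  \underbrace{\frac{\text{screened correctly}}{\text{eligible}}}_{\text{screening stage}}
  \times
  \underbrace{\frac{\text{correctly managed}}{\text{screen-positive}}}_{\text{management stage}}$$

with eligibility meaning attendance at antenatal care. The product equals
correctly-managed true positives over the true positives one would estimate
among all attenders (the two published denominator readings — all attenders
with the positives-per-screened rate, or the screening stage times the
managed-per-positive rate — are algebraically identical here, which is why
the object stores the stages and their product rather than two composites).
Both stage proportions are reported in every `cascade_result`, together
with the four monotone counts.

Stage definitions per pathway:

* **Diabetes**: urine sugar at the booking (first) visit for everyone; a
  blood sugar test within the closed 24–28-week window for women not
  already urine-sugar positive; a glucose challenge test when either screen
  is positive. Positive means a challenge result strictly above 140 mg/dl.
  Correct management is referral, judged at the clinic: a correct referral
  counts regardless of whether the woman followed through at the receiving
  facility.
* **Hypertensive disorders**: blood pressure at *every* attended visit
  (one missing measurement fails the screening stage — the literal serial
  -measurement requirement). Positive is any hypertensive reading
  (≥ 140/90 mmHg by default). Mild gestational hypertension is correctly
  managed by a proteinuria work-up at or after detection; chronic
  (hypertension observed at ≤ 20 weeks) and moderate/severe (≥ 160/110)
  cases by referral.
* **Pre-eclampsia**: screening additionally requires a urine protein test
  following observed hypertension after 20 weeks; positive is hypertension
  after 20 weeks with positive proteinuria; correct management is hospital
  referral. A hospital-referred woman stops attending the clinic, so the
  cascade credits her management even though her later visits are absent.

Three conventions deserve explanation:

* **Strict inequalities.** The clinical cut descriptions mix "below" and
  "or less"; the package adopts the strict reading (`< 11`, `< 7` g/dl,
  `< 18.5` kg/m², `> 140` mg/dl) with every cut configurable in
  `clinical_thresholds()`.
* **Missing data are failures, not exclusions.** A pregnancy missing a
  required screening datum counts as not screened correctly, and missing
  vaccination/supplementation records count as not vaccinated/not
  supplemented. Differential missingness between record dialects is a real
  phenomenon the pipeline is meant to expose, not noise to be dropped; a
  complete-case analysis would hide exactly the difference of interest.
* **Empty denominators.** When no screen-positive case exists the
  management stage is undefined; coverage is reported as 0 with an explicit
  `undefined` flag, never as `NaN`, and unavailable indicators are explicit
  markers (`NA` plus an availability tag), never silent zeros.

## The synthetic cohort generator

No record-level antenatal dataset is shipped; the generator produces
cohorts with the statistical structure the cascades assume, and its
defaults describe the study conditions the package is designed around — a
West Bank-like public-clinic antenatal population:

* latent condition frequencies: diabetes 6%, chronic hypertension 1%, mild
  gestational hypertension 4%, moderate/severe 1.5%, pre-eclampsia 2%
  (arising only among hypertensive pregnancies after 20 weeks, so the
  marginal pre-eclampsia incidence may not exceed the summed hypertension
  incidences);
* hemoglobin N(11.4, 1.25) g/dl at the pregnancy level (implying ~37%
  anemia under the strict < 11 cut) with a 0.2% severe-anemia floor;
  booking BMI below 18.5 with probability 3.5%;
* a booking visit drawn uniformly from weeks 8–16 (no published enrollment
  distribution exists, so a uniform window is the least-informative choice)
  followed by routine visits at weeks 12, 16, 20, 24, 28, 32, 36, 40 —
  the schedule must contain a week in 24–28 or the diabetes pathway cannot
  be completed;
* tetanus missingness 7% per pregnancy in the registry dialect and 42%
  after degradation to the paper dialect, the two documentation regimes the
  dialect comparison is about.

Compliance acts **per pregnancy and pathway**: a non-compliant pregnancy
misses its whole diabetes work-up, or one blood-pressure measurement. This
makes the correctly-screened fraction estimate the configured screening
compliance exactly, which is what turns the cascade indicators into
estimators with a known truth — on a large cohort the diabetes cascade
coverage converges to (screening compliance) × (management compliance) and
the positives-per-screened fraction to the latent incidence. Conditions
manifest **only through the screening pathway**: a latent diabetic shows a
challenge value above 140 mg/dl only if the challenge test was performed.
The latent truth table rides along as an attribute for validation but is
never read by any indicator operation (the test suite shuffles and deletes
it to prove this).

Blood-pressure values are drawn above the conventional cuts for
hypertensive states (severe ≥ 160/110) and below for normotensive ones;
the categories, not the mmHg values, carry the information. Two
sensitivity-like constants are fixed in the generator rather than exposed:
30% of latent diabetics already show glycosuria at booking, and 2% of
non-diabetic blood sugar tests trigger a (negative) challenge test. Only
the 140 mg/dl decision boundary matters to the cascades, so the shape of
the challenge-value distribution is uniform on either side of it.

Random draws occur in one fixed, documented order (pregnancy-level vectors,
then visit-level vectors), so a seed identifies a cohort across versions;
dialect degradation uses an independent stream derived as seed + 9901 so
that degrading never perturbs generation. Mild and moderate/severe
gestational onsets are drawn in weeks 21–34, pre-eclampsia onsets in weeks
21–36 (never before the hypertensive onset).

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: calendar time and seasonality, repeat
pregnancies per woman, facility-level clustering, correlated missingness
(a chaotic clinic missing everything at once), transcription error in paper
records, and any dependence of attendance on the woman's condition.
Inference validated here is validated for independently-missing,
independently-attending cohorts.

## Aggregate sources

The routine estimator divides referred cases by registered pregnancies ×
incidence. Incidence must be supplied externally — in the demo
configuration it is borrowed from the record-level cohort's cascade
(positives per correctly-screened), mirroring how a routine analysis
borrows incidence from a record review. Because numerator and denominator
come from different reporting levels, the ratio can exceed 1: that is
treated as saturation (capped at 1 with a warning, and flagged by
`validate_config()`), not as an error, since over-reporting is a data
property worth surfacing rather than refusing.

The survey estimator is a deliberate placeholder crosswalk — contact
coverage × quality fraction, which can never exceed contact coverage — with
a strategy slot (`method =`) so a published indirect regression can be
substituted without touching the callers.

## The projection engine

Within each cause, interventions combine by multiplicative residual risk:

$$D_{c,t} = D^{*}_{c}\prod_{i}\bigl(1 - \mathrm{Eff}_{i,c}\,
\mathrm{AF}_{i,c}\,\mathrm{cov}_{i,t}\bigr)$$

where the latent envelope $D^{*}_{c}$ is calibrated so that projecting at
baseline coverage reproduces the input deaths exactly (an identity the
tests verify to 1e-10; a residual-risk factor ≤ 0 is rejected as
infeasible rather than silently producing negative deaths). Anemia
prevalence follows the same form with iron-folate as its only intervention,
and anemia cases apply the prevalence to a constant yearly number of
pregnancies. The population is constant across years: the comparison is
between scenarios sharing the same population, so demographic projection
would add machinery without changing any difference.

The scale-up scenario raises public-sector coverage to
`max(target, baseline)` from the second year — a scale-*up* never lowers
coverage where the baseline already exceeds the target — and mixes sectors
as `p_public × public + (1 − p_public) × other`, holding the other sector
and the attendance share fixed. Other-sector coverage defaults to the
public baseline (constant-quality imputation); it is a named argument
because the mixing inputs are rarely published. Indicators a source cannot
populate are held at a reference coverage in *both* scenarios, so their
averted contribution is structurally zero — this, not any effect-size
estimate, is why a routine-report analysis attributes 100% of maternal
lives saved to pre-eclampsia management and averts no anemia cases.

Attribution is computed one-intervention-at-a-time (raise only intervention
*i*, hold the rest at comparator levels) and normalized to shares. With a
multiplicative model the one-at-a-time sum need not equal the joint averted
(interactions), so the package asserts only that shares are in [0, 1] and
sum to 1; when nothing is averted the shares are flagged undefined rather
than normalized by zero. The percent change in each rate is reported both
against the intervention scenario's own first year and against the
comparator's final year, since the two readings answer different questions.

Shipped effectiveness and affected-fraction defaults
(`default_epi_inputs()`) are **illustrative**. Their *structure* — which
intervention touches which cause (maternal hypertensive deaths ←
hypertension and pre-eclampsia management; neonatal tetanus ← vaccination;
antepartum stillbirths ← pre-eclampsia and diabetes management; anemia ←
iron-folate) — is the standard antenatal linkage and is what the structural
attribution results rest on; the magnitudes are not an effectiveness
database, and any analysis that matters should set them explicitly.

## Numerical and I/O choices

Continuous measurements are generated at fixed decimal precision
(hemoglobin and BMI to 0.1; pressures and glucose to integers) so the CSV
round-trip is bit-exact: the decimal text re-parses to the identical
double. Missing values are empty fields; the sidecar JSON carries the
generating parameters (named maps serialized as objects so names survive),
dialect, censoring state and a schema version. Latent-truth columns are
written only on request (`with_truth = TRUE`), keeping indicator inputs
honest by default.

Per-pregnancy aggregation orders visits by gestational age and treats the
first visit as the booking visit. Ties in referral precedence resolve
hospital > high-risk clinic. All of `run_comparison()`'s randomness derives
from the single configured seed (per-source cohort seeds are
`seed + 101 × source index`), making identical configurations
byte-identical end to end.

## Test design and problem sizes

Cascade oracles are 6–12-pregnancy fixtures enumerated by hand before the
cascades were implemented; the projection engine is checked against a
separately-coded brute-force loop evaluator on randomized small instances
(≤ 3 causes, ≤ 4 active interventions) to 1e-10. Statistical recovery
tests run at 10,000–20,000 pregnancies and use three-standard-error bands;
for the cascade coverage, whose estimator is a product of two stage
proportions, the band uses the delta-method standard error of the product
(a single-binomial band at the product value would be too narrow, since the
management stage rests on only the screen-positive subset). Property
checks (monotone cascade counts, proportions in [0, 1], averted
nondecreasing in the target) run over hundreds of random-parameter cohorts
at 50–60 pregnancies each — sizes chosen to exercise degenerate cases
(empty positive sets, total missingness) frequently.

## Limitations

* The lives-saved engine is a minimal multiplicative model: no herd
  effects, no intervention interactions beyond residual risk, no
  uncertainty intervals, no demographic change.
* The indirect survey estimator is a crosswalk, not a validated published
  regression.
* Effectiveness defaults are illustrative; conclusions about magnitudes
  require user-supplied values.
* The generator's independence assumptions (missingness, attendance,
  conditions) are stronger than real clinics satisfy; dialect differences
  are modeled only where documented (iron-folate encoding, tetanus
  missingness).
* Growth-restriction screening (symphysis-fundal height) is out of scope:
  management data do not exist in any of the emulated sources.
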