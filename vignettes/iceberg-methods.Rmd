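---
title: "Methods: the ICEBERG score, its validation pipelines, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ICEBERG score, its validation pipelines, and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icebergscreen)
```

## The instrument

ICEBERG is an additive screening questionnaire for emergency-room patients
aged 70 and older. It covers nine geriatric domains — social situation, age,
mobility and falls, cognition and depression, delirium, prior care contact,
polypharmacy, functional limitation, malnutrition — through 14 scoreable
sub-items (Q1–Q9b). Each selected response option carries a fixed
non-negative integer weight and the total is the plain sum:

$$ T \;=\; \sum_{j=1}^{14} w_j(r_j), \qquad T \in [1, 30], $$

where $r_j$ is the selected option of item $j$. The minimum is 1, not 0,
because the age item Q2 contributes at least 1 point for any patient in the
instrument's population; the bounds are recomputed from the weights by
per-item reduction (`score_bounds()`) rather than hard-coded, and an
exhaustive enumeration of all $3^2 \cdot 2^{12} = 36{,}864$ response
combinations in the test suite confirms that every value in between is the
sum the weights dictate. (Accompanying narrative material for this
instrument sometimes quotes a "0 to 30" range; the weights make 0
unattainable, so the package documents 1–30 and treats the 0 as a textual
discrepancy.)

Totals are dichotomized at a cut-point derived as the pooled median of the
validation cohorts: **high risk when $T \ge 10$**, low otherwise, with the
tie at the threshold going to high. The package ships 10 as
`threshold_default` and also exposes `median_threshold()` (interpolated
median floored to an integer) so the same rule can be re-derived on a new
cohort.

### Missing and unassessable answers

The delirium item in particular can be unassessable in the ER (about 3.5% of
patients in the feasibility pilot), and the original description of the tool
does not state the scoring consequence. `score_responses()` therefore takes
a `missing_policy`:

* `zero` (default): an unanswered item contributes 0 points and `n_missing`
  is reported. This is deliberately conservative — missingness never adds
  risk points — and keeps every patient scoreable, which matters for a
  screening tool applied to a whole ER population.
* `error`: any missing item aborts, naming the items.
* `exclude_patient`: the patient is returned as an excluded sentinel.

The age item is mandatory under every non-excluding policy because the
instrument is undefined without it. Likewise, scoring a record with age
below 70 is an error: the tool's population starts at 70 and the age item
cannot be extrapolated downward.

## Validation pipelines

### Construct validity

`build_construct_report()` reproduces the structure of the first pilot:
score the cohort, split at the cut-point, and compare each variable between
classes. The test is chosen to match each variable's summary format:

* sex — Pearson chi-square **without** continuity correction. The
  uncorrected statistic is the one consistent with the pilot's printed
  p-value for the one-on-one care table (`[[7,122],[23,136]]` gives
  p = 0.0125; the Yates-corrected version gives ≈ 0.021);
* age — pooled-variance two-sample t-test (age is summarized as mean/SD);
* every CGA component (Barthel, SPI, MMSE, MNA, grip strength right/left,
  SPPB, clock drawing, Frailty-Fried, Frailty-SHARE) — Wilcoxon rank-sum
  via the normal approximation with tie correction and no continuity
  correction (components are summarized as median/IQR).

No multiple-testing correction is applied, matching the source analyses;
the report footer says so. `spearman_score_vs_components()` adds Spearman
rank correlations (average ranks for ties, pairwise-complete deletion;
components with fewer than 3 complete pairs are flagged, never silently
dropped). Display rounding follows the pilot tables — two decimals above
0.05, `<0.05` / `<0.001` bands below — while machine output always carries
the raw statistic and p-value.

### Criterion validity

`build_criterion_report()` reproduces the second pilot's shape: contingency
summaries for one-on-one nursing care, 30-day readmission, in-hospital
mortality and nursing-home discharge; rank-sum comparisons of length of stay
and nursing workload minutes; and logistic regressions of each binary
outcome on the risk class adjusted for age (linear in years) and sex
(indicator coded female = 1, the cohort majority; the original coding is
unstated). Odds ratios carry 95% Wald intervals,
$\exp(\hat\beta \pm 1.96\,\mathrm{SE})$ — the standard default of the
statistical software generation the pilots used; profile-likelihood
intervals are out of scope and the choice is recorded in the report
metadata. Fits showing separation (runaway coefficient or standard error)
are returned with `converged = FALSE` and no interval rather than a
spuriously finite one; zero events is an error, not an estimate.

Two denominator subtleties are options rather than silent choices:

* **Nursing-home discharge** is defined among patients admitted from home,
  but the published group percentages use the full group sizes
  (10/129 = 7.8%, 42/159 = 26.4%). `denominator_policy` defaults to
  `full_group` (reproducing the printed numbers) with
  `admitted_from_home` available for the definition-faithful denominator.
* **Readmission** cannot happen to in-hospital decedents; the generator and
  pipelines treat death as logically excluding readmission and nursing-home
  discharge. The source is silent on this; it is a logical necessity.

Nursing minutes may be missing for a whole site (they were exported by two
of the three pilot hospitals); they are excluded pairwise and the excluded
fraction is reported, with the LOS row still produced even if every nursing
value is missing.

## The synthetic cohort generator

No patient-level data from the pilots were ever deposited — only group
summaries and event counts. The generator therefore emulates, not
replicates: a **single latent frailty factor** $F \sim N(0,1)$ per patient
drives everything, the simplest dependence structure consistent with a score
that separates eight of nine CGA components at once.

* Items: cumulative-logit models over weight-ordered options,
  $P(\text{option} \ge k \mid F) = \operatorname{logit}^{-1}(a_k + \lambda F)$,
  with per-item loadings $\lambda$ (defaults 0.5–1.2). The age item is
  derived deterministically from age.
* Age: jointly normal with $F$ (correlation 0.25, which reproduces the
  roughly 2.5-year age gap between risk classes), truncated below at 70 by
  re-drawing the age-specific noise. Truncation shifts the realized mean up
  by roughly half a year relative to the nominal mean — the preset means are
  the published ones and the shift sits well inside sampling noise at the
  pilot sizes.
* CGA components: $\text{intercept} + \text{slope}\cdot F + \varepsilon$,
  rounded half-up where integer-valued, clipped to each instrument's
  admissible range (Barthel 0–100, SPI 0–40, MMSE 0–30, MNA 0–30, clock
  0–7, SPPB 0–12, frailty indices 0–5, grip ≥ 0 kg). Intercepts target the
  published overall medians; slopes are negative for capability measures
  and positive for frailty indices. SPI is given a deliberately weak
  negative loading — it was the one component the score did not separate —
  and its direction (higher = more self-care capacity) is an assumption,
  flagged as such.
* Binary outcomes: $\operatorname{logit} P = a + b_F F + b_{\text{age}}(\text{age}-80)
  \,[+\, \gamma\,\mathbb{1}(T \ge 10)]$. The optional exposure term
  $\gamma$ exists purely for parameter-recovery and coverage studies.
* LOS and nursing minutes: lognormal with log-scale mean linear in $F$
  (medians 7 days and about 1,600 minutes; LOS rounded to whole days with a
  1-day floor).

### Calibration is deterministic, not simulated

Configured rates are **marginal** targets. At config construction the
intercepts are solved by 1-D quadrature and root finding:
$\int \phi(z)\, w(z)\, \operatorname{logit}^{-1}(a + b_F z + b_{\text{age}}
m_{\text{age}}(z))\, dz = \text{rate}$, where $m_{\text{age}}(z)$ is the
truncated-normal conditional mean of age minus 80 and $w(z)$ is the
probability of being in the outcome's denominator (survival for
readmission; survival × living at home for nursing-home discharge). This
keeps repeated generation cheap and makes the marginal-calibration property
(rates within 3 Monte-Carlo standard errors at n = 10,000) a check on the
model, not on a tuned constant. The residual approximation (the inner age
noise is integrated at its conditional mean) is an order of magnitude below
the Monte-Carlo band.

The published adjusted odds ratios (2.86 for one-on-one care, 3.70 for
nursing-home discharge) are not recomputable without patient data; they
served as calibration anchors for the default frailty slopes. The
nursing-home slope (1.8) is larger than the others because restricting the
outcome to patients living at home removes the frailest patients from its
denominator and attenuates the association; the slope compensates so the
fitted OR at large n sits near the anchor.

### What the generator does not emulate

One factor cannot carry everything: true inter-component correlations of
the CGA are unpublished, so only marginals and one shared axis are matched;
there are no hospital-site effects, no seasonality, no admission diagnoses,
no sex effects on grip strength. Passing tests on this cohort demonstrate
that the pipelines are correct and calibrated under a plausible dependence
structure — not that the instrument performs identically on real ER
patients.

## Numerical choices

* Percentages and rendered summaries use round-half-up (`round_half_up()`),
  matching how the pilot tables were typeset; machine outputs are never
  rounded.
* The Wilcoxon implementation's normal approximation tracks the exact
  permutation p-value closely in the separated-groups regime (verified
  against an exhaustive 252-split oracle within 0.02); in the mid-p range
  the approximation is the documented behavior, as in any large-sample
  rank test.
* Degenerate inputs surface, never silently pass: empty groups error,
  zero-variance comparisons return p = 1 (or 0 with separated means) with
  a `"no variation"` flag, an empty risk class flags the whole report as a
  degenerate split, zero-event contingency tables are flagged `"no events"`.
* Type-I calibration of the tests is run under `null_config()` (all
  loadings zero, age decoupled from frailty). Because the age item is
  derived from age by construction, the score is never independent of age
  even under the null; the calibration therefore applies each test to a
  variable that is genuinely null — completion time for the t-test, MMSE
  for the rank-sum, sex for the chi-square.

## Problem sizes used by the shipped studies

The test suite and acceptance script run: exhaustive enumeration of all
36,864 response combinations; 2,000 null cohorts of n = 80 for the 5%-level
calibration; 1,000 replicates of n = 500 for Wald-interval coverage at a
generative OR of 2.0; a single n = 5,000 cohort for point recovery of a
generative OR of 3.0; and n = 10,000 cohorts for marginal calibration.
These sizes put Monte-Carlo error comfortably inside each acceptance band
while keeping a full run on one CPU within a couple of minutes.

## Known limitations

* The score–age association is structural (the age item), so age-adjusted
  odds ratios on synthetic cohorts are mildly attenuated relative to their
  crude counterparts by design, as in the real instrument.
* `exclude_patient` reduces the analyzed n; the pipelines report but do not
  reweight for it.
* Handgrip units and best-of-trials protocol are treated as given numeric
  values; MNA is generated on a continuous scale.
* The cut-point re-derivation (`median_threshold`) floors the interpolated
  median; with heavily discrete score distributions other conventions
  (nearest integer, splitting exactly at the median patient) can differ by
  one point.
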