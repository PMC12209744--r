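---
title: "Methods: serum IFN score stratification of time to clinical worsening in lcSSc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum IFN score stratification of time to clinical worsening in lcSSc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifnttcw)
```

## The problem

Limited cutaneous systemic sclerosis (lcSSc) progresses slowly, which makes
single-organ endpoints impractical for trials: clinically meaningful events
are spread across lungs, heart, skin, gut, kidneys and the digital
vasculature, and each is individually rare. A composite "Morbi-mortality"
time-to-event endpoint — time to clinical worsening (TTCW), the months from
a serum-sample baseline to the first qualifying event — pools them. The
biological question is whether serum type I interferon (IFN) activity,
measured as a six-chemokine score, stratifies that risk.

`ifnttcw` implements the full analysis chain: score computation and
healthy-control thresholding, composite-endpoint adjudication on
longitudinal visit records, event-free survival analysis, Cox modelling with
discrimination metrics, clinical-by-serologic risk stratification, and the
event-driven power design — together with a synthetic cohort generator that
reproduces the statistical structure the chain assumes, so every stage is
testable without patient-level data.

## The IFN score and its threshold

The score for one serum sample is the average natural logarithm of the
concentrations (pg/mL) of CCL2, CCL8, CCL19, CXCL9, CXCL10 and CXCL11:

$$\mathrm{IFN} = \frac{1}{6}\sum_{j=1}^{6}\ln c_j .$$

It is dimensionless up to the choice of concentration unit: multiplying all
six concentrations by a constant shifts every score equally, and the
high/low contrast is unaffected. The "high" threshold is the healthy-control
mean plus two sample standard deviations (n − 1 denominator; with 72
controls the distinction from the population formula is negligible, and the
sample convention is standard for a reference cohort). Classification is
strictly above the threshold; a score exactly on the boundary is "low". The
score is continuous, so the tie convention is measure-zero and purely a
documented convention. The threshold is always derived from control data at
run time — the package never hard-codes a published threshold value.

## Endpoint adjudication

A subject's record is a baseline table plus an approximately 6-monthly visit
stream carrying FVC%-predicted, DLco%-predicted, mRSS, and boolean event
flags. The first qualifying event among the following defines TTCW:

* **SSc-related death** (visit flag; non-SSc death censors instead).
* **New PAH** by right heart catheter — only for subjects without baseline
  PAH ("new").
* **ILD progression**: over any ordered visit pair at most 12 months apart,
  an absolute FVC drop of at least 10 percentage points; or a drop in the
  5–9 point band together with a relative DLco decline of at least 15%
  between the same visits. The DLco criterion is interpreted as *relative*
  decline (the standard progression convention); the window is rolling, not
  baseline-anchored. The 5–9 band is applied exactly as stated, so a
  fractional drop between 9 and 10 points qualifies under neither branch;
  both choices are configurable through `adjudication_rules()`.
* **Cardiac**: ejection fraction below 45%, impairing pericardial effusion,
  treated arrhythmia, or a cardiac device (visit flags).
* **Renal crisis** (flag).
* **GI failure**: enteral nutrition for three or more weeks, any parenteral
  feeding, or admission for (pseudo-)obstruction (flags).
* **Severe digital vasculopathy** requiring hospitalization (flag).
* **Skin worsening**: mRSS at least 5 units *and* at least 25% above
  baseline, both inclusive; a baseline mRSS of 0 qualifies on the absolute
  increase alone.

Exact ties in event time are broken by a fixed severity order (death > PAH >
ILD > cardiac > renal > GI > digital > skin); simultaneous qualifying events
are an artifact of the 6-month visit grid, and the convention only fixes the
reported *type* — the time is identical. Subjects without an event are
censored at the minimum of their last visit and the 120-month horizon. The
five-year completeness filter used in the sensitivity analysis drops exactly
the subjects censored before 60 months: anyone with an observed event, or
with 60+ event-free months, contributes complete five-year information.

## Survival analysis

Event-free survival uses the Kaplan-Meier product-limit estimator with the
Greenwood plug-in variance $S(t)^2 \sum d_i /(n_i(n_i-d_i))$. Fixed-time
contrasts compare the KM estimates at 12, 24, 36, 60 and 120 months with a
normal approximation on the survival scale (the difference in KM estimates);
a complementary log-log transform variant is available but off by default,
since the survival-scale difference is the stated comparison and the
transform matters only near the boundary. Restricted mean TTCW is the area
under the KM curve up to tau, the smaller of the two groups' maximum
observed times, with the standard plug-in variance
$\sum A_i^2 d_i/(n_i(n_i-d_i))$ where $A_i$ is the area beyond event time
$t_i$; the groups are treated as independent for the difference. Group
comparison uses the two-sample log-rank test.

## Cox models and discrimination

Univariable and multivariable Cox proportional-hazards models use the Efron
tie correction — visit-grid data generate heavy ties, where Breslow is
noticeably biased. The IFN score as a continuous covariate enters as a
penalized spline with 4 degrees of freedom, reported as a linear-component
HR/CI/p and a nonlinear-component p. Fixing the degrees of freedom (rather
than AIC selection, available via `spline_df = 0`) keeps the
reported effective dimension stable across bootstrap refits on small event
counts. The univariable screen applies Benjamini-Hochberg q-values across
the screened covariates. The two multivariable models share the clinical
covariates ILD, PAH, mRSS, DU disease and age, plus either the spline score
(Model 1) or the high/low class (Model 2). Proportional hazards are
inspected via complementary log-log curves with a parallelism summary (the
maximum deviation of per-time offsets from their mean).

Discrimination uses an incident case / dynamic control time-dependent ROC:
at each observed event time the cases are the subjects failing exactly then
and the controls those still under observation later; AUC(t) is the rank
probability that a case's marker exceeds a control's (ties half-credited).
Published implementations differ in how per-time AUCs are aggregated, so the
package documents its own convention and tests invariances instead of
matching any one default: reported AUC(tau) aggregates event times up to tau
with Kaplan-Meier weights $2\hat f(t)\hat S(t)$, and the C-index is the same
aggregate up to the 120-month horizon. Both are invariant under strictly
monotone marker transformations; a perfect marker gives exactly 1, an
uninformative one 0.5. Standard errors come from a subject-level bootstrap
stratified by event status (1,000 iterations in reported analyses), with
model refitting inside the bootstrap when the marker is a fitted linear
predictor.

## Risk stratification

Acral involvement is mRSS > 4 (strict, so 5 or more) or DU disease;
cardiopulmonary involvement is baseline PAH or ILD. The four involvement
classes crossed with the IFN class give eight strata, reported with
upset-style intersection counts and event rates. "High risk" requires at
least one clinical involvement *and* a high IFN score. Relative risks versus
the overall cohort are ratios of KM cumulative incidences at 24, 36 and 48
months. Because the group is a subset of the overall cohort, the two
incidences share subjects; the default CI is therefore a subject-level
bootstrap, with a delta-method approximation (independence assumed,
documented as such) available for speed.

## Power design

The design module implements the transparent Schoenfeld closed form for
required events,
$\lceil (z_{1-\alpha/2}+z_{\beta})^2 / (p(1-p)\ln^2\mathrm{HR}) \rceil$,
an incidence-based conversion to per-arm sample size using the
proportional-hazards transform $P_2 = 1-(1-P_1)^{\mathrm{HR}}$, and
multiplicative censoring inflation $\lceil n(1+a)\rceil$. At HR 2.0,
two-sided alpha 0.05, power 80% and equal allocation this yields 66 required
events — published designs computed with accrual-model software report
smaller counts (42) at the same settings; the closed form is kept because it
is auditable, and the difference is documented rather than forced to agree.
Only the censoring-inflation arithmetic (112 -> 140 at 25%) is exactly
reproducible by hand.

## The synthetic cohort generator

The generator's defaults are the study conditions being emulated, not
tuning knobs:

* **Controls**: 72 panels with score ~ N(4.97, 0.27²). Per-chemokine ln
  values are score + fixed offsets (the printed per-chemokine means,
  centred) + mean-zero noise re-centred within each panel so the realized
  score equals the drawn score exactly — downstream code consumes only the
  score, but the panels remain realistic analyte by analyte.
* **Patients**: 149 subjects with score ~ N(5.45, 0.46²) (Table-style
  cohort summary; the alternative printed summary 5.50 ± 0.44 is exposed
  via `patient_score_mean`/`patient_score_sd` and deliberately not
  adjudicated). About 45% fall above the mean + 2 SD control threshold.
* **Baseline covariates** are drawn independently at the published
  prevalences (ILD 24%, PAH 6%, DU 39%, calcinosis 36%, upper GI 64%, mRSS
  ~ N(2.09, 2.63²) clamped at 0, FVC ~ N(109, 20²), DLco ~ N(67, 15²),
  etc.). Independence is a simplification; see limitations.
* **Latent events**: exponential first-event times whose hazard carries a
  group effect for latent IFN-high versus IFN-low *and* clinical
  prognostic effects (defaults on the HR scale: ILD 2.73, PAH 4.78, DU
  disease 2.12, mRSS 1.13 per unit — the reported univariable
  associations; set `clinical_log_hr = NULL` for an IFN-only hazard). The
  default group HR is 6.2 with the baseline hazard calibrated numerically
  so the IFN-low stratum's marginal ten-year event fraction is 12%: these
  are the cohort-scale observations being emulated (they imply the ~55% vs
  ~12% ten-year event fractions), whereas HR 2.0 is the *power-design*
  hypothesis and is used as such in the design module and the calibration
  suites. An alternative log-linear score effect (`effect = "score"`)
  supports spline null calibration. Event types follow the published
  first-event mix (PAH 13/47, death 9/47, ...), excluding "new PAH" for
  subjects with baseline PAH.
* **Visit realization**: 6-monthly visits up to the event or censoring.
  An ILD truth drops FVC by 11 points at the event visit; a skin truth
  raises mRSS by max(5, ceil(0.25 b)); flag truths set the corresponding
  flag. Measurement noise (FVC sd 0.8, DLco sd 1.0 points) is kept far
  below the rule thresholds so that exactly the intended rule fires — the
  latent truth table lets tests verify ≥ 99% type-and-time recovery.
* **Censoring** is administrative with uniform staggered entry over 62
  months against a 120-month horizon, giving a median available follow-up
  of about 89 months; censoring is identical in distribution across IFN
  groups, matching the equal observed median censoring times.

What the generator does *not* emulate: correlation between baseline organ
involvement and the IFN score (covariates are drawn independently of the
score, matching the absence of baseline differences across IFN groups),
longitudinal IFN dynamics, informative censoring, and measurement
artefacts such as assay floors. Passing tests
therefore demonstrate that the machinery is correct under the assumed
structure, not that the published effect sizes are externally valid.

## Numerical choices and problem sizes

All times are months (floats) from the serum-sample baseline. Randomness
flows from a single integer seed; a replicate index offsets it
deterministically. Test-suite simulation sizes were chosen so each check
has conventional statistical resolution at fixed seeds: 1,000 replicates
for log-rank type-I error (binomial SE ≈ 0.7 points around 5%), 500 for
Cox CI coverage, 100 cohorts of n = 500 for hazard-ratio recovery
(SE of the geometric mean ≈ 3%), 40 cohorts for the stratification
ordering, 30 for spline null calibration. The acceptance script runs the
default 149-subject pipeline with 300 bootstrap iterations for
discrimination and RR intervals.

## Known limitations

* The adjudicator evaluates the written rules mechanically; it does not
  model chart-review confirmation of FVC drops, nor between-visit timing
  irregularities beyond storing raw visit times.
* RR confidence intervals versus the overall cohort have no published
  reference method; both provided options are approximations.
* The incident/dynamic ROC aggregation convention is the package's own;
  other implementations weight differently and will not agree numerically,
  though rankings and invariances coincide.
* Competing risks are deliberately out of scope: SSc-related death is part
  of the composite, and non-SSc death is treated as censoring.
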