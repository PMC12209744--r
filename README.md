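# ifnttcw

Serum type I interferon (IFN) score stratification of **time to clinical
worsening (TTCW)** in limited cutaneous systemic sclerosis (lcSSc).

lcSSc progresses slowly and across many organ systems, so trials and
observational analyses in this population lean on a composite
"Morbi-mortality" endpoint: the first of SSc-related death, new pulmonary
arterial hypertension, new/progressive interstitial lung disease, a major
cardiac event, renal crisis, severe gastrointestinal failure, hospitalized
digital vasculopathy, or qualifying skin worsening. This package is for
biostatisticians and clinical researchers who need that full analysis chain
as tested, reusable code:

* **IFN scoring** — the score for a serum sample is the mean natural log of
  six chemokine concentrations (pg/mL),
  `IFN = (1/6) * sum(ln c_j)` over CCL2, CCL8, CCL19, CXCL9, CXCL10,
  CXCL11; "high" means strictly above the healthy-control mean + 2 SD.
* **Endpoint adjudication** — the composite-event rules (e.g. an absolute
  FVC% drop of ≥ 10 points within 12 months, or 5–9 points with a ≥ 15%
  relative DLco decline; an mRSS rise of ≥ 5 units and ≥ 25% of baseline)
  applied to longitudinal visit records, yielding a first-event TTCW table.
* **Survival analysis** — Kaplan-Meier with Greenwood variance, fixed-time
  survival contrasts, restricted mean TTCW comparison (area under the KM
  curve up to the smaller group maximum), log-rank tests.
* **Cox modelling and discrimination** — univariable screens with
  Benjamini-Hochberg q-values, multivariable models with the IFN score as a
  penalized spline (linear + nonlinear components) or as a high/low class,
  complementary log-log diagnostics, incident/dynamic time-dependent ROC
  and C-index with bootstrap uncertainty.
* **Risk stratification** — acral (mRSS > 4 or digital-ulcer disease) and
  cardiopulmonary (PAH or ILD) involvement crossed with the IFN class into
  eight strata; upset-style intersection counts; relative risks versus the
  overall cohort at 24/36/48 months.
* **Power design** — Schoenfeld required events, incidence-based per-arm
  sample size, censoring inflation.
* **Synthetic cohorts** — a seeded generator that emulates the statistical
  structure the chain assumes (control/patient score distributions, baseline
  prevalences, a latent proportional-hazards first-event process realized as
  6-monthly visit trajectories, staggered administrative censoring), with a
  latent truth table so adjudication can be verified end to end.

## Worked example

```r
library(ifnttcw)

config <- run_config(seed = 42, n_boot = 0)  # n_boot = 1000 for reported SEs
report <- run_all(config)
print(report)
```

```
Cohort: 149 patients (62 IFN-high, 87 IFN-low); threshold 5.576
Events: 41 (27.5%); IFN-high 50% vs IFN-low 11%
Restricted mean TTCW (tau 114): high 75.4 vs low 105.6 months, p = 1.8e-07
Log-rank chi-square 28.90, p = 7.61e-08
Model 2 IFN-high HR 9.63 (95% CI 4.27-21.72)
Model 1 C-index 0.843; Model 2 C-index 0.820
High-risk stratum RR at 24 months: 2.65
```

Reading this: the generator drew a 149-patient cohort; the threshold 5.576
was derived from the 72 simulated controls (mean + 2 SD); 62 patients
scored above it. Adjudicating the simulated visit streams produced 41 first
events, concentrated in the IFN-high group (50% vs 11%), which translates
into a ~30-month shorter restricted mean TTCW, a multivariable hazard ratio
of 9.6 for IFN-high versus IFN-low (a noisy single-cohort estimate — the
low group contributes only a handful of events at n = 149; adjusted for
ILD, PAH, mRSS, DU disease and age), C-indices around 0.82-0.84, and a
2.7-fold relative risk at 24 months for the high-risk stratum (clinical
involvement + high IFN) versus the whole cohort.

Individual stages are exported — for instance:

```r
derive_threshold(c(4, 5, 6))      # mean 5, SD 1 -> threshold 7
schoenfeld_events(hr = 2)         # 66 required events
censoring_inflation(112, 0.25)    # 140
```

## Layout

```
R/                 implementation (data model, simulator, scoring,
                   adjudication, survival, Cox/ROC, strata, power, pipeline)
tests/testthat/    unit, property and acceptance tests with brute-force oracles
scripts/acceptance.R   end-to-end reproduction script
vignettes/         methods vignette (model, assumptions, design choices)
inst/cli/ttcw-ifn.R    thin command-line wrapper (simulate | power | run-all)
inst/extdata/      published summary-count fixture (transcribed)
```
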