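# hfsubtype

Unsupervised subtyping of incident heart-failure (HF) patients from
longitudinal coded electronic health records. The package is aimed at
epidemiologists and methodologists who want to stratify a disease cohort by
its *pre-diagnosis* coded history — diagnoses, procedures, medications — and
then ask whether the resulting clusters differ where it matters: one-year
mortality, HF hospitalisation, and incident comorbidities after diagnosis.

## What it implements

Two patient vectorisers feed one clustering-and-evaluation pipeline:

* **Transformer encoder** (the package's core): each pre-index event is
  embedded as the sum of code, age, calendar-year and visit-position
  embeddings and passed through a self-attention encoder stack. The model is
  trained with the InfoNCE contrastive objective over cosine similarities,

  `L = -(1/N) Σᵢ log[ exp(sim(aᵢ,pᵢ)/τ) / Σⱼ exp(sim(aᵢ,pⱼ)/τ) ]`,

  where the positive pair (aᵢ, pᵢ) is two stochastic views of the same
  patient (independent dropout masks, or span masking). Patient vectors are
  the token-wise mean of the averaged first and final layer outputs.
  Forward, backward and Adam are implemented in R and gradient-checked
  against finite differences in the test suite.
* **TF-IDF baseline**: smoothed `idf = ln((1+N)/(1+df)) + 1` over each
  patient's pre-index code multiset, raw counts as tf, unit-norm vectors.

Shared stages:

* **K-means** (seeded, best of 10 restarts) with nearest-centroid
  assignment of validation patients to derivation centroids.
* **Prediction strength** under 5-fold CV selects the number of clusters:
  the largest `k` whose fold-mean co-assignment consistency is ≥ 0.8
  (`ps(1) = 1` by definition; the fold score is the minimum over test-side
  clusters of the pairwise co-assignment proportion under training-side
  centroids).
* **Evaluation**: mean silhouette and Calinski–Harabasz on the validation
  cohort; per-cluster one-year Kaplan–Meier cumulative incidence for death
  and HF hospitalisation with Greenwood exponential (log-minus-log)
  confidence bands, `S^{exp(±z·√V/|log S|)}`; per-cluster code prevalence
  with the ≥30-percentage-point spread rule for discriminative codes; and
  incident-comorbidity curves that exclude prevalent cases.
* **Synthetic cohorts**: a generator with planted latent subtypes
  (signature-code carrier prevalence 0.9 vs background 0.05) and
  subtype-specific exponential outcome hazards, so the whole pipeline is
  testable without restricted data.

Cohorts are two delimited tables (patients, events) with an ISO-date
schema; every result object is a tibble or has `tidy()`/`glance()`/
`autoplot()` methods.

## Worked example

```r
library(hfsubtype)

sim <- simulate_cohort(default_synth_config(2000, seed = 1))
report <- run_subtyping(sim$cohort, run_config(vectoriser = "tfidf", seed = 1))
report
```

```
<run_report> tfidf arm
  chosen k: 3
  validation silhouette: 0.123, Calinski-Harabasz: 38.7
  one-year mortality range across clusters: 0.228
  one-year HF-hospitalisation range: 0.235
  discriminative codes (spread >= 0.30): 17
```

Prediction strength selects `k = 3` — the number of planted subtypes. The
discriminative codes are the 3 × 5 planted signature codes (plus, at this
seed, two of the planted comorbidity codes), and the one-year mortality
spread across clusters (0.228) tracks the planted hazard contrast (closed
form `exp(-0.10) - exp(-0.45) = 0.27` at the generator's hazards, estimated
here on 380 validation patients). Per-cluster detail:

```r
tidy(report)
#> # A tibble: 3 × 8
#>   cluster     n mortality mortality_lo mortality_hi hospitalisation  ...
#> 1       1   119     0.143       0.0913        0.220           0.182
#> 2       2   135     0.370       0.295         0.458           0.417
#> 3       3   126     0.159       0.105         0.235           0.288
```

`autoplot(report$curves_death)` draws the per-cluster incidence curves with
their bands; `autoplot(report$prevalence, min_spread = 0.3)` the
cluster-by-code heatmap. The transformer arm runs the same way with
`vectoriser = "transformer"`; see the methods vignette
(`vignettes/hfsubtype-methods.Rmd`) for the architecture, the contrastive
training scheme, every tunable default, and known desk-scale limitations.

A thin command-line wrapper with verbs `simulate`, `fit`, `select-k`,
`cluster`, `evaluate`, `run-all` lives at `inst/cli/hfsubtype.R`.

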