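# t2drisk

Machine-learning pipeline for **type 2 diabetes (T2D) diagnosis and
prognosis** from heterogeneous cohort data, written for biostatisticians
and epidemiological modellers who need the full chain — data quality
improvement, leakage-safe feature selection, tuned gradient-boosted-tree
models, threshold metrics, and explainability — as tested, seeded, reusable
R functions.

Two feature domains are modelled: **ENV** (lifestyle questionnaires,
anthropometry, diseases/treatments, and municipality-derived geospatial
features) and **CLI** (clinical biochemistry). They define two scenarios —
Environmental (ENV only) and Healthcare (HEA = ENV ∪ CLI) — crossed with two
tasks: **diagnosis** (undetected T2D at baseline, among individuals with no
prior diagnosis) and **prognosis** (incident T2D over a ~7.5-year follow-up,
from baseline features only), giving four models: D-ENV, D-HEA, P-ENV,
P-HEA.

The methodological core:

* **Geospatial augmentation** — 10-year municipal pollution series collapsed
  by a recency-weighted moving average, x̄ᵥ = Σᵢ i·xᵢ / w with w = n(n+1)/2;
  municipalities without records imputed by inverse-distance weighting over
  the k = 10 nearest covered municipalities, wₗ = 1/d(m,l)^β with β = 2;
  region labels that keep residents of one region on a single side of every
  split.
* **Imputer selection by Quality Score** — per feature, a menu of
  univariate and multivariate imputers is assessed on masked observed
  entries and gated by a distribution-discernibility test; the feature's
  score QS = γ + (1−γ)·μ combines completeness γ and imputability μ, and
  features with QS < 0.7 are dropped. Imputers fit on training rows only.
* **Quasi-constancy filter** — the Gini coefficient of the L-transform
  ℒ(x)ᵢ = s·σ/xᵢ (standardized, min-anchored-at-1 input; s the skew sign)
  is an index in [0,1] that is exactly 0 for constants; features below 0.05
  are discarded.
* **Feature selection** — permutation importance (AUROC drop on held-out
  data) over 100 region-grouped 70/30 splits with a 95% CI gate (keep iff
  the CI of the mean drop is strictly positive), then backward sequential
  selection on a paired battery of splits, keeping the subset with the best
  mean AUROC.
* **Modelling** — XGBoost classifiers tuned by a tree-structured Parzen
  estimator (20-fold grouped CV, `scale_pos_weight` in the space), evaluated
  by 10-fold region-grouped CV with vertically averaged ROC curves, and
  reported at the cutoff maximizing Youden's J = TPR + TNR − 1 (TPR, TNR,
  PPV, F1, J). Partial-dependence curves explain the selected features.

Cohorts of this kind are sensitive and not redistributable, so the package
ships a first-class **synthetic cohort generator** that reproduces the
structure the analysis must handle — 4617 individuals, 242 raw environmental
features engineered down to 84 ENV + 16 CLI, 319 municipalities (56 with
pollution coverage, leaving 50.4% of individuals without direct records),
block-structured missingness, 4200 diagnosis-eligible individuals at 5.4%
baseline prevalence and 1608 prognosis-eligible at 7.8% incidence — with
exact-count label thresholding so those numbers hold for every seed.

## Worked example

```r
library(t2drisk)

cfg    <- small_cohort_config(seed = 7)   # fast, structurally faithful
cohort <- inject_missingness(generate_cohort(cfg))
cohort
#> cohort_bundle: 400 individuals x 37 features (33 ENV, 4 CLI)
#>   labels: 36 known T2D, 20 baseline new diagnoses, 160 in follow-up, 11 incident
#>   observed entries: 95.5%

report <- run_pipeline(cfg, profile = "test")
report
#> report_bundle: 4 model(s), seed 7
#>   D-ENV  n=364 (20 positive), 3 selected, mean AUROC 0.680
#>   P-ENV  n=132 (11 positive), 2 selected, mean AUROC 0.772
#>   D-HEA  n=364 (20 positive), 5 selected, mean AUROC 0.834
#>   P-HEA  n=132 (11 positive), 2 selected, mean AUROC 0.770

m <- report$models[["D-HEA"]]
m$selected
#> [1] "age"             "fasting_glucose" "pollution_so2"   "waist_cm"
#> [5] "weight_kg"
m$evaluation
#> model_evaluation: 5-fold mean AUROC 0.834 (95% CI 0.699-0.968)
#> Youden-threshold metrics (fold mean +/- sd):
#>   TPR  0.90 +/- 0.22
#>   TNR  0.81 +/- 0.16
#>   PPV  0.26 +/- 0.06
#>   F1   0.39 +/- 0.05
#>   J    0.71 +/- 0.19
```

Reading the output: each model line reports the task sample after the
exclusion rules (e.g. 364 = 400 individuals minus 36 known-T2D), the
positive count, the size of the backward-selected feature subset, and the
mean cross-validated AUROC. The healthcare models beat the environmental
ones here because fasting glucose is the generator's strongest risk driver
and only HEA may select it — the structural contrast the scenario design
exists to expose. The Youden block gives the operating point that maximizes
sensitivity + specificity: here the model recalls 90% of positives at 81%
specificity, with the low PPV typical of a 5%-prevalence screening setting.
Identical configuration and seed reproduce this output byte for byte.

At production settings, use `cohort_config()` (the full 4617-individual
structure) and `profile = "paper"` (100 importance/selection repetitions,
20-fold tuning, 10-fold evaluation).

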