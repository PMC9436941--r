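# egfrtree

Accurate assessment of kidney function in chronic kidney disease (CKD)
hinges on the glomerular filtration rate (GFR). Measuring GFR directly
(e.g. by renal dynamic imaging with an exogenous tracer) is accurate but
impractical for routine care, so clinicians estimate it (eGFR) from serum
creatinine and cystatin C through published regression equations. No single
equation is accurate for everyone: each was fitted to a particular
population and loses calibration outside it. `egfrtree` implements a
*per-patient equation selector*: a classification tree, trained against
measured GFR, that decides from ordinary clinical covariates which of four
well-validated equations — BIS-2, CKD-EPI(CysC), CKD-EPI(Cr-CysC), Ruijin —
to trust for each patient, and then dispatches the estimate through that
equation.

The package is aimed at nephrology researchers with a cohort of CKD
patients carrying both biomarkers and a measured ("standard") GFR, who want
to train, inspect and evaluate such a selector — and at anyone needing a
clean, tested R implementation of the common eGFR equations.

## What is inside

* **Thirteen eGFR equations** (`estimate_egfr()`, `estimate_all()`):
  Cockcroft-Gault, MDRD and abbreviated MDRD with their Chinese
  modifications, CKD-EPI(Cr), CKD-EPI(CysC), CKD-EPI(Cr-CysC), the Asian
  modified CKD-EPI(Cr), BIS-2, MacIsaac, Ruijin and Xiangya — with exact
  unit handling (1 mg/dL creatinine = 88.4 umol/L), Du Bois body surface
  area `BSA = 0.007184 · W^0.425 · H^0.725`, and normalisation of absolute
  clearances to mL/min per 1.73 m².
* **Best-match labelling** (`assign_best_equation()`, `label_cohort()`):
  each patient's label is the candidate equation minimising
  |eGFR − sGFR·1.73/BSA|.
* **A from-scratch CART-style classification tree** (`fit_tree()`,
  `predict_tree()`, `variable_importance()`): entropy impurity
  H = −Σ pᵢ log₂ pᵢ, splits chosen by maximal information gain
  H(parent) − [n_L·H(L) + n_R·H(R)]/n over numeric thresholds and
  categorical subsets, deterministic tie-breaking, JSON serialisation.
* **Evaluation battery** (`rmse()`, `mae()`, `bland_altman()`,
  `comparison_report()`): RMSE = √(Σ(ŷ−y)²/n), MAE = Σ|ŷ−y|/n, and
  Bland–Altman bias ± 1.96·SD limits of agreement, reported for all 13
  equations plus the selector.
* **A synthetic cohort generator** (`generate_cohort()`): emulates a severe
  CKD population (median measured GFR ≈ 27.7 mL/min/1.73 m², 63.3% male,
  mean age 60.6) and plants a known covariate → equation mechanism by
  inverting the monotone equations, so the whole pipeline is testable
  without patient data.

## Worked example

```r
library(egfrtree)

# one patient, all 13 equations (mL/min per 1.73 m^2)
patient <- data.frame(age = 64, sex = "female", height = 158, weight = 55.6,
                      scr = 310, scr_unit = "umol/L", cysc = 2.8,
                      bun = 17.4, alb = 35.1)
round(estimate_all(patient)[1, ], 1)
#>  cockcroft_gault             mdrd      mdrd_abbrev          mdrd_cn
#>             15.8             13.7             13.1             16.5
#>   mdrd_cn_abbrev       ckd_epi_cr     ckd_epi_cysc  ckd_epi_cr_cysc
#>             21.4             13.1             18.2             14.7
#> ckd_epi_cr_asian             bis2         macisaac           ruijin
#>             13.7             20.1             26.8             19.0
#>          xiangya
#>             30.9

# full pipeline on a planted synthetic cohort
cohort <- generate_cohort(synthetic_config(n = 2000, seed = 7))
cohort <- label_cohort(cohort)                     # best-matched equations
cohort$split <- split_cohort(cohort, 0.7, seed = 7)
selector <- train_selector(cohort, tree_params(max_depth = 3))

head(selector$importance, 4)
#>               variable importance
#> 1 diabetic_nephropathy     100.00
#> 2                  bsa      92.21
#> 3                  bmi      54.70
#> 4                 rasi      11.83

metrics <- comparison_report(cohort, selector, split = "test")
metrics[metrics$method %in% c(egfr_candidates(), "tree_selector"),
        c("label", "rmse", "mae", "bias", "n")]
#>                     label  rmse   mae   bias   n
#>             CKD-EPI(CysC) 16.25 10.99  6.415 600
#>          CKD-EPI(Cr-CysC)  6.26  4.45 -1.908 600
#>                     BIS-2  7.56  5.97  3.062 600
#>                    Ruijin 11.51  8.75 -0.479 600
#>  Decision tree classifier  3.94  1.91 -0.365 600
```

The tree recovers the planted mechanism (diabetic nephropathy → BIS-2 at
the root, then body surface area, BMI, RASi use), and the dispatched
estimate ("Decision tree classifier") beats every fixed candidate equation
on held-out rows: RMSE 3.9 and MAE 1.9 mL/min/1.73 m² versus 4.5–11.0 MAE
for the single equations. Units throughout are mL/min per 1.73 m².

A command-line front end with `compute`, `simulate`, `label`, `train`,
`predict` and `run` subcommands lives at `inst/cli/egfr.R` (installed under
`system.file("cli", "egfr.R", package = "egfrtree")`).

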