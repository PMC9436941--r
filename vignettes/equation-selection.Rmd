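---
title: "Selecting the optimal eGFR equation with a classification tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the optimal eGFR equation with a classification tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfrtree)
```

## The problem and the model

Glomerular filtration rate (GFR) is the reference measure of kidney
function, but direct measurement (tracer clearance, renal dynamic imaging)
is too cumbersome for routine use. Instead, GFR is estimated from serum
creatinine (Cr) and/or cystatin C (CysC) through published regression
equations. Every such equation is a compromise: each was fitted to a
particular population (ethnicity, GFR range, body habitus, comorbidity mix)
and can be badly miscalibrated outside it. Obese or diabetic patients
hyperfilter; drugs such as calcium dobesilate interfere with creatinine
assays; muscle mass distorts creatinine independently of filtration.

`egfrtree` implements a *meta-estimator*: rather than developing yet
another equation, it learns which existing equation to trust for whom.
Given a cohort with measured GFR (sGFR):

1. **Label.** For every patient, compute eGFR under the four candidate
   equations — BIS-2, CKD-EPI(CysC), CKD-EPI(Cr-CysC), Ruijin — and label
   the patient with the equation minimising the absolute deviation
   |eGFR − sGFR| on the 1.73 m²-normalised scale
   (`sGFR_norm = sGFR_abs · 1.73 / BSA`, Du Bois BSA).
2. **Split.** Randomly assign ⌊0.7·n⌋ patients to a training set and the
   rest to a test set (a 518-patient cohort gives 362/156).
3. **Train.** Fit a classification tree on 28 demographic, comorbidity,
   medication and laboratory covariates with the best-matched equation as
   the class.
4. **Dispatch.** For a new patient, route through the tree to a predicted
   equation and return that equation's eGFR.
5. **Evaluate.** Compare all 13 implemented equations and the dispatched
   estimate against sGFR with RMSE, MAE and Bland–Altman limits of
   agreement on the test set.

The assumptions are modest: equation error structure must be *predictable
from covariates* (otherwise the tree cannot beat the best single equation),
and measured GFR must be trustworthy enough to serve as ground truth for
labelling.

## The equation library

All 13 equations are implemented exactly as published, with creatinine
converted internally to mg/dL (factor exactly 88.4) for every equation
except Xiangya, whose published form takes µmol/L. The CKD-EPI family is
piecewise in the marker with knots at Cr 0.9 (male) / 0.7 (female) mg/dL
and CysC 0.8 mg/L; both branches agree at the knot by construction, and the
test suite asserts continuity to 1e-9 relative. Values are returned at full
precision, never clamped or rounded.

Three design points deserve explanation:

* **Cockcroft-Gault numerator.** The source description of Cockcroft-Gault
  places *height* in the numerator; the classical formula uses *weight*.
  We implement weight by default and expose
  `cg_numerator = "height_as_printed"` for fidelity to the printed variant,
  since the printed form is almost certainly a typographical slip but the
  choice cannot be settled from the text. Cockcroft-Gault is evaluated in
  absolute mL/min and normalised to 1.73 m² via the patient's BSA; all
  other equations are already indexed.
* **MDRD units.** The MDRD family's urea nitrogen and albumin coefficients
  were fitted to conventional units (mg/dL, g/dL). Cohort files carry SI
  values (mmol/L, g/L); `si_units = TRUE` (default) converts internally
  (BUN mg/dL = mmol/L × 2.801; Alb g/dL = g/L / 10), `FALSE` passes values
  through for users whose files already hold conventional units.
* **The "Chinese modification abbreviated MDRD"** is implemented exactly as
  printed (170·Cr^−0.999·Age^−0.176·1.202, ×0.762 if female) even though it
  looks like the full Chinese MDRD with the BUN/albumin terms dropped
  rather than a re-fitted abbreviation; fidelity to the printed formula was
  preferred over speculation. Likewise Xiangya's trailing 0.8526126 factor
  is treated as a female-only multiplier.

## The classification tree

The tree is written from scratch (no recursive-partitioning dependency) so
that the split criterion matches the procedure exactly: entropy impurity
H = −Σ pᵢ log₂ pᵢ (Gini available by configuration), splits chosen to
maximise the information gain H(parent) − [n_L·H(L) + n_R·H(R)]/n.

* **Candidates.** Numeric variables: midpoints between consecutive distinct
  sorted values. Categorical variables with ≤ 12 observed levels: every
  binary partition of the levels (2^(k−1) − 1 candidates, evaluated on
  aggregated per-level counts, so this is cheap); above 12 levels, levels
  are ordered by their within-level proportion of the overall majority
  class and cut along that ordering — the standard CART reduction.
* **Admissibility.** Both children must contain at least
  `min_samples_leaf` rows and the gain must reach `min_gain`. With the
  default `min_gain = 0` a zero-gain split of an impure node is *kept*:
  XOR-style interactions produce exactly this situation (no single split
  helps, but the children become separable), and the depth and node-size
  limits bound the resulting growth.
* **Determinism.** Equal-gain ties are resolved by variable name
  (lexicographic), then by smallest threshold (numeric) or
  lexicographically smallest left-level set (categorical). Fitting the same
  table twice yields byte-identical trees.
* **Stopping.** Purity, `max_depth` (default 5), `min_samples_split`
  (default 20), `min_samples_leaf` (default 7), or no admissible split.
  These defaults echo common recursive-partitioning practice and produce
  shallow trees of the kind the procedure reports (about six active
  variables); there is deliberately *no* cost-complexity pruning — the
  source procedure's hyperparameters are unstated, and pre-pruning
  reproduces the shallow regime with fewer moving parts.
* **Missing data.** Fitting requires complete covariates. At prediction
  time a row missing a split variable (or carrying an unseen categorical
  level) is routed to the larger child — the simplest defensible rule;
  surrogate splits are out of scope.
* **Prediction ties.** A leaf predicts its majority class; exact count ties
  are broken by the fixed candidate priority order BIS-2 < CKD-EPI(CysC) <
  CKD-EPI(Cr-CysC) < Ruijin, which is also the tie order used in
  best-match labelling.
* **Importance.** score(v) = Σ n·gain over nodes splitting on v, rescaled
  to max 100. The covariate filtering step reported in the source ("15
  relatively important variables") has no stated criterion, so it is
  exposed as an ordinary ranked table the user may threshold, not
  hard-coded.
* **Serialisation.** Trees round-trip through a JSON node list; thresholds
  and gains are stored both in decimal and as C99 hex-float strings so the
  round trip is bit-exact, as the interface contract requires.

One departure from the offered covariate list: biopsy pathology enters the
default 28-variable list as the biopsy-confirmed *diabetic nephropathy
indicator* rather than the raw multi-level pathology category. Most
pathology levels are sparse (< 4% each), and many-level categorical
variables hold a well-known spurious advantage in greedy split search (more
candidate partitions to overfit with); offering the raw category lets it
displace the DN flag at the root on noise alone. Users can pass
`covariates =` to `train_selector()` to restore the raw category.

Labelling offers absolute (default) and relative deviation. A *signed*
deviation option was considered and rejected: the argmin of a signed
difference simply selects the most negatively biased equation and is not a
best-match rule.

## The synthetic cohort: what it emulates and what it does not

No patient-level data ship with the package; the generator
(`synthetic_config()`, `generate_cohort()`) produces cohorts whose
*marginals* mirror a severe Chinese CKD population: age ~ truncated
N(60.6, 12²) on [18, 95]; 63.3% male; BSA ~ N(1.7, 0.15²) and
BMI ~ N(25, 3.5²), with height and weight *back-solved* so Du Bois BSA and
BMI hold exactly; diabetic nephropathy 14.3%; RASi use 31.3%; the other
comorbidity/medication flags at their reported prevalences; 24-h urine
protein log-normal matched to quartiles 224/2782 mg; measured GFR
log-normal with median 27.7 and quartiles 15.2/36.8 mL/min/1.73 m²,
truncated to [2, 120]. Urea nitrogen and albumin are drawn from plausible
marginals purely so the MDRD family is computable — they carry no signal.
sGFR is generated on the *normalised* scale and converted to absolute
mL/min through each record's BSA, so the labelling stage's normalisation is
exercised non-trivially.

A hidden covariate → equation mechanism is planted with first-match rules
(thresholds configurable, defaults shown):

1. diabetic nephropathy → BIS-2;
2. RASi and age > 65 → Ruijin;
3. BSA < 1.65 or BMI < 22 → CKD-EPI(Cr-CysC);
4. otherwise → CKD-EPI(CysC).

**Biomarker construction.** The two biomarkers give only two degrees of
freedom against four candidate equation values, so the generator can pin
exactly two: the *planted* equation is inverted to hit
sGFR · exp(ε), ε ~ N(0, 0.05), and one other equation is pinned at a signed
log-offset sign·|N(0.30, 0.10)| (creatinine via Ruijin when CysC carries
the planted signal, and vice versa; for the two-marker equations,
creatinine takes the offset and CysC is solved from the planted equation
given that creatinine). The remaining two equation values are *derived*,
and their deviations combine the offset with systematic between-equation
differences — which can partially cancel. The offset's **sign is therefore
chosen per row to maximise the smallest deviation of the non-planted
candidates** from the measured GFR. Without this, a naive zero-centred
"large noise" draw lands within the planted-noise band often enough that
best-match labelling recovers the hidden equation for only ~80% of rows,
below the generator's own ≥ 85% identifiability contract; with it,
recovery is ~93% under the default configuration. The offset magnitude is
deliberately bounded away from zero (mean 0.30, SD 0.10) for the same
reason. Setting `noise_other_bias = 0` and `noise_other_sd =
noise_planted` removes the asymmetry entirely (the sign becomes a fair
coin) and recovery collapses toward chance — the degenerate control the
test suite asserts.

What a green planted-recovery test establishes: the labelling, split
search, tree growth, prediction and dispatch stages jointly recover a
genuine axis-aligned covariate → equation mechanism of realistic prevalence
structure at n = 2000. What it does **not** establish: that such a
mechanism exists in real patients, that the real mechanism is axis-aligned,
or that the error magnitudes resemble a hospital cohort's. Real biomarker
error is assay- and physiology-driven and correlated with covariates in
ways the generator does not model (no assay error structure, no
longitudinal visits, no comorbidity correlation beyond marginals). The
source study's reported error figures come from a private cohort and are
deliberately not used as test targets.

## Numerical and procedural choices

* Entropy uses the 0·log 0 = 0 convention; closed forms ({2,2} → 1 bit,
  pure → 0, uniform 4 → 2 bits) are asserted exactly.
* Percentiles use linear interpolation between order statistics
  (`quantile` type 7), the most common convention; summary tables depend
  on it.
* Bland–Altman limits use bias ± 1.96·SD with the sample SD (n − 1); the
  multiplier is configurable since the convention is not universal. The
  x-axis of the pair data is the mean of the two methods (the classical
  choice; plotting against sGFR alone is a documented alternative the user
  can derive from the returned pairs).
* Train-fraction rounding is ⌊n·f⌋, which reproduces the 362/156 partition
  of 518 rows at f = 0.7. The split is a uniform random permutation,
  deterministic per seed; the original study's split membership is
  unrecoverable and no attempt is made to match it.
* Truncated distributions are sampled by inverse-CDF transforms of uniform
  draws (never rejection), so the number of RNG draws is fixed and
  per-seed determinism is robust to parameter changes.
* Equation inversion is closed-form per branch; for piecewise equations the
  branch is chosen by comparing the target with the equation's value at the
  knot, so round trips are exact (≤ 1e-8 relative asserted over random
  targets) including exactly at the knot.
* Patients on calcium dobesilate are *not* excluded anywhere; the flag is
  an ordinary covariate (the selector is meant to learn around such
  interference, not to discard it).
* Structured-text configuration files (pipeline and CLI) are JSON: the
  environment provides a JSON parser but no YAML parser, and nothing in the
  contract requires YAML specifically.

## Limitations

* The tree is a single weak classifier by design (interpretability over
  accuracy); no forests, boosting, surrogate splits or pruning paths.
* No pediatric equations, race coefficients beyond those printed, CKD
  staging, P30 accuracy, concordance correlation or significance testing
  between methods.
* Cross-validation and hyperparameter search are out of scope: the
  procedure uses a single 70/30 split.
* The selector's advantage on synthetic data is by construction an upper
  bound on what real cohorts can show; external validation on an
  independent measured-GFR cohort is the only honest test of clinical
  utility.
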