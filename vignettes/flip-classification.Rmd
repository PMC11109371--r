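---
title: "Flip-based classification of unbalanced biomarker cohorts"
author: "cactusflip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flip-based classification of unbalanced biomarker cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cactusflip)
```

## The problem

Patients presenting with haematuria (blood in urine) form a heterogeneous
and heavily unbalanced population: haematuria clinics see far more men than
women (roughly 2.5:1), and within each gender far more patients with an
identifiable cause ("sick" — infection, chronic kidney disease, benign
disease, bladder or other cancer) than patients in whom no cause is found
("healthy"). A multi-marker panel of urine and serum biomarkers is an
attractive non-invasive alternative to cystoscopy and CT urography for
pre-stratifying these patients, but conventional learners (decision trees,
random forests) fitted to such data tend to collapse onto the majority
class: sensitivity looks excellent while specificity — the clinically
valuable ability to spare healthy patients invasive work-up — approaches
zero.

`cactusflip` implements a classification pipeline built around a two-state
abstraction of each biomarker and a prior-free conditional-probability
classifier (the CACTUS approach), together with the standard baselines it
should be compared against and a synthetic cohort generator that reproduces
the structural pathologies of real haematuria data (imbalance, skewness,
detection limits, gender-specific markers, missingness).

## The model

### Flips

Each quantitative biomarker $x$ is reduced to a two-state *flip*: state
**U** when the (log-scale) value lies strictly above a per-marker cut-off
$t_x$, state **D** when it lies at or below it. The cut-off is chosen by
maximizing $|J|$ over all candidate thresholds, where
$J = \text{sensitivity} + \text{specificity} - 1$ is Youden's index for the
rule "value $> t$ ⇒ sick". Candidates are the midpoints between consecutive
sorted unique values plus $\pm\infty$ sentinels, so the threshold never
coincides with an observed value; ties are broken towards the smallest
threshold, and equality with the threshold encodes as D. We maximize $|J|$
rather than $J$ because a marker may run *lower* in the sick class; the
classifier consumes both $P(U\mid c)$ and $P(D\mid c)$, so only the
placement of the threshold matters, not the direction.

The cut-point criterion is a deliberate design choice: Youden's $J$ is the
standard ROC-derived operating point, and the choice is isolated inside
`youden_cutoff()` so alternatives (closest-to-(0,1), fixed-specificity)
could be swapped without touching anything else.

### Conditional probabilities and ranks

For every marker, flip state $f \in \{U, D\}$ and class
$c \in \{\text{sick}, \text{healthy}\}$, the model stores the smoothed
conditional probability

$$P(f \mid c) = \frac{n_{f,c} + \alpha}{n_c + 2\alpha},$$

with $n_{f,c}$ the count of state $f$ among class-$c$ patients with an
observed value and $\alpha$ a pseudocount (default $0.5$, the Jeffreys
prior; $\alpha > 0$ keeps every probability strictly inside $(0,1)$ so
log-products stay finite). Missing flips are excluded from the counts.

The *rank* of a flip measures how much its conditional probability varies
across the $N$ classes:

$$R_{xf} = \frac{\sum_{i<j} \left| P(f \mid c_i) - P(f \mid c_j) \right|}
{\binom{N}{2}},$$

which for two classes is simply $|P(f\mid\text{sick}) -
P(f\mid\text{healthy})|$. Ranks are the pipeline's importance/explainability
score; for binary flips $R(U) = R(D)$ by the complement rule, an identity
asserted on every fit. The implementation supports general $N$ even though
the study pipeline is two-class.

### The cost function

A patient with observed flips $f_1, \dots, f_m$ receives one *cost* per
class,

$$C_s = \prod_i \sigma_{s,i}^{x_i}, \qquad
\sigma_{s,i} = P(f_i \mid s),$$

where $x_i$ is 1 when marker $i$ is observed and 0 when missing (so missing
markers contribute a neutral factor of 1). The class with the greater cost
is the prediction. This is a naive-Bayes likelihood *without a prior term*:
because no $P(s)$ factor enters, the decision is invariant to duplicating
all patients of one class, which is exactly the property that protects the
classifier when sick outnumbers healthy 10:1. The exponent-as-indicator
reading of the cost function is the only one consistent with both the
"greater value wins" decision rule and the claimed robustness to class
imbalance; treating the exponent as the raw biomarker value would reinstate
scale dependence that the flip abstraction exists to remove.

Costs are accumulated in log space — an 80-marker product of probabilities
underflows double precision — and the test suite verifies that
`exp(log cost)` equals the naive direct product to $10^{-12}$ relative
error for up to 12 markers, over all $2^{12}$ flip patterns. Exact ties
predict sick: in a screening context the false negative is the costly
error. The tie class is configurable.

## Evaluation

Positive class is sick throughout. From the confusion counts we report
sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$, accuracy and *balanced
accuracy* $(\text{sens}+\text{spec})/2$, the headline metric under
imbalance. Each model is tested against chance with an uncorrected Pearson
$\chi^2$ on the 2×2 prediction-vs-truth table (the variant is recorded in
output metadata; a degenerate table with a zero marginal reports $p=1$ with
a warning). Models are compared pairwise with McNemar's test on the
discordant correct/incorrect pairs: exact two-sided binomial at
$p = 1/2$ when $b + c < 25$, else the continuity-corrected
$\chi^2 = (|b-c|-1)^2/(b+c)$; $b + c = 0$ gives $p = 1$ exactly. Metric
values are kept at full precision internally and rounded only in reports, 3
decimals, half away from zero.

Two evaluation modes exist for the flip classifier. *Resubstitution* fits
cut-offs and probabilities on a subset and evaluates on the same subset —
the optimistic view closest to how such results are usually tabulated.
*Cross-validation* (the default) runs stratified 10-fold CV repeated 3
times, re-fitting medians, cut-offs and the model inside every training
fold and pooling per-patient predictions by majority vote across repeats,
so neither imputation nor threshold selection leaks into held-out folds.
Both modes are reported because published tables rarely state which one
they used.

## Baselines

* **k-means silhouette scan** — features are z-scored (80 markers on wildly
  different scales would otherwise let one dominate the distances), k-means
  is run for each candidate $k$ with 10 restarts, and the mean silhouette
  width selects $k$. Silhouette is undefined at $k=1$, so a scan request
  starting at 1 records $k=1$ as undefined and effectively starts at 2.
* **Single-marker logistic regression** — per marker, `label ~ marker` is
  fit linearly and with a natural cubic spline (3 df, the smallest basis
  that can express a U-shaped risk); the spline is kept only when the
  deviance test prefers it at 0.05. Balanced accuracy is computed from
  resubstitution predictions at threshold 0.5, which deliberately exposes
  the majority-class collapse of weak markers under imbalance.
* **Decision tree / random forest** — `rpart` (cost-complexity pruned at
  the internal-CV minimum) and `randomForest` (500 trees, default mtry; no
  hyper-parameter search because none is warranted at these sizes) under
  the same stratified 10-fold × 3 harness, predictions pooled by majority
  vote, forest importances averaged over the 30 fits.
* **LIME-style local explainer** — quartile bins learned from background
  data, perturbed samples drawn by resampling bins, proximity weights from
  an exponential kernel on the fraction of mismatched bins, and a
  ridge-regularized weighted linear surrogate (intercept unpenalized) whose
  coefficients are the reported feature contributions with the instance's
  bin ranges. This is a documented surrogate in the spirit of LIME, not a
  reimplementation of any particular LIME package's internals — its role
  here is decision-boundary reporting, for which bin edges and signed
  weights suffice.

## The synthetic cohort generator

Real haematuria biomarker cohorts are not publicly distributable, so the
generator is a first-class, tested module: it defines the conditions under
which every downstream claim is verified. Its defaults emulate the
structure of a real haematuria clinic population:

* 675 patients: 485 males (444 sick : 41 healthy) and 190 females
  (111 sick : 79 healthy) — the per-gender imbalance is the phenomenon of
  interest, and the "both genders" subset is the pool of the two.
* Raw marker values are $\exp(\mathcal{N}(\mu_c, \sigma))$ — lognormal, so
  positive and right-skewed, which is what the log-transform preprocessing
  assumes. 24 markers with realistic names, units and scales; 10 are
  informative, with a log-scale class shift of
  $2\sigma\,\Phi^{-1}(0.7) \approx 0.52$ at $\sigma = 0.5$, i.e. a
  class-conditional flip-probability gap of 0.4 at the midpoint threshold —
  a moderate, realistic single-marker effect (each informative marker alone
  has AUC ≈ 0.77).
* serum tPSA is male-only: females sit exactly at the detection limit.
* Values below a per-marker LOD are stored as censored flags (no number);
  preprocessing substitutes $0.9 \times$ LOD. ~3% of cells are missing at
  random.
* Age is drawn $\mathcal{N}(65, 10)$ for sick and $\mathcal{N}(58, 10)$ for
  healthy, truncated to [18, 95], reflecting the higher malignancy risk
  above age 60; the generator's diagnosis mix spreads sick patients over
  six subcategories (infection, benign disease, bladder cancer, …) that by
  default do not shift marker levels, because no per-subcategory effect
  sizes are available to emulate — an optional hook exists in the config.

What the generator does **not** emulate: real per-marker marginal
distributions, inter-marker correlation (markers are conditionally
independent given the class, which favours the naive-Bayes-style
classifier; passing tests therefore demonstrate correctness of the
machinery and the imbalance-robustness mechanism, not expected real-data
performance), assay batch effects, or label noise. Published real-data
metric values are consequently not reproduction targets; the test suite
instead verifies the arithmetic identities those published tables must
satisfy and the qualitative ordering (flip classifier ≫ tree/forest under
male-subset imbalance) on synthetic cohorts.

One printed inconsistency in the source cohort description is worth
recording: the per-gender sick counts (444 males, 111 females) sum to 555,
not to the 523 quoted as the combined sick count. The generator therefore
exposes every count as configuration rather than reconciling them; the
default uses the per-gender counts, and pooled subsets report whatever they
actually contain.

## Preprocessing order and numerical choices

The pipeline is: below-detection substitution → label derivation → natural
log transform → gender split → per-subset median imputation. Natural log
because the base only rescales and every downstream step is
monotonicity-invariant. Medians are computed per subset *after* splitting
so a gender-specific marker's imputed value cannot leak across genders, and
inside CV they are computed on training folds only. Markers constant within
a subset (tPSA in females) are dropped from that subset with a message.
Median imputation is idempotent and never alters an observed value; both
properties are asserted in tests.

Degenerate inputs are handled explicitly: an all-identical marker yields a
$J=0$ cut-off with a warning; a class absent from a fitting call is an
error; $\alpha = 0$ with a zero flip count is an error directing the user
to $\alpha > 0$; a patient with no observed flips cannot be scored.

## Problem sizes used in the test suite

Simulation-based tests run at the smallest sizes at which the tested
property is stable: parameter-recovery checks use 1000–2000 patients per
class (binomial standard error ≈ 0.015, against a ±0.03 tolerance at 95%
of markers); the imbalance-robustness experiment runs the full 485-patient
male-subset configuration over 20 seeds; oracle-equivalence checks
(exhaustive threshold enumeration, direct-product classification over all
$2^{12}$ flip patterns, binomial tail sums for all $b+c \le 24$) are exact
and sized to enumerate completely.

## A worked run

```{r, eval = FALSE}
cfg <- study_config(seed = 1, mode = "cv")
report <- run_study(cfg)
print(report)
report$mcnemar$male          # pairwise model comparison
report$rank_tables$male      # top-10 markers by rank
report$boundaries            # decision boundaries, raw scale
```

On the default synthetic cohort this reproduces the qualitative published
pattern: the flip classifier's balanced accuracy stays high on the heavily
unbalanced male subset while tree and forest sensitivity saturates and
specificity collapses, k-means selects $k = 2$ on every subset, and no
single marker approaches the multi-marker performance.

## Known limitations

* Markers are treated as conditionally independent by the classifier; a
  pair of strongly correlated informative markers is double-counted.
* The flip abstraction discards within-state magnitude: a value far above
  the cut-off counts exactly as much as one just above it.
* Cut-offs are fit per marker in isolation (marginal ROC), not jointly.
* The LIME-style explainer is a faithful local surrogate only to the extent
  the quartile binning matches the black-box model's own resolution.
* With only ~4 healthy males per CV fold, per-fold specificity estimates
  for the male subset are coarse; pooling across folds and repeats
  mitigates but does not remove this.
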