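---
title: "Methods: biomarker panel discovery for urinary metabolomics"
author: "metabopanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker panel discovery for urinary metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabopanel)
```

# Scope and model of the data

`metabopanel` implements a complete discovery workflow for targeted urinary
metabolomics in a three-group case-control design — healthy controls (CTRL),
type 2 diabetes with preserved renal function (DM2), and diabetic
nephropathy (DN). The measured quantity is an absolute concentration table
(µM) of up to a few hundred metabolites per urine sample, together with a
per-metabolite assay limit of detection (LOD), per-sample urinary creatinine
(mM), and clinical covariates, chiefly the glomerular filtration rate (GFR,
mL/min/1.73 m²).

Urinary concentrations are strictly positive, right-skewed, and confounded
by urine dilution. The workflow therefore models them on the log scale and
removes dilution by dividing by creatinine. Values below the LOD are not
zeros but left-censored observations; they are carried as missing with the
LOD retained, and handled explicitly in preprocessing.

# Preprocessing chain

The chain is fixed and order-enforced:

1. **Missingness filter** — metabolites with *strictly more than* 20% of
   values below LOD are removed. Exactly 20% is retained: the rule is read
   literally, and the boundary case is covered by a dedicated test.
2. **Left-censored imputation** — each remaining below-LOD value is replaced
   by one fifth of that metabolite's minimum positive observed value. The
   minimum is computed over all samples of the table at hand; inside
   cross-validation this means the training partition only (see below).
3. **Creatinine normalization** — division by per-sample creatinine,
   yielding µmol/mmol creatinine. The CSV reader accepts creatinine in mM or
   mg/dL (converted by 0.0884).
4. **Log transformation** — natural log. The base is not identified by the
   downstream analysis: any fixed base rescales columns by a constant and
   Pareto scaling absorbs the difference.
5. **Pareto scaling** — per metabolite, subtract the mean and divide by the
   square root of the sample (n−1) standard deviation. Constant columns map
   to zero. Pareto scaling damps, but does not erase, the dominance of
   high-variance metabolites; after scaling, each column's variance equals
   the original column's standard deviation, an identity the tests check to
   1e-9.

Every parameter of the fitted chain — retained metabolites, imputation
minima, creatinine flag, scaling means and standard deviations — is frozen
by `fit_preprocess()` and re-applied to held-out samples by
`apply_frozen()`. All cross-validation in the package refits preprocessing
inside each training fold and freezes it onto the corresponding test fold,
so no information flows from test to train. An instrumentation test
verifies the contract directly: flipping a held-out sample's label changes
nothing about its out-of-fold prediction.

If a metabolite fails both the missingness filter and imputation
preconditions, filtering is applied first, following the order in which the
steps are defined.

# Univariate statistics

Group comparisons are nonparametric throughout: two-sided Mann-Whitney U
for two groups, Kruskal-Wallis for three, both with average ranks and
tie-corrected variances (as implemented in base R's `wilcox.test` and
`kruskal.test`), and Benjamini-Hochberg false-discovery-rate control within
each comparison family. Fully tied (zero-variance) comparisons are assigned
p = 1. Metabolite-covariate association uses Spearman rank correlation;
rank-based methods match the nonparametric stance of the group tests, and
all of them are invariant to strictly monotone transforms of the data — so
their results do not depend on where in the (monotone) preprocessing chain
they are computed.

Clinical tables report numeric variables as mean ± SD with a Kruskal-Wallis
p-value and categorical variables as count (%) with a chi-squared test for
trend. A D'Agostino-Pearson K² omnibus statistic is attached to numeric
variables for reference only — it informs reporting, not inference, and no
parametric branch exists.

# PLS-DA

`fit_plsda()` implements NIPALS partial least squares: a single 0/1
response column for two classes, a one-hot indicator matrix for three. Per
component: iterate weights, scores and loadings to convergence, then
deflate both blocks. Variable importance in projection is

$$\mathrm{VIP}_j = \sqrt{p \cdot \frac{\sum_a SS_a\, w_{ja}^2}{\sum_a SS_a}},$$

with unit-norm weight vectors and $SS_a$ the response sum-of-squares
explained by component $a$; the mean of the squared VIPs is exactly 1,
asserted to 1e-8. Features with VIP > 1.5 are flagged, matching the
screening threshold used with this assay family.

Model quality is summarized by cumulative $R^2Y$ and cross-validated
$Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$, with preprocessing refrozen inside
each fold and TSS measured against training-fold class means. The component
count is chosen to maximize $Q^2$, capped at 5. The permutation test
permutes class labels, recomputes $Q^2$ at the fitted component count, and
reports $p = (1 + \#\{Q^2_{perm} \ge Q^2_{obs}\})/(1 + n_{perm})$, which is
floored at $1/(n_{perm}+1)$ by construction. $Q^2$ was chosen as the
permutation statistic because it is the quantity the validation reports
pair with; prediction-accuracy or separation-distance variants would be
straightforward alternatives but are not implemented.

# Strategy 1: LASSO panel

`lasso_select()` fits the L1-penalized logistic path by coordinate descent
(glmnet) and picks the penalty by stratified 10-fold cross-validated
deviance; the deviance-minimizing `lambda.min` is the default, `lambda.1se`
is available. Nonzero-coefficient features, ranked by absolute coefficient,
seed `stepwise_refit()`: bidirectional stepwise selection by AIC on an
unpenalized logistic model, started from the null model with a final guard
that returns the full candidate fit whenever greedy search ends above its
AIC. Perfect separation is detected and resolved by a vanishing ridge
refit (λ = 1e-6) with a warning.

Panel validation follows the protocol of validating an *already chosen*
panel: `kfold_cv_auc()` refits preprocessing and the panel's coefficients
inside each training fold but keeps the feature list fixed, pooling
out-of-fold probabilities into one ROC with a DeLong 95% CI. This mirrors
how a selected clinical panel is internally validated, and deliberately
excludes selection uncertainty; passing a builder function instead re-runs
the entire selection per fold for a fully nested estimate.
`mccv_roc()` draws class-balanced training subsamples (two thirds of each
class, 500 splits by default), reports the mean split AUC with percentile
95% CI, and pools held-out scores for the curve. `compare_rocs()` tests a
paired AUC difference by randomly exchanging the two models' scores within
samples.

The two published fixed-coefficient diagnostic equations for the DM2-vs-DN
contrast are shipped as `published_models()` and can be applied to any data
in the frozen scaled space; they are evaluation objects, not refits, since
their coefficients were estimated on the original cohort.

# Strategy 2: GA + elastic net with nested CV

The wrapper selection engine encodes metabolite subsets as binary masks and
evolves them with tournament selection (size 4), two-point crossover
(probability 0.8), elitism (top 3), and adaptive bit-flip mutation. The
mutation schedule follows the convention of generational GA frameworks: the
probability that a child undergoes mutation decays linearly from 0.25 to
0.05 across generations, and a mutated child flips each bit independently
with probability 1/p. Reading 0.25 as a *per-bit* rate would flip a quarter
of all bits per child and reduce the search to noise — with 268
metabolites, about 67 flips — so the per-individual reading is used. The
initial population draws each bit with probability `max_features/p`,
seeding the search near the sparsity the complexity penalty targets.
Equal-fitness ties resolve toward fewer features (an epsilon far below the
plateau tolerance), making runs deterministic given the seed. Evolution
stops at the generation cap or after 10 generations without improvement
beyond 1e-6.

Fitness of a mask is the mean validation MCC of an elastic-net logistic
fit (L1/L2 ratio 0.5) over a list of train/validation splits, minus
`penalty_weight × max(0, k − max_features)` with defaults 0.05 and 8; an
empty mask scores −1. The elastic-net strength is expressed so that
`en_strength = 1` equals the common inverse-regularization default
(glmnet λ = strength/n); the value is configurable because the original
protocol states the mixing ratio but not the strength.

`nested_cv()` wires this into unbiased evaluation: an outer CV loop
(leave-one-out by default; k-fold selectable) holds samples out entirely;
within each outer training set, an inner stratified 4-fold CV defines four
train/validation splits, and one GA runs per inner fold, maximizing the
mean MCC over the three splits that do **not** validate on its own fold.
The four runs therefore differ in which validation folds drove them,
giving the per-feature selection frequencies the meaning of a stability
measure; a split-level fitness cache is shared across the runs. Features
selected by at least half of the inner folds are retained, an elastic net
is retrained on the full outer-training set (optionally with a z-scored
clinical covariate such as GFR forced in), and the held-out samples are
scored. Pooled out-of-fold probabilities feed `bootstrap_metrics()`:
AUC, accuracy, F1, sensitivity, specificity, MCC and Brier score with
percentile 95% CIs from 2000 nonparametric resamples of the
(probability, label) pairs; replicates that lose a class are redrawn.

A known property worth stating plainly: with ~40 samples, subset selection
by cross-validated MCC admits overfit masks — among thousands of candidate
subsets some combination of noise features will outscore the true markers
on 32 validation samples. Selection stability at the 50% threshold is
therefore only achieved by features whose individual effects are strong;
weak-to-moderate markers (one standard deviation or less on the log scale)
are selected intermittently. This is a property of wrapper selection at
this sample size, not of the implementation — the tests demonstrate both
sides: a dominant feature is recovered essentially always, while a panel of
moderate planted effects yields partial stability.

# Over-representation analysis

`ora()` is a database-agnostic hypergeometric over-representation test:
user-supplied metabolite sets (GMT format) are intersected with a universe,
and each set receives a one-sided upper-tail p-value, a BH q-value across
sets, and an enrichment ratio (observed/expected hits). The universe
defaults to the metabolites surviving preprocessing — the features that
could have been selected define the sampling frame; passing the assay's
full panel (or any other frame) is a one-argument change and materially
affects p-values, so the choice is the caller's.

# Synthetic data generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, so every stage is testable without patient data:

* 20 samples per group by default, 268 metabolites, log-normal
  concentrations (baseline natural-log mean 1, SD 1).
* A planted-effect table shifts chosen metabolites in one group; the
  default plants four metabolites down and four up in DN at |log2| = 2
  (4-fold). The magnitude was calibrated so that small planted panels
  reach the cross-validated discrimination reported for real urinary
  panels in this setting (AUC ≈ 0.8–0.95); depletion effects are capped in
  practice by the censoring mechanism below, since a strongly depleted
  metabolite falls below the LOD and is then removed by the missingness
  filter — a realistic interaction worth keeping in mind when planting
  strong negative effects.
* Type-I left-censoring: each metabolite's LOD sits at the 5% quantile of
  its baseline distribution (30% for a designated block, so the
  missingness filter has work to do); values below it are recorded missing
  with the LOD retained.
* Per-sample creatinine is log-normal (median 10 mM, log-SD 0.4).
* GFR is drawn per group with the means 112.5 / 107.8 / 71.2 and SDs
  14.28 / 13.92 / 31.95 of the emulated cohort; designated toxin-like
  metabolites share a latent renal-function factor with GFR, inducing a
  target negative correlation (−0.5 by default) — the simplest generative
  route to the uremic-toxin/GFR associations the analysis should recover.
* Age, sex and albumin-to-creatinine ratio are generated per group at
  cohort-like values for the clinical summary table.

The generator makes no attempt to simulate chromatographic or
mass-spectrometric artifacts, batch effects, inter-metabolite pathway
correlation (beyond the single renal factor), or realistic per-metabolite
distributional diversity. Passing tests on this generator therefore
demonstrates correctness of the statistical machinery under the assumed
model, not performance on real cohorts.

# Numerical and design choices

* Random draws all flow from one seed, salted per stage
  (`derive_seed()`), so reruns are byte-identical and stages are
  decoupled.
* Stratified fold assignment is deterministic given its seed;
  leave-one-out assignment is label-independent, which is what makes the
  leakage instrumentation tests exact.
* NIPALS converges on the score vector to a relative 1e-10; constant
  (zero-variance) input matrices are rejected.
* Mann-Whitney and Kruskal-Wallis delegate tie handling to base R
  (average ranks, tie-corrected variance; exact two-group p-values where
  available). Degenerate all-tied comparisons report p = 1.
* The bidirectional stepwise search starts from the null model and is
  guarded to never return a model with AIC above the full candidate fit.
* Percentile bootstrap CIs use type-7 quantiles; DeLong CIs accompany
  single pooled ROCs.
* Problem sizes in the test-suite simulations (e.g. 10–50 seeds, panels of
  30–200 metabolites, the reduced GA profile of 100 individuals × 20
  generations with outer 5-fold CV) are the package's desk-scale defaults,
  chosen to exercise every code path at the study's sample sizes; the full
  protocol profile (3000 × 60, leave-one-out outer CV, 2000 permutations
  and bootstraps) is selected with `profile = "full"` and behaves
  identically up to scale.

# Known limitations

* Wrapper (GA) selection stability degrades at n ≈ 40 for moderate
  effects, as discussed above; the stability frequencies are reported so
  users can see it rather than be shielded from it.
* The fixed-panel cross-validation intentionally excludes
  feature-selection uncertainty (matching the protocol it reproduces); the
  fully nested builder interface exists for users who want
  selection-inclusive estimates.
* The multinomial three-class problem is only addressed by PLS-DA;
  penalized panels are binary by design.
* ORA p-values depend strongly on the universe definition, which is left
  explicit for that reason.
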