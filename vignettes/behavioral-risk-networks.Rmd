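---
title: "Laboratory-free T2DM risk scoring and behavioral influence networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laboratory-free T2DM risk scoring and behavioral influence networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Most Type 2 Diabetes Mellitus (T2DM) prediction models lean on biochemical
markers (HbA1c, fasting glucose) that flag dysglycemia already under way.
This package implements a complementary, laboratory-free framework with two
coupled halves:

1. **Individual risk.** A Cox proportional-hazards model over behavioral,
   psychosocial, dietary and demographic predictors yields a linear-predictor
   risk score, which a leaf-capped decision tree discretizes into five
   ordered strata validated by Kaplan–Meier curves and pairwise log-rank
   tests.
2. **System-level coherence.** For each health state (incident-disease vs.
   disease-free), every predictor in turn becomes the target of a
   feed-forward neural-network ensemble trained on the remaining predictors.
   Signed input-to-target *effective weights* — sums over all hidden-layer
   paths of the products of connection weights — are aggregated into a
   directed influence matrix.  Comparing matrices across health states
   (difference matrix, network centralities, role classification) quantifies
   how the web of behavioral relationships reorganizes in disease.

Because the motivating cohort data (a large UK population biobank) is
access-gated, the package ships a synthetic-cohort generator that emulates
the 18-predictor schema, so every stage is exercised end to end on data with
known ground truth.  Published summary tables (hazard coefficients,
influence scores, centrality shifts) are included as reference *inputs* for
arithmetic-consistency validation only.

# The survival half

## Model

The hazard for participant $i$ is
$h(t \mid x_i) = h_0(t)\,\exp(\beta^\top x_i)$, with categorical predictors
dummy-coded against epidemiological reference levels (never-intake,
wholewheat bread, bran cereal, absent flags) and salt intake entering as an
ordinal score.  The risk score is the linear predictor
$\sum_j \beta_j x_{ij}$, an interpretable log-relative hazard.

## Model development

`univariate_screen()` retains terms with single-term Wald $p < 0.05$ —
dimensionality reduction only, not final selection.  `low_variance_filter()`
drops indicators whose minority class falls below 1% overall or within
either outcome stratum; `vif_filter()` iteratively removes the worst column
with variance-inflation factor $1/(1-R_j^2) > 10$.  The joint fit
(`fit_multivariate_cox()`) supports an L2 (ridge) penalty applied on the
standardized scale (default $10^{-2}$; not reported by the reference study,
so small and configurable) and refines the term set backwards: the
largest-$p$ term with $p \ge 0.05$ is removed only if its removal changes
every remaining coefficient by less than 10% *and* costs fewer than 2 units
of penalized partial log-likelihood; the model is refit after every removal
so reported estimates always come from the final term set.  Ties in event
times use Efron's approximation — inevitable with year-scale follow-up.

Proportional hazards are tested per term on scaled Schoenfeld residuals
against untransformed time; violating terms receive a covariate-by-time
interaction and the model is refit.  Discrimination is measured by Harrell's
C under 10-fold cross-validation stratified on the event indicator.

## Printed-table arithmetic

Published hazard tables print $\beta$, $\mathrm{HR} = e^\beta$, and
$\mathrm{HR}\% = (\mathrm{HR}-1)\times 100$ at two decimals.  The printed
columns are internally consistent only if HR% is derived from the *rounded*
HR, and the printed HR itself derives from the unrounded coefficient (e.g. a
printed $\beta = -0.55$ with printed HR $0.57$, although
$e^{-0.55} = 0.577$ rounds to $0.58$).  `hazard_table()` therefore derives
HR% from the rounded HR (`policy = "table_match"`, with an `"exact"` policy
available), and accepts a printed-HR column to reproduce published rows
without pretending the rounded coefficient determines them.

## Stratification

`derive_strata()` trains a single-feature decision tree of observed
incidence on the risk score.  Two implementation details matter:

* rpart's *classification* complexity sequence ranks splits by
  majority-class changes, so splits separating, say, 20% from 40% incidence
  are invisible to its pruning.  The tree therefore uses variance (anova)
  splitting on the 0/1 outcome — node impurity $n\,p(1-p)$, proportional to
  the Gini index for a binary outcome — and is cut back to the leaf cap by
  snipping the terminal split with the smallest impurity reduction until at
  most five leaves remain.
* Each leaf must hold at least 5% of participants so that leaf incidence is
  estimable; the resulting 4 cutpoints are frozen and applied uniformly.
  Cross-validation refits report cutpoint stability (SD of the nearest
  refit threshold) without re-selecting the cuts.

Published stratum ranges carry 0.01-wide gaps (… 0.22 | 0.23 …);
`risk_stratification()` places boundaries at gap midpoints so every real
score maps to exactly one stratum, with boundary scores going to the higher
stratum.  Scores outside the published span clamp to the end strata with a
warning.

`km_validation()` computes product-limit curves per stratum, all pairwise
log-rank $\chi^2$ tests, and 25/50/75% event-time percentiles with an `Inf`
sentinel when a curve never crosses the threshold ("not reached").

# The influence half

## Architecture and encodings

Each target is modelled by a two-hidden-layer network (64 and 32 rectified
linear units) with an L2 penalty on the weights entering the second hidden
layer, trained with Adam on mini-batches of 64 at learning rate $10^{-3}$.
The output head follows the target's scale: sigmoid/cross-entropy for
binary, linear/squared-error for continuous, softmax/cross-entropy for
categorical targets.  Training length (200 epochs maximum, early stopping
on the held-out fold with patience 20) is not specified by the reference
study; these defaults are conventional for small tabular networks and are
configurable (`network_architecture()`).

ANN encodings deliberately differ from the Cox design: continuous and
ordinal variables are min–max scaled to $[0,1]$; six-level intake
frequencies collapse to an indicator of the top intake band versus all
lower levels; smoking history collapses to ever/never; bread and cereal
types stay one-hot because they are nominal product choices whose
substitution structure a binary collapse would erase.  Network nodes are
the encoded features, so each bread and cereal type is its own node —
matching how published centrality tables list them.

## Effective weights, stability, aggregation

For input $i$ and output $o$,
$W^{\mathrm{eff}}_{i,o} = \sum_{h_1}\sum_{h_2} w_{i,h_1} w_{h_1,h_2} w_{h_2,o}$,
which equals the ordered product of the three weight matrices; biases are
excluded.  A unit test and the acceptance script verify the identity
against brute-force path enumeration to $10^{-10}$.

Training repeats over 10 independent shuffles of 5-fold cross-validation
(50 networks per target; configurable).  Per input–target pair, the
influence estimate is the median effective weight over members; stability
is the percentage of members sharing the majority sign, tiered as highly
stable ($\ge 70$%), moderately stable (60–69%), low stability ($<60$%), and
unstable ($\approx$ 50/50, implemented as a majority below 55%).  Exact
zeros join the smaller sign class, a conservative choice; percentages
always total 100.  Stability is computed over all ensemble members (a
per-fold variant of the published description collapses to the same
estimator under median aggregation).  For categorical targets, each class
column of the softmax head supplies its own target node, so no cross-class
reduction is needed.

Member seeds derive deterministically from `(seed, run, fold)` and the
*name* of the target variable, making the influence grid invariant to the
ordering of the selected variable set; a seed-scrambling helper keeps all
derived seeds inside 32-bit range and decouples derived streams (covariate
draws vs. event times, in particular, never share a stream even when given
the same seed).

## Networks and roles

`build_network()` keeps a directed edge where the median influence is
strictly positive (the positive-influence convention; published fractional
degree values imply a thresholded graph) with an optional stability gate.
`centrality_profile()` computes normalized in-/out-degree (incident edges
over $n-1$), eigenvector centrality in the prestige convention (a node is
central when *pointed to* by central nodes; undirected fallback on
non-convergence), betweenness over shortest paths with distances
$1/\text{weight}$ (stronger influence = shorter path; unweighted variant
available), and PageRank at damping 0.85.  Healthy-to-disease deltas are
reported at two decimals; vector shifts plot each node's movement in the
(eigenvector, betweenness) plane with behavioral-theme colors.

`classify_roles()` crosses hazard evidence with centrality shifts:
*dual-priority targets* (significant risk factor whose eigenvector or
betweenness rises in disease), *structural stabilizers* (significant
protective factor whose eigenvector falls), *emergent drivers*
(risk-direction factor gaining outgoing or bridging influence while
eigenvector does not rise), else *other*.  Thresholds are configurable;
categorical hazard terms map to their parent node.

# The synthetic generator

`simulate_covariates()` draws every marginal exactly as specified (level
probabilities; uniform over the range for age 40–70 and BMI 18.5–50).  The
joint distribution is a latent two-factor Gaussian copula (default loading
0.7): one factor couples psychosocial and sleep variables, the other
dietary and demographic ones.  Real questionnaire covariates are
correlated, and joint structure is what makes "structurally inconsistent
profile" outliers meaningful; an `"independent"` mode is available.

`simulate_survival()` draws event times by inverse transform from a
Weibull-baseline proportional-hazards model,
$T = b\,(-\log U / e^{\beta^\top x})^{1/a}$, with defaults $a = 1.2$ and
$b = 280$ — calibrated once so that the 90th-percentile linear-predictor
group reaches ~50% cumulative incidence by the 17-year administrative
cutoff under the default coefficients, which echo the published effect
directions and magnitudes.  Sub-year event times are resampled; because the
conditional hazard of $T \mid T \ge 1$ equals the unconditional hazard on
$[1, 17]$, Cox estimation is unaffected while the generated range matches
the 1–17-year follow-up window.  An independent Uniform(1, 17) censoring
time is applied by default (in addition to administrative censoring) so
censored follow-up varies over the full window, as last-assessment
censoring does in cohort data.

`inject_missingness()` gives a configurable fraction of rows >20% missing
cells (to exercise the row filter), sparse cell-level missingness
elsewhere, and writes part of the categorical missing cells as integer
special codes (e.g. −7).  `inject_outliers()` shifts each selected row's
continuous fields along a random direction of the 8-standard-deviation
sphere and re-draws its categorical fields uniformly, returning the row
indices as ground truth.

## What the generator does and does not emulate

It reproduces the variable typing, marginal plausibility, correlation
skeleton, proportional-hazards event structure, censoring window,
questionnaire missingness and planted anomalies.  It does not attempt to
match any real cohort's marginal frequencies, the true covariance of
behavioral measures, non-proportional effects (except in dedicated test
scenarios), or informative missingness.  Passing tests demonstrate that the
machinery is correct and calibrated under these idealized conditions — not
that the published biobank findings are reproduced, which would require the
gated data.

# Preprocessing pipeline

Order: recode special values → drop rows with missing share strictly above
20% (computed over schema columns only) → typed imputation (categorical
mode, continuous mean, least frequent binary category with ties going to 0)
→ z-scoring (zero-variance columns pass through as zeros) → unsupervised
outlier removal → down-sampling of the larger (disease-free) group to the
case count, unconditional on covariates.

The outlier stage embeds the standardized design in 2-D — an exact t-SNE
implemented in compiled code (Gaussian input kernel calibrated to
perplexity 40 by bisection, Student-t output kernel, momentum gradient
descent with early exaggeration, 5,000 iterations by default), with PCA as
a fast deterministic alternative — selects the cluster count by maximum
average silhouette width over $k = 2..10$ (ties to the smallest $k$), cuts
a Ward tree at that $k$, and flags points beyond the 95th percentile of
Euclidean distance to their cluster centroid (per cluster by default; a
global-percentile variant is available).

## A measured limitation of margin-based outlier detection

The flagging rule marks, by construction, ~5% of each cluster.  With 5%
planted contamination, recovering ≥70% of the planted rows would require
near-perfect separation in embedded centroid distance.  Simulation shows
the information exists — a 40-nearest-neighbor distance score in the
*standardized input space* separates the planted outliers at AUC ≈ 0.995 —
but 2-D embeddings discard most of it: t-SNE's row-normalized affinities
give every point equal total attraction (isolated points are absorbed into
cluster margins) and its layouts equalize within-cluster density, so
centroid distance in the embedding recovers only a minority of the planted
rows (the acceptance script reports the measured recall, typically
0.2–0.4).  Constructions that *are* recoverable by the rule (compact
distant groups) are instead isolated as their own clusters by the
silhouette search and flagged at 5% internally.  We report this as a
property of the margin-trimming procedure itself; the per-cluster flagged
share (5% ± 1 row) behaves exactly as specified.

# Statistical cautions established in simulation

* **Balanced down-sampling attenuates hazard ratios.**  Keeping every
  incident case and a random subset of censored participants makes
  inclusion depend on the outcome; in simulation the Cox coefficients of
  the balanced sample shrink noticeably toward zero relative to truth.
  The pipeline retains the balancing step (it mirrors the published
  procedure, and ranking-based outputs are less affected), but
  parameter-recovery validation runs on the clean cohort *before*
  balancing, where 95% CI coverage is nominal.
* **Five-stratum incidence monotonicity needs sample size.**  With five
  strata of ≥5% each and adjacent true incidence gaps of a few percentage
  points, stratum incidence standard errors at ~120 rows per stratum exceed
  the gaps, so strict monotonicity fails for many seeds at the demo scale
  (600 per group) even when scoring with the true linear predictor.  The
  acceptance check therefore validates monotone ordering on the known risk
  gradient at 2,500 per group (five strata of ≥250), where it holds
  consistently, and validates the demo configuration for completion and
  determinism.

# Problem sizes used by tests and acceptance

Unit tests run on hundreds to a few thousand rows.  The acceptance script
uses: 20 replicates of 35,000-row cohorts (≥5,000 per outcome group) for
coefficient recovery; 1,000 single-term null fits at $n = 300$ for screen
calibration; a 5-variable, 2,000-row system with a planted noiseless linear
dependence (2 runs × 3 folds) for influence recovery; 2,000 rows at 5%
contamination for the outlier pipeline (2,000 t-SNE iterations); random
directed graphs up to 25 nodes (with ≤6-node brute-force betweenness
oracles); and the demo pipeline at 600 per group with the PCA embedding and
a 2 × 3 ensemble.  These sizes were chosen so the whole acceptance run
completes in a few minutes on one CPU while every check retains comfortable
statistical power.

# Known limitations

* The ANN influence scores are raw path-product sums; their scale is not
  comparable across targets with different output heads.  The published
  tables report them raw, and so does the package.
* Signed effective weights forgo the absolute-value normalization of
  classic connection-weight importance algorithms; with rectifier
  activations they recover the sign structure of planted monotone
  relations, but saturate or mislead for strongly non-monotone
  relationships.
* No competing risks, no time-varying covariate data (only
  covariate-by-time interaction repair), no multiple imputation, and no
  attempt to reproduce cohort-specific estimates of the motivating study.
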