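---
title: "Stability-driven non-negative decomposition of personality questionnaires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-driven non-negative decomposition of personality questionnaires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitfactor)
```

## The problem

Big Five inventories record agreement with short trait statements on
five-point Likert scales. Classical factor analysis of such item tables
produces signed, bipolar components in which every item contributes to every
factor. `traitfactor` implements an alternative decomposition built around
orthogonal projective non-negative matrix factorization (OPNMF), together
with the machinery needed to use it responsibly: a cross-validated
stability/generalizability framework for choosing the number of factors, a
permutation-adjusted analysis of how well one overall model transfers to
demographic or cultural subgroups, and a two-dimensional trait space in
which directional combinations of the two super-factors — a Social
Adaptation axis (Extraversion + Agreeableness + Conscientiousness item
covariance) and a Spontaneous Mentation axis (Neuroticism + Openness) — are
related to external phenotype features by thresholded partial least squares
(T-PLS) with permutation and bootstrap inference.

Everything is exercised end to end on synthetic data with planted structure,
so every claim the package makes about itself is checked by code in this
repository.

## The factorization

Given a non-negative items-by-subjects matrix $X$ (Likert responses after
reverse scoring and imputation), OPNMF seeks a non-negative basis
$W \in \mathbb{R}^{M \times r}_{\ge 0}$ minimizing

$$\lVert X - W W^\top X \rVert_F .$$

The projective form has two consequences that matter for psychometrics.
First, factor scores are not free parameters: for any data with the same
items, $H = W^\top X$, so a basis learned in one sample applies directly to
another. Second, the objective drives $W^\top W$ towards the identity, so
factors have approximately orthogonal, sparse, unipolar loading patterns and
items can be hard-assigned to the factor with their maximal loading without
doing violence to the fit.

The solver uses the standard multiplicative update
$W \leftarrow W \circ (X X^\top W) \oslash (W\, W^\top X X^\top W)$ with a
spectral-norm renormalization of $W$ after each step, and the denominator
guarded by $10^{-16}$. Only the item Gram matrix $X X^\top$ enters the
iteration, so per-iteration cost is independent of the number of subjects —
this is what makes thousands of cross-validation fits affordable. Three
numerical choices deserve explanation:

* **Objective evaluation.** The trace records
  $\lVert X - W W^\top X\rVert_F$ computed in residual form through a
  symmetric square root of the Gram matrix, which remains accurate at the
  $10^{-16}$ level; the algebraically equivalent trace formula loses all
  precision near an exact fit through cancellation.
* **Monotonicity safeguard.** The heuristic multiplicative step carries no
  descent guarantee and occasionally overshoots by a relative $10^{-6}$.
  When a full step would increase the objective, the elementwise multiplier
  is damped by successive square roots until it does not; if no damped step
  decreases the objective the iterate is numerically stationary and the
  loop stops. The recorded trace is therefore monotone by construction.
* **Support polish and restarts.** Multiplicative updates approach the
  non-negativity boundary only asymptotically, so when the true optimum has
  disjoint factor supports (exactly representable data) the fit is finished
  by the exact per-support solution — each factor's loading becomes the
  leading eigenvector of its items' Gram block — adopted only when it
  strictly lowers the objective. Separately, a solution that assigns no
  item to some factor is a degenerate local optimum; the fit then retries
  from two seeded random initializations and keeps the lowest objective.
  Both mechanisms are deterministic given the seed.

Defaults: NNDSVD initialization (deterministic; exact zeros filled with the
matrix mean so no entry is permanently locked), `max_iter = 50000`,
`tol = 1e-5` on the relative Frobenius change of $W$. Cross-validation fits
cap `max_iter` at 2000: at 60 items the fits converge far earlier, and the
cap bounds worst-case runtime. Final bases are column-normalized to unit
Euclidean norm so the per-item argmax is scale-fair across factors; exact
ties break towards the lower factor index. Note the tie rule makes hard
assignments of exactly tied items sensitive to column order — irrelevant in
practice since fitted loadings are never exactly tied.

## Choosing the number of factors

`run_crossvalidation()` implements the evaluation protocol: per repetition the
subjects are split into $k$ folds (reshuffled every repetition); each fold
serves once as hold sample against the complementary main sample; both are
factorized independently at each candidate rank; and the pair of models is
scored by

* **aRI** — adjusted Rand index of the two hard item partitions (1 iff
  identical up to labels);
* **VI** — variation of information between the partitions, in nats;
* **CI** — concordance index: Lin's concordance correlation coefficient
  between the vectorized upper triangles of the two item-by-item
  cosine-similarity matrices. An agreement coefficient on the
  loading-geometry summaries (rather than a plain correlation) is used
  because two bases should score 1 only when their cosine structures
  coincide, not merely co-vary; Pearson-on-triangles is available as an
  option. For signed baselines the cosines use absolute loadings, so
  polarity is not conflated with structure;
* **iRE** — increased reconstruction error: normalized RE of the main basis
  on the hold data minus that of the hold basis on its own data. A
  difference, not a ratio, because the within-sample RE can approach zero;
* **IV** — per-item variability: one minus the mean pairwise Jaccard
  overlap of the item sets an item travels with across partitions.

`summarize_rank_selection()` takes per-rank medians (robust to outlier
folds), orients the four model-level indices (aRI, CI up; VI, iRE down),
min-max normalizes each across the candidate ranks, and averages them into
a composite in $[0,1]$ whose confidence band comes from bootstrap-resampling
records within rank. An index that is constant across ranks contributes 0.5
everywhere, by rule, rather than an arbitrary 0 or 1. IV is reported but not
folded into the composite: it lives on the item, not the model, unit.
Group-stratified folds (no country split across the fold boundary) and a
cross-sample bootstrap between two instruments sharing items implement the
cultural and version-robustness variants. Folds are reshuffled every
repetition, which makes repetitions exchangeable draws of the same
experiment.

Missing cells are item-mean imputed once on the full table by default —
item-mean imputation is deterministic and standard for Likert inventories,
and the strategy argument is an enum left open for alternatives. Because full-table imputation lets hold
subjects' observed cells influence main-sample item means only through the
imputed values of *other* subjects (a second-order effect), the default is
pragmatic; `impute_per_fold = TRUE` computes item means on the main sample
only and fills both samples with them, so nothing crosses the fold boundary.
An acquiescence-robustness variant (`preprocess = "center"`) subtracts each
subject's mean response and restores non-negativity by a global shift —
the one restoration that preserves all between-item and between-subject
contrasts.

PCA (singular vectors of item-centered data) and EFA (principal-axis
factoring with varimax rotation — an orthogonal rotation keeps the baseline
comparable to OPNMF's orthogonality) run inside
the identical protocol, with partitions by maximal absolute loading and
reconstruction through the projector onto the loading column space.
`split_poles()` separates each signed factor into its positive and negative
item poles for inspecting bipolarity.

## Subgroup generalizability

`subgroup_generalizability()` measures how well one overall basis transfers
to labelled subgroups: the actual normalized RE of the overall model on a
group is compared with `n_null` (default 100) label shuffles that preserve
every group's size. Generalizability is the mean actual-minus-null
difference; `intra_group_heterogeneity()` repeats the logic with a model
fitted on the group itself (nulls refit on shuffled memberships), and
`model_similarity()` is the CI between group and overall bases. A one-sample
t-test of the differences is reported as the classical summary, but note
it is anti-conservative under exchangeable labels — the
actual error is itself a single draw from the null — so the two-sided
empirical rank `p_perm` is also reported, and it is what the package's own
calibration checks use. `explain_generalizability()` runs the three
univariate regressions (on heterogeneity, model similarity, sample size)
with $r^2$ and two-tailed $p$; a zero-variance predictor is flagged and
reported as $r^2 = 0$. Group-specific fits reuse the overall rank, which is
a parameter, since the analysis is meaningful at any chosen rank.

## The 2D trait space and directional prediction

`standardize_scores()` z-scores the two factor-score axes; the convention
throughout is 0° = +Social Adaptation, 90° = +Spontaneous Mentation,
counterclockwise — chosen so that predominantly internally-oriented
phenotypes peak near 90°. The directional projection at angle $\theta$ is
$\cos\theta \cdot \mathrm{SA} + \sin\theta \cdot \mathrm{SM}$; for exactly
standardized axes with correlation $\rho$ its variance is
$1 + \rho\sin 2\theta$, so the variance profile peaks at 45° (135°) for
positively (negatively) correlated axes — a closed form the tests verify to
$10^{-10}$.

T-PLS regresses a target on column-standardized features: a $K$-component
PLS1 fit is back-projected to a feature-space coefficient vector and all but
the $\lceil \eta p \rceil$ largest-magnitude coefficients are zeroed.
$(K, \eta)$ are tuned by inner cross-validation whose folds keep families
together, scored by the correlation between the target and out-of-fold
predictions; ties prefer fewer components, then larger $\eta$. At
$\eta = 1$ the model is exactly plain PLS — verified against an independent
NIPALS implementation and against `mixOmics` to $10^{-8}$. The PLS1 core
uses the Krylov-space characterization of the coefficient path (only
$X^\top X$ and $X^\top y$ enter), which makes the $\sim 10^5$ refits of a
direction scan affordable; default grids are $K \in 1..\min(25, n-1, p)$ and
$\eta \in \{0.05, 0.10, \dots, 1\}$, wide enough that the inner
cross-validation, not the grid boundary, decides the model.

`direction_scan()` runs this model over angles 1°–180°. The observed
accuracy per angle is the mean out-of-fold Pearson correlation between
actual and predicted projections over `n_reps` repetitions of grouped
`n_folds`-fold cross-validation, with $(K,\eta)$ re-selected inside every
training fold (fully nested). Permutation inference shuffles the target
across subjects; recomputing the full nested protocol for every permutation
and angle would cost $\sim 10^7$ fits for nothing — a permuted target
carries no information for hyperparameters to adapt to — so each null
replicate fixes $(K, \eta)$ at the angle's full-data selection and performs
one grouped k-fold pass. $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 +
n_\text{perm})$, Benjamini–Hochberg-adjusted across the 180 angles.
Permutations are free across subjects by default (family-blocked available
via `permute_within_family`), and a per-angle batched solver computes all
permutation coefficient vectors from one Gram matrix per fold.

`bootstrap_feature_z()` resamples subjects with replacement, refits at fixed
$(K, \eta)$ — fixing the hyperparameters isolates coefficient variability —
and summarizes each feature as $z = \text{mean}/\text{SD}$ over the
bootstrap distribution; a zero-SD feature gets $z = 0$ by rule and a flag.
Signature responses are the dot product of the z-vector with standardized
features; the full z-vector is used by default (restricting to
FDR-significant features is the caller's choice via the returned flags),
and `correlate_signatures()` reports Pearson correlations with any trait
table. `compare_targets()` runs the identical nested protocol on named
targets and compares final coefficient vectors by Pearson correlation.

## What the synthetic generator emulates — and what it does not

`build_true_loadings()` plants a block non-negative loading matrix: one
dominant block per Big Five dimension (entries uniform on $[0.6, 1]$),
cross-loadings uniform on $[0, \texttt{cross\_loading}]$, every fourth item
negatively keyed. Under `structure = "big2_hier"` the latent score
covariance couples $\{E, A, C\}$ at `rho_social` (default 0.5) and
$\{N, O\}$ at `rho_mentation` (default 0.55). The slight cohesion asymmetry
is deliberate generator design: with exactly uniform coupling, the
three-factor solution is unambiguous (split the two-dimension cluster, keep
the three-dimension cluster whole) and therefore spuriously stable; the
asymmetry puts the "which cluster do I split" decision at ranks 3 and 4 in
genuine tension, which is precisely the scale ambiguity a trait hierarchy
creates — ranks 2 and 5 are natural descriptions of the data, 3 and 4
are not.

`simulate_responses()` draws latent scores from a multivariate normal with
mean 2 and the planted covariance, left-censored at zero (a censoring, not
an exact truncation; at unit variance it touches about 2% of draws, and
correlations are specified on the uncensored scale). Latent responses
$W H + \text{acquiescence} + \text{noise}$ are discretized per item by
affine rescaling to $[1, 5]$ between the item's own 1st and 99th
percentiles, rounding, and clamping — this keeps non-negativity and
realistic marginals without inventing a threshold model. Because noise is
added on the latent scale before rescaling, `noise_sd` is calibrated in
approximate, not exact, Likert units. Reverse-keyed items are flipped
($6 - x$) before storage so the table mimics raw keying, and missing cells
are inserted uniformly at random. `simulate_subgroups()` draws each group
from its own perturbed loadings and noise multiplier but discretizes the
*pooled* sample — one instrument has one response mapping, and per-group
calibration would silently normalize away exactly the between-group
differences the subgroup analysis is supposed to detect.
`simulate_phenotypes()` plants a signal subset of features as noisy linear
encodings of the projection at a chosen angle, with unit-magnitude,
random-sign true weights (so the amplitude SNR of a signal feature is
$1/\texttt{noise\_sd}$), the rest pure noise, and consecutive subjects
grouped into synthetic families.

What passing tests on these data do **not** show: the generator has
conditionally independent items given the latent scores (no local
dependence, no facet structure), a single planted hierarchy rather than the
messy partial hierarchies of real inventories, stationary response styles
(an additive acquiescence constant; no extreme-responding or
social-desirability styles), families that are labels rather than genetic
structure, and phenotype features that are linear in a single direction.
Results on real questionnaire data can and will be less clean, which is why
the evaluation framework — not any single fit — is the product.

## Problem sizes used by the checks

The package's own test suite and the acceptance script run desk-scale
versions of every analysis, chosen to finish in minutes on one core while
leaving the qualitative conclusions stable across seeds: rank selection on
`big2_hier` data with 60 items, 2,000 subjects, response noise 0.5, ranks
2–5 and 30–50 repetitions of fivefold cross-validation; the OPNMF-vs-EFA
stability comparison at 1,000 subjects and 15–20 repetitions on shared
folds; subgroup calibration on 400 subjects with 100 label shuffles and the
heterogeneity regression across 12 groups of 100; direction scans at 400
subjects and 60 features with 500 permutations (200 under the pure-noise
null); and bootstrap calibration at 1,000 resamples. The full-scale
protocol (1,000 repetitions, 5,000 permutations and bootstraps, ranks 2–8)
is what the defaults encode and is reachable by changing the corresponding
arguments; a full-scale run is a compute-budget, not a code, question.

## Known limitations

* OPNMF optimizes a non-convex objective with a heuristic update; the
  safeguarded solver guarantees a monotone trace and deterministic output,
  not global optimality. The degenerate-partition restart removes the one
  failure mode observed in testing (an empty factor), but adversarial data
  can presumably produce others.
* The concordance and item-variability indices implement reasonable
  readings of tersely described quantities; other readings exist and would
  change absolute values (not, in the cases examined, orderings).
* T-PLS thresholding selects features by coefficient magnitude on
  standardized features; correlated features share credit and the retained
  set is not a causal statement.
* The permutation null of the direction scan conditions on the observed
  hyperparameter selection (see above); its p-values are calibrated under
  the null of no feature–target association, which is the hypothesis being
  tested, but they do not account for selection variability under partial
  nulls.
* Reported subgroup t-tests inherit the anti-conservatism of testing a
  single draw against its own null; use `p_perm` when calibration matters.
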