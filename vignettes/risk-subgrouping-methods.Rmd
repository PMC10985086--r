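---
title: "Interpretable risk subgrouping: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable risk subgrouping: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chronic diseases such as osteoarthritis are heterogeneous: the factors that
put one patient at risk (obesity, occupational load, medication history,
socioeconomic context) differ from those that put another at risk. A single
risk score hides this. The workflow in this package asks a sharper question:
*which subgroups of at-risk individuals share the same reasons for being at
risk, and can those subgroups be described by rules simple enough to apply
in the clinic?*

The pipeline proceeds in six stages, each exposed as package functions and
driven by the numbered scripts under `analysis/`:

1. **Cohort construction** — a case-control table with an index date per
   subject (diagnosis date for cases, a matched stand-in for controls) and a
   retrospective capture window; a discovery population with an
   assessment-to-index gap of 0–5 years and a holdout population with a
   5–11 year gap.
2. **Risk model** — a gradient-boosted tree classifier
   (`binary:logistic`) under nested 5×5 case-control stratified
   cross-validation, with all preprocessing (missingness/variance filters,
   median imputation) refitted inside every training partition.
3. **Explanation** — path-dependent TreeSHAP attributions on the log-odds
   scale, taken for each subject from the fold model that held that subject
   out, so `base + sum(attributions) = logit(out-of-fold probability)`
   exactly.
4. **Subgrouping** — PCA of the SHAP matrix to 10 dimensions, a
   shared-nearest-neighbour (SNN) graph, Louvain community detection over a
   resolution grid, and selection of the resolution by a cluster score
   combining silhouette robustness with per-cluster prediction F1.
5. **Rules** — per-cluster one-vs-rest conjunctive threshold rules induced
   from bagged shallow decision trees on the original (imputed) inputs,
   filtered on out-of-bag precision and recall.
6. **Validation and markers** — rule-based assignment of the holdout
   population with a case-percentage ambiguity rule, concordance of
   per-cluster case/size fractions, and one-vs-rest logistic
   likelihood-ratio marker tests with a sex covariate, Bonferroni-corrected
   per cluster.

## Models and their assumptions

**Risk model.** The booster uses fixed structural parameters
(`max_depth = 10`, `min_child_weight = 50`, `subsample = 0.8`,
log-loss objective; `colsample_bytree = 0.8` only when omics features are
present) and searches learning rate
`eta ∈ {0.05, …, 0.30}` × rounds `∈ {50, …, 1000}` by mean inner-fold
ROC-AUC. The depth/child-weight combination assumes subgroup structure is
expressible as interactions over at least ~50 effective subjects — smaller
latent groups will not earn their own leaves. Because boosting is
sequential, the grid over round counts is evaluated by truncated prediction
of a single maximally-grown booster per learning rate, which is exact.

**SHAP space.** Clustering attributions rather than raw features groups
subjects by *why* the model considers them at risk, not by what they look
like. The assumption inherited from TreeSHAP is path-dependence: attributions
are with respect to the training distribution encoded in tree cover, and
out-of-fold attribution keeps training optimism out of the geometry. Using
each subject's own held-out fold model means the SHAP space mixes five
models; the PCA step absorbs small inter-fold differences, and the
additivity contract is enforced per subject (tolerance `1e-3` log-odds,
observed errors are ~`1e-6`).

**Cluster score.** A candidate solution at resolution $r$ is scored as

$$\mathrm{score}(r) \;=\; \frac{\operatorname{mean}_k\,
\tilde{s}_k}{1 - \operatorname{median}_k\, F1_k}$$

where $\tilde{s}_k$ is the median over 30 random 80% subsamples of cluster
$k$'s mean silhouette width (Euclidean, in the 10-dimensional embedding) and
$F1_k$ is cluster $k$'s case-classification F1 from the out-of-fold
probabilities at threshold 0.5. The numerator rewards geometric robustness,
the denominator rewards solutions whose typical cluster predicts its cases
well; the score diverges as the median F1 approaches 1 (capped to an `Inf`
sentinel, resolved by the tie-break chain: more clusters, then lower
resolution).

Both summaries are *equal-weighted across clusters*. This was a genuinely
open design point, and the choice matters: weighting by cluster size makes
the score increase whenever poorly predicted mass is split into many small
clusters that sit below the weighted median — fragmentation is rewarded
rather than resolution. With equal weights the score asks whether the
typical subgroup is robust *and* predictive, and on planted-structure
cohorts its argmax coincides with the planted partition.
`cluster_score()` accepts arbitrary weights for callers who want the
size-weighted variant.

**Rules.** Candidate rules are root-to-leaf paths of ten bootstrap-bagged
Gini classification trees (depth ≤ 5, `rpart` with `cp = 0.001`,
`minsplit = 20`, no surrogate splits), kept when the leaf is
majority-positive; conditions on one feature are intersected, each rule is
scored on its own tree's out-of-bag samples, and rules with OOB recall
< 0.2 or OOB precision ≤ 0.5 are dropped. Leaf paths — rather than every
majority-positive internal node — matter: internal-node prefixes are shared
by many trees and would dominate the "appears in most trees" selection with
near-vacuous single conditions, which in turn floods holdout assignment
with ambiguity. Selection is a total order: source-tree count, OOB
precision, OOB recall, fewest conditions, then the lexicographic condition
string.

**Markers.** For cluster $c$ and feature $f$, the test compares nested
logistic regressions `member ~ covariates + f` vs `member ~ covariates` by
the likelihood-ratio statistic against $\chi^2_1$; direction is the sign of
the feature coefficient, and p-values are Bonferroni-adjusted within each
cluster (adjusted p = p × number of features tested in that cluster). No
minimum-detection filter is applied and both directions are reported. The
default subset is cases-only: markers then separate *risk profiles among
those who develop disease* rather than cases from controls.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `k_outer`, `k_inner` | 5, 5 | folds | stratified nested CV; outer folds give the 95% t-interval (4 df) |
| `threshold` | 0.5 | probability | standard classification threshold for all confusion metrics |
| `pca_dim` | 10 | components | enough to hold several subgroup directions; capped at feature count |
| `k_neighbors` | 20 | subjects | SNN neighbourhood; Jaccard edge weights, pruned below 1/15 |
| `resolutions` | 0.002–1.0 (9 points) | Louvain γ | spans solution collapse to over-fragmentation (see below) |
| `n_subsamples`, `frac` | 30, 0.8 | — | silhouette subsampling; medians per cluster over subsamples |
| `n_estimators`, `max_depth` | 10, 5 | trees, depth | bagged rule induction |
| `recall_min` | 0.2 | — | OOB recall floor for candidate rules |
| `max_depth_duplication` | 7 | terms | rule-identity cap for deduplication (thresholds at 6 significant digits) |
| `top_k` (ranking / profile / waterfall) | 40 / 6 / 15 | features | headline feature counts per output |
| marker `k` | 2 | features | top up- and down-regulated markers per cluster |

**The resolution grid.** Louvain community counts at a fixed resolution grow
with the size of the graph, so a grid appropriate for hundreds of thousands
of subjects is far too fine for a cohort of a few thousand: at $n = 4000$,
resolution 0.3 already yields a dozen communities. The default grid
$\{0.002, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1.0\}$ spans from "all
subjects in one community" (invalid, excluded) to clear over-fragmentation,
so the score maximum is bracketed inside the scan rather than pinned to a
grid boundary. When applying the pipeline to much larger cohorts the grid
should be shifted upward correspondingly.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable against
known ground truth without access to restricted individual-level data.

**Case labels.** Features are drawn from declared marginals (normal,
Bernoulli, ordinal, or a Gaussian mixture); the case label is Bernoulli with
$P(\text{case}) = \operatorname{logit}^{-1}(\beta_0 + \sum_j \beta_j x_j +
\text{shift})$, with $\beta_0$ calibrated by bisection so the realized case
fraction matches the configured one within 1%. Dates are integer days with
a 365-day year; the assessment-to-index gap is uniform on the configured
window, `(0, 5]` years for discovery and `(5, 11]` for holdout.

**The analytic benchmark** (`gaussian_signal_config`) gives its single
feature the binormal mixture marginal $(1-\pi)N(0,1) + \pi N(d,1)$ with
log-odds effect $d$. Then $P(\text{case}\mid x)$ is *exactly* the logistic
model above with intercept $-d^2/2 + \operatorname{logit}(\pi)$, the
class-conditional densities are unit normals separated by $d$, and the
attainable ROC-AUC is $\Phi(d/\sqrt{2})$ in closed form — for $d = 1.19$,
0.800. Note that drawing the feature $N(0,1)$ marginally and then labelling
through the same logistic model does *not* produce this value (the
class-conditionals are then skewed tilts of the normal; simulated AUC
≈ 0.77), which is why the benchmark pins the marginal, not just the effect.

**Planted archetypes** (`planted_archetype_config`) are latent subgroups
defined by two-condition conjunctive rules (one `>` and one `<=` condition
at |z| = 1.6 on its own pair of unit-normal features), prevalence 0.10
each, and a +2 log-odds risk shift — strong enough that a depth-10 booster
with `min_child_weight = 50` can carve leaves for a ~10% subgroup at
$n = 4000$. Membership is noiseless by construction, and the planting
geometry makes the thresholds identifiable *at data resolution*:

* members' condition values are drawn uniformly on a short interval beyond
  the threshold (margin 0.25, width 0.2, in SD units);
* non-members are rejection-sampled out of the band from the threshold to
  the midpoint of the member interval on each condition feature, and out of
  the entire rule region relaxed by a buffer of 0.15.

The consequences: (i) each planted threshold sits inside an empty band of
the data, so any separating tree split — whatever bootstrap bag it saw —
lands its midpoint inside that band; (ii) background subjects still occupy
the outer half of the member interval and beyond on every *single*
condition, so no single condition is pure and induction is forced to learn
the conjunction; (iii) no non-member sits within the buffer of the joint
boundary, so the conditional observation gap around each threshold has a
deterministic minimum width that dominates bag-to-bag split jitter. The
width satisfies the pinning condition
$w < (1-\Phi(e))/\phi(e)$ at the member edge $e$ (0.2 < 0.447), which keeps
the empirical Gini optimum from drifting past the member boundary.
Without this geometry, threshold recovery is a coin flip on bootstrap luck
— the zero-margin variant leaves the learnable boundary under-determined at
the scale of one observation spacing.

**Longitudinal records** are monthly biomarker values (subject mean plus
stationary AR(1) noise, so the lag-1 autocorrelation of a subject's series
equals the configured ρ) and yearly Bernoulli prescription events with
case/control-specific probabilities; all record dates precede the index
date.

**What the generator does not emulate.** Missingness is MCAR (the median
imputation it feeds is only unbiased under mechanisms near MCAR);
archetypes are disjoint-feature and mutually exclusive; there is no
calendar structure, no informative censoring beyond the eligibility flag,
no code-system semantics, and no correlation between features except what
the archetype coercion induces. Passing tests therefore demonstrate that
the machinery recovers structure it is designed to see — they say nothing
about confounding, drift, or coding noise in real EHR data.

## Numerical choices

* Quantiles are type-7 (linear interpolation) everywhere: winsorization
  bounds, the NPX subject filter, medians. One consequence worth knowing:
  winsorization is only idempotent up to an interpolation fraction of one
  observation spacing, because the re-estimated 1st percentile of clipped
  data sits just inside the clip value.
* Dates are integer days, year = 365 days; windows are half-open below and
  closed above. The excluded month in each yearly bin is the 30 days
  adjacent to the index-date side of the bin — the stated time-gap between
  snapshots and diagnosis; medication flags use the full bin.
* NPV is TN/(TN+FN). (A printed formula in the source material repeats the
  specificity expression for NPV; that is treated as a typo.)
* 95% CIs on fold-level metrics are t-intervals with k−1 = 4 df; the CI
  construction was not documented upstream and min–max or normal intervals
  are defensible alternatives.
* PCA component signs are fixed by making each component's
  largest-magnitude loading positive; grid-search ties break toward fewer
  rounds then smaller eta; resolution-score ties break toward more
  clusters then lower resolution; rule-selection ties end at a
  lexicographic condition string so selection is a total order.
* Louvain is stochastic; every clustering call reseeds the R RNG, and the
  whole pipeline is byte-reproducible for a fixed master seed with
  single-threaded boosting.
* Degenerate inputs: single-cluster solutions are invalid (score `NA`);
  isolated SNN vertices are attached to the nearest cluster centroid;
  all-missing vectors, single-class folds and all-excluded feature sets are
  explicit errors; a subsample that loses a cluster contributes no
  silhouette for it.

## Problem sizes

The bundled analyses and tests run on desk-scale cohorts chosen to keep the
full suite in the minutes range while leaving every effect detectable with
margin: $n = 5000$ for the analytic AUC benchmark, $n = 2000$ with 20
repetitions for the permutation null, $n = 4000$ for archetype recovery and
rule induction, $n = 3000$ for the holdout, $n = 1500$ × 200 features × 14
clusters (20 null repetitions) for the marker calibration, and $n = 1200$
for the byte-determinism check. The compact hyperparameter grid used at
these sizes (eta {0.1, 0.3} × rounds {50, 100, 200}) is a subset of the
full protocol grid, which `hyper_grid()` produces in full when wanted.

## Known limitations

* The cluster score compares solutions only within the scanned grid; if the
  data's natural granularity falls outside it, the argmax will sit at a
  grid edge — re-scan with a shifted grid when that happens.
* Rule induction assumes axis-aligned structure; oblique subgroup
  boundaries will be approximated by staircases of conditions and the
  tree-count selection may then prefer unstable fragments.
* Marker tests are one-vs-rest logistic LR tests; they inherit the
  anti-conservatism of the χ² approximation in small clusters and do not
  model correlation between features.
* Holdout validation applies discovery rules verbatim; it measures
  transportability of the rule definitions, not of the underlying model.
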