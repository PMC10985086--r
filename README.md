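# shapclust

Interpretable risk-subgroup discovery for case-control cohorts.

Clinical risk models answer *who* is at risk; prevention needs to know
*why*. `shapclust` implements a complete, tested workflow that trains a
cross-validated gradient-boosted risk model on tabular cohort data with
longitudinal records, explains every out-of-fold prediction with TreeSHAP,
clusters subjects in the space of their attributions (PCA → shared-nearest-
neighbour graph → Louvain) to find subgroups that are at risk *for the same
reasons*, selects the clustering resolution with a score that balances
silhouette robustness against per-cluster prediction F1,

```
score(r) = mean_k( median subsampled silhouette_k ) / (1 − median_k F1_k)
```

derives one conjunctive threshold rule per subgroup from bagged decision
trees (out-of-bag filtered, tree-count selected), validates the rules on an
independent holdout population with a longer risk horizon, and tests omics
features for per-subgroup markers by one-vs-rest logistic likelihood-ratio
tests with a sex covariate and per-cluster Bonferroni correction.

Individual-level cohort data of the kind this workflow targets (UK primary
care records linked to biobank assessments) is access-restricted, so the
package ships a synthetic cohort generator with planted ground truth:
latent "archetype" subgroups defined by conjunctive feature rules with a
log-odds risk shift, longitudinal biomarker/medication records, date
matching, and discovery (0–5 year) / holdout (5–11 year) windows. Every
stage is exercised against that ground truth or against analytic oracles
(e.g. the binormal closed form AUC = Φ(d/√2)).

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
cohort of 4,000 discovery and 3,000 holdout subjects with four planted
archetypes plus NSAID prescription history:

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_train_risk_model.R
Rscript analysis/04_explain.R
Rscript analysis/05_cluster_subgroups.R
Rscript analysis/06_rules_validate.R
Rscript analysis/07_markers.R
```

Stage 3 prints the cross-validated model performance:

```
out-of-fold ROC-AUC: 0.847 (95% CI 0.833-0.861)
sensitivity 0.744, specificity 0.776, PPV 0.767, NPV 0.755, F1 0.755
```

i.e. the booster recovers both the planted conjunctive risk shifts and the
medication-history signal. Stage 5 scans Louvain resolutions over the SHAP
embedding and selects 20 subgroups (score 3.53): the planted archetypes
crossed with NSAID history, each with its own case fraction (0.12 to 1.00)
and prediction F1. Stage 6 turns each subgroup into a rule such as

```
cluster 6: nsaid_pre1y > 0.5 & nsaid_pre2y > 0.5 & z2_hi > 1.713
```

and applies all rules to the holdout population:

```
assignment: 85.0% unique, 10.0% ambiguous, 5.0% unassigned
case-fraction R^2 0.947, size-fraction R^2 0.944
```

so five years further from the assessment, subjects are still almost always
uniquely assignable and the subgroups keep their case-enrichment ordering.
Stage 7 finds 18 significant (cluster, protein) marker pairs, including the
four proteins the simulation shifted in the archetype members.

The methods vignette (`vignettes/risk-subgrouping-methods.Rmd`) documents
the models, every tunable parameter, the generator's planting geometry, and
the numerical conventions.

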