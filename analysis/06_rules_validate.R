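#!/usr/bin/env Rscript
# Stage 6: cluster-defining rules and holdout validation.
#
# One-vs-rest bagged-tree rule induction on the imputed model inputs gives
# each cluster a single conjunctive rule (out-of-bag filtered, tree-count
# selected). The rules then assign subjects of the independent 5-11 year
# holdout population to clusters; ambiguous matches go to the cluster with
# the higher discovery case percentage, and per-cluster case/size fractions
# are compared across populations by squared Pearson correlation.

library(shapclust)
library(jsonlite)

discovery <- read_cohort_tsv("results/discovery_cohort.tsv")
holdout <- read_cohort_tsv("results/holdout_cohort.tsv")
feat <- utils::read.delim("results/feature_table.tsv")
X <- feat[, setdiff(names(feat), "subject_id")]
labels <- utils::read.delim("results/cluster_labels.tsv")$cluster
clusters <- as.data.frame(fromJSON("results/cluster_metrics.json"))
seed <- 21L

imp <- fit_impute(X, seq_len(nrow(X)))
ruleset <- induce_cluster_rules(apply_impute(imp, X), labels, seed = seed)
write_ruleset_json(ruleset, "results/cluster_rules.json")
for (cid in names(ruleset$rules)) {
  r <- ruleset$rules[[cid]]
  cat(sprintf("cluster %s: %s\n", cid,
              if (is.null(r)) "(no rule)" else format(r)))
}

# holdout features, assembled exactly like the discovery table (winsorized
# base features + yearly-binned records); subjects missing any rule
# variable are excluded before assignment (non-imputed data)
hold_records <- utils::read.delim("results/holdout_records.tsv")
base_features <- c(sprintf("z%d_hi", 1:4), sprintf("z%d_lo", 1:4),
                   "noise1", "noise2")
hold_X <- holdout[, base_features]
for (j in base_features) hold_X[[j]] <- winsorize(hold_X[[j]])
hold_X <- cbind(hold_X, bin_yearly(hold_records, holdout,
                                   med_codes = "nsaid"))
assignment <- assign_clusters(
  ruleset, hold_X,
  discovery_case_pct = setNames(clusters$case_fraction, clusters$cluster),
  discovery_sizes = setNames(clusters$size, clusters$cluster))
concordance <- compare_populations(clusters, assignment, holdout$is_case)

write.table(assignment$table, "results/holdout_assignment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_json(list(fractions = as.list(assignment$fractions),
                excluded_missing = assignment$n_excluded_missing,
                per_cluster = concordance$per_cluster,
                r2_case_fraction = concordance$r2_case_fraction,
                r2_size_fraction = concordance$r2_size_fraction),
           "results/holdout_concordance.json", auto_unbox = TRUE,
           digits = NA, pretty = TRUE)

cat(sprintf("assignment: %.1f%% unique, %.1f%% ambiguous, %.1f%% unassigned\n",
            100 * assignment$fractions["unique"],
            100 * assignment$fractions["ambiguous"],
            100 * assignment$fractions["unassigned"]))
cat(sprintf("case-fraction R^2 %.3f, size-fraction R^2 %.3f\n",
            concordance$r2_case_fraction, concordance$r2_size_fraction))
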