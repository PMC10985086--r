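#!/usr/bin/env Rscript
# Stage 4: TreeSHAP explanation of the out-of-fold predictions.
#
# Per-subject attributions come from the fold model that held the subject
# out; the global ranking is the mean absolute attribution per feature, and
# one example subject gets a waterfall risk profile.

library(shapclust)

discovery <- read_cohort_tsv("results/discovery_cohort.tsv")
feat <- utils::read.delim("results/feature_table.tsv")
X <- feat[, setdiff(names(feat), "subject_id")]
state <- readRDS("results/model_state.rds")

shap <- shap_values(state$bundle, X)
stopifnot(max(abs(shap$base + rowSums(shap$values) -
                    qlogis(state$probs))) < 1e-3)

ranking <- global_ranking(shap, top_k = 40L)
write.table(ranking, "results/shap_ranking.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cbind(subject_id = discovery$subject_id,
                  as.data.frame(shap$values)),
            "results/shap_values.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
saveRDS(shap, "results/shap_state.rds")

subject <- which.max(state$probs)
wf <- waterfall_profile(shap, subject, X)
cat(sprintf("top features by mean |SHAP|: %s\n",
            paste(head(ranking$feature, 6), collapse = ", ")))
cat(sprintf("example subject %s: predicted risk %.2f\n",
            discovery$subject_id[subject], wf$predicted_prob))
print(head(wf$profile, 5), row.names = FALSE)
cat(sprintf("risk without the top attribution: %.2f\n",
            prob_without_feature(shap, subject, wf$profile$feature[1])))
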