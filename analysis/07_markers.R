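#!/usr/bin/env Rscript
# Stage 7: per-cluster molecular marker discovery.
#
# Simulates an NPX-style protein panel for the discovery subjects with one
# protein shifted per archetype, normalizes it (per-subject mean outlier
# filter), and runs the one-vs-rest logistic likelihood-ratio test with a
# sex covariate among cases only, Bonferroni-corrected per cluster; the
# heatmap panel takes the top 2 up-/down-regulated proteins per cluster.

library(shapclust)
library(jsonlite)

discovery <- read_cohort_tsv("results/discovery_cohort.tsv")
labels <- utils::read.delim("results/cluster_labels.tsv")$cluster
seed <- 31L

set.seed(seed)
n <- nrow(discovery)
n_prot <- 100L
omics <- as.data.frame(matrix(rnorm(n * n_prot), n, n_prot))
names(omics) <- sprintf("prot%03d", seq_len(n_prot))
# plant one marker per archetype (+1.5 SD in that archetype's members)
for (k in 1:4) {
  sel <- discovery$true_archetype == k
  omics[[k]][sel] <- omics[[k]][sel] + 1.5
}
sex <- rbinom(n, 1L, 0.5)

omics_n <- normalize_omics(omics, "protein")
kept <- setdiff(seq_len(n), attr(omics_n, "removed_subjects"))
cat(sprintf("NPX outlier filter removed %d of %d subjects\n",
            n - length(kept), n))

res <- de_markers(omics_n, labels[kept],
                  covariates = data.frame(sex = sex[kept]),
                  case_labels = discovery$is_case[kept],
                  subset = "cases_only")
panel <- top_markers(res, k = 2L)

write.table(res, "results/marker_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_json(panel$per_cluster, "results/marker_panel.json", auto_unbox = TRUE,
           digits = NA, pretty = TRUE)

sig <- res[res$p_adjusted <= 0.05, ]
cat(sprintf("%d significant (cluster, protein) pairs across %d clusters\n",
            nrow(sig), length(unique(res$cluster))))
cat(sprintf("marker panel: %s\n", paste(panel$panel, collapse = ", ")))
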