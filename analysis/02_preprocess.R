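#!/usr/bin/env Rscript
# Stage 2: assemble the model-ready feature table.
#
# Winsorizes the assessment-centre style features at the 1st/99th
# percentiles, bins the longitudinal records into yearly pre-index features
# (11-month medians for biomarkers, binary flags for medications), and
# reports which features the missingness / near-zero-variance filters would
# exclude on the full table. Fold-internal filtering and imputation happen
# inside the model stage; this stage only materialises the combined table.

library(shapclust)
library(jsonlite)

discovery <- read_cohort_tsv("results/discovery_cohort.tsv")
records <- utils::read.delim("results/discovery_records.tsv")

base_features <- c(sprintf("z%d_hi", 1:4), sprintf("z%d_lo", 1:4),
                   "noise1", "noise2")
X <- discovery[, base_features]
for (j in base_features) X[[j]] <- winsorize(X[[j]])

binned <- bin_yearly(records, discovery, med_codes = "nsaid")
X <- cbind(X, binned)

flt <- filter_features(X, train_rows = seq_len(nrow(X)))
write.table(cbind(subject_id = discovery$subject_id, flt$table),
            "results/feature_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_json(flt$exclusions, "results/feature_exclusions.json",
           auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("feature table: %d subjects x %d features (%d excluded)\n",
            nrow(flt$table), ncol(flt$table), nrow(flt$exclusions)))
cat(sprintf("missing cells: %d (%.2f%%)\n", sum(is.na(flt$table)),
            100 * mean(as.matrix(is.na(flt$table)))))
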