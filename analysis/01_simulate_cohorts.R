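#!/usr/bin/env Rscript
# Stage 1: simulate the study populations.
#
# Builds a case-control cohort with four planted risk archetypes (conjunctive
# feature rules with a +2 log-odds shift), splits it into the discovery
# population (index date 0-5 years after assessment) and simulates an
# independent holdout population with a 5-11 year window, plus longitudinal
# biomarker/medication records for the discovery subjects.

library(shapclust)

dir.create("results", showWarnings = FALSE)
seed <- 11L

discovery <- generate_subjects(planted_archetype_config(n = 4000L,
                                                        seed = seed))
holdout <- generate_subjects(planted_archetype_config(n = 3000L,
                                                      seed = seed + 1000L,
                                                      window = c(5, 11)))

specs_bio <- list(
  list(code = "crp", mean = 3, between_sd = 1, ar_rho = 0.6, ar_sd = 0.5),
  list(code = "igf1", mean = 22, between_sd = 4, ar_rho = 0.8, ar_sd = 1))
specs_med <- list(
  list(code = "nsaid", p_case = c(0.6, 0.4, 0.3, 0.2, 0.2),
       p_control = 0.15))
records <- simulate_longitudinal(discovery, specs_bio, specs_med,
                                 seed = seed + 2L)
records_h <- simulate_longitudinal(holdout, specs_bio, specs_med,
                                   seed = seed + 3L)

write_cohort_tsv(discovery, "results/discovery_cohort.tsv")
write_cohort_tsv(holdout, "results/holdout_cohort.tsv")
write_records_tsv(records, "results/discovery_records.tsv")
write_records_tsv(records_h, "results/holdout_records.tsv")

cat(sprintf("discovery: %d subjects (%.1f%% cases), archetype sizes: %s\n",
            nrow(discovery), 100 * mean(discovery$is_case),
            paste(table(discovery$true_archetype), collapse = " ")))
cat(sprintf("holdout: %d subjects (%.1f%% cases)\n",
            nrow(holdout), 100 * mean(holdout$is_case)))
cat(sprintf("longitudinal records: %d rows, %d codes\n",
            nrow(records), length(unique(records$code))))
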