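test_that("generator produces the configured cohort size and case fraction", {
  cfg <- cohort_config(n_cases = 19120L, n_controls = 19252L,
                       features = list(feature_spec("x", "continuous")),
                       seed = 7L)
  coh <- generate_subjects(cfg)
  expect_equal(nrow(coh), 38372L)
  expect_true(all(coh$is_case %in% 0:1))
  expect_equal(anyDuplicated(coh$subject_id), 0L)
  target <- 19120 / 38372
  expect_lt(abs(mean(coh$is_case) - target), 0.02)
})

test_that("no-signal cohorts carry no discrimination", {
  cfg <- cohort_config(5000L, 5000L,
                       features = list(feature_spec("x", "continuous",
                                                    effect = 0)),
                       seed = 11L)
  coh <- generate_subjects(cfg)
  # constant true risk: rank AUC is exactly 1/2
  expect_equal(auc_rank(coh$is_case, coh$true_risk), 0.5)
  expect_lt(abs(auc_rank(coh$is_case, coh$x) - 0.5), 0.02)
})

test_that("binormal benchmark feature attains the closed-form AUC", {
  coh <- generate_subjects(gaussian_signal_config(n = 10000L, d = 1.19,
                                                  seed = 3L))
  expect_lt(abs(auc_rank(coh$is_case, coh$x) - pnorm(1.19 / sqrt(2))), 0.02)
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- planted_archetype_config(n = 600L, n_archetypes = 2L, seed = 5L)
  expect_identical(generate_subjects(cfg), generate_subjects(cfg))
})

test_that("planted archetype membership is noiseless and near target prevalence", {
  cfg <- planted_archetype_config(n = 3000L, n_archetypes = 3L, seed = 13L)
  coh <- generate_subjects(cfg)
  X <- cohort_features(coh)
  for (k in 1:3) {
    sat <- X[[sprintf("z%d_hi", k)]] > 1.6 & X[[sprintf("z%d_lo", k)]] <= -1.6
    expect_identical(unname(coh$true_archetype == k), unname(sat))
  }
  prev <- table(factor(coh$true_archetype, levels = 0:3)) / nrow(coh)
  expect_true(all(abs(prev[2:4] - 0.10) < 0.03))
})

test_that("infeasible intercept calibration is an explicit error", {
  cfg <- cohort_config(100L, 9900L,
                       features = list(feature_spec("x", "continuous",
                                                    effect = 100)),
                       seed = 1L)
  expect_error(generate_subjects(cfg), "infeasible")
})

test_that("missingness is inserted at the configured per-feature rate", {
  cfg <- cohort_config(2000L, 2000L,
                       features = list(feature_spec("a", "continuous"),
                                       feature_spec("b", "continuous")),
                       missing_rate = c(a = 0.3, b = 0),
                       seed = 21L)
  coh <- generate_subjects(cfg)
  expect_lt(abs(mean(is.na(coh$a)) - 0.3), 0.03)
  expect_identical(sum(is.na(coh$b)), 0L)
})

test_that("population split partitions subjects by index-assessment gap", {
  cfg <- cohort_config(300L, 300L,
                       features = list(feature_spec("x", "continuous")),
                       assessment_to_index_years = c(0, 12), seed = 9L)
  coh <- generate_subjects(cfg)
  # plant exact boundary gaps (days; year = 365)
  coh$assessment_date[1:3] <- 0L
  coh$index_date[1:3] <- c(round(4.9 * 365), round(5.1 * 365), 12L * 365L)
  sp <- split_populations(coh)
  expect_equal(nrow(sp$discovery) + nrow(sp$holdout) + nrow(sp$dropped),
               nrow(coh))
  expect_true(coh$subject_id[1] %in% sp$discovery$subject_id)
  expect_true(coh$subject_id[2] %in% sp$holdout$subject_id)
  expect_true(coh$subject_id[3] %in% sp$dropped$subject_id)
  gap <- sp$discovery$index_date - sp$discovery$assessment_date
  expect_true(all(gap > 0 & gap <= 5 * 365))
  gap_h <- sp$holdout$index_date - sp$holdout$assessment_date
  expect_true(all(gap_h > 5 * 365 & gap_h <= 11 * 365))
  empty <- split_populations(coh[0, ])
  expect_equal(nrow(empty$discovery), 0L)
  expect_equal(nrow(empty$holdout), 0L)
})

test_that("control matching is date-anchored, eligible-only and seeded", {
  cfg <- cohort_config(100L, 100L,
                       features = list(feature_spec("x", "continuous")),
                       seed = 31L)
  cases <- generate_subjects(cfg)[1:100, ]
  cases$is_case <- 1L
  pool <- generate_subjects(cohort_config(500L, 500L,
    features = list(feature_spec("x", "continuous")), seed = 32L))[1:500, ]
  pool$obs_start_date <- -10000L
  pool$obs_end_date <- 100000L
  m1 <- match_controls(cases, pool, seed = 3L)
  m2 <- match_controls(cases, pool, seed = 3L)
  expect_identical(m1$subject_id, m2$subject_id)
  expect_equal(anyDuplicated(m1$subject_id), 0L)
  expect_identical(m1$index_date, cases$index_date)

  # a control whose observation starts 2 years before the diagnosis date is
  # ineligible (coverage must span the full 5 years before the index date)
  one_case <- cases[1, ]
  short <- pool[1:1, ]
  short$obs_start_date <- one_case$index_date - 2L * 365L
  expect_error(match_controls(one_case, short, seed = 1L),
               one_case$subject_id, fixed = TRUE)
})

test_that("longitudinal simulation honours means, flags and AR(1) structure", {
  cfg <- cohort_config(30L, 30L,
                       features = list(feature_spec("x", "continuous")),
                       seed = 41L)
  coh <- generate_subjects(cfg)
  # zero noise: every monthly value equals the subject mean
  rec <- simulate_longitudinal(coh,
    biomarker_specs = list(list(code = "crp", mean = 7, between_sd = 0,
                                ar_rho = 0, ar_sd = 0)), seed = 2L)
  expect_true(all(rec$value == 7))
  expect_true(all(rec$date < coh$index_date[match(rec$subject_id,
                                                  coh$subject_id)]))
  # medication probability 1 in year -1 for cases: every case has an event
  recm <- simulate_longitudinal(coh,
    med_specs = list(list(code = "nsaid", p_case = c(1, 0, 0, 0, 0),
                          p_control = 0)), seed = 3L)
  idx <- coh$index_date[match(recm$subject_id, coh$subject_id)]
  yr1 <- recm[idx - recm$date <= 365, ]
  expect_setequal(unique(yr1$subject_id), coh$subject_id[coh$is_case == 1])
  # empty specs are not an error
  expect_equal(nrow(simulate_longitudinal(coh, seed = 1L)), 0L)
})

test_that("AR(1) series reproduce the specified lag-1 autocorrelation", {
  cfg <- cohort_config(500L, 500L,
                       features = list(feature_spec("x", "continuous")),
                       seed = 43L)
  coh <- generate_subjects(cfg)
  rec <- simulate_longitudinal(coh,
    biomarker_specs = list(list(code = "alt", mean = 30, between_sd = 0,
                                ar_rho = 0.5, ar_sd = 1)), seed = 4L)
  ac <- vapply(split(rec$value, rec$subject_id), function(v) {
    stats::cor(v[-1], v[-length(v)])
  }, numeric(1))
  expect_lt(abs(mean(ac) - 0.5), 0.05)
})

test_that("cohort TSV round-trips with empty cells as missing", {
  cfg <- cohort_config(50L, 50L,
                       features = list(feature_spec("x", "continuous")),
                       missing_rate = 0.2, seed = 51L)
  coh <- generate_subjects(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_tsv(coh, path)
  back <- read_cohort_tsv(path)
  expect_equal(back$subject_id, coh$subject_id)
  expect_equal(is.na(back$x), is.na(coh$x))
  expect_equal(back$x, coh$x, tolerance = 1e-12)
})
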