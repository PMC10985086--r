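# Shared fixtures, computed lazily and cached for the whole test run.
# The two expensive ones (the analytic-benchmark nested CV and the
# planted-archetype pipeline) are reused across several test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# single binormal Gaussian feature, d = 1.19, n = 5000, 5x5 nested CV
gauss_run <- function() {
  fixture("gauss_run", function() {
    cohort <- generate_subjects(gaussian_signal_config(n = 5000L, d = 1.19,
                                                       seed = 1301L))
    fit <- nested_cv_auc(cohort_features(cohort), cohort$is_case,
                         grid = hyper_grid(eta = 0.3, nrounds = c(50, 100)),
                         seed = 1302L)
    fit$cohort <- cohort
    fit$shap <- shap_values(fit$bundle, cohort_features(cohort))
    fit
  })
}

# 4 planted archetypes, n = 4000: full pipeline plus a 5-11y holdout cohort
arch_run <- function() {
  fixture("arch_run", function() {
    cohort <- generate_subjects(planted_archetype_config(n = 4000L,
                                                         seed = 2401L))
    pipeline <- run_pipeline(cohort, seed = 2402L)
    holdout <- generate_subjects(planted_archetype_config(
      n = 3000L, seed = 2403L, window = c(5, 11)))
    validation <- validate_holdout(pipeline, holdout)
    list(cohort = cohort, pipeline = pipeline, holdout = holdout,
         validation = validation)
  })
}

# small two-blob embedding with a planted case blob, for subgroup unit tests
blob_embedding <- function(n_per = 250L, sep = 10, seed = 501L) {
  set.seed(seed)
  scores <- rbind(matrix(rnorm(n_per * 2), n_per, 2),
                  matrix(rnorm(n_per * 2, mean = sep), n_per, 2))
  list(scores = scores, truth = rep(1:2, each = n_per))
}

# build a rule object directly (bypasses induction) for holdout/rules tests
make_rule <- function(conditions, precision = 1, recall = 1, trees = 1L) {
  structure(list(conditions = do.call(rbind, lapply(conditions, function(co)
                   data.frame(feature = co[[1]], op = co[[2]],
                              threshold = as.numeric(co[[3]])))),
                 oob_precision = precision, oob_recall = recall,
                 tree = 1L, tree_count = trees),
            class = "rule")
}

make_ruleset <- function(rules) {
  structure(list(rules = rules, candidates = list(),
                 clusters = as.integer(names(rules))),
            class = "rule_set")
}
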