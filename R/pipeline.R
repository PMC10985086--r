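#' Benchmark cohort configurations with planted structure
#'
#' `gaussian_signal_config()` builds the analytic benchmark: a single
#' Gaussian feature whose class-conditional distributions are unit-variance
#' normals separated by `d`, so the attainable ROC-AUC has the closed form
#' `pnorm(d / sqrt(2))`. This is realised inside the generator's logistic
#' label mechanism by giving the feature the equal binormal mixture marginal
#' `(1-pi) N(0,1) + pi N(d,1)` with log-odds effect `d`; the calibrated
#' intercept then equals `-d^2/2 + logit(pi)` analytically and
#' `P(case | x)` is exactly the stated logistic model.
#'
#' `planted_archetype_config()` builds the subgroup-recovery benchmark:
#' `n_archetypes` latent subgroups, each defined by a two-condition
#' conjunctive rule on its own pair of standard-normal features (one `>`
#' and one `<=` condition at |z| = 1.6), prevalence 0.10 each, and a +2
#' log-odds risk shift for members; two additional noise features carry no
#' effect. Membership is noiseless by construction: members' condition
#' values are drawn uniformly on a short interval beyond the threshold
#' (margin 0.25, width 0.2) and non-members are rejection-sampled out of
#' both the joint rule region and the threshold-to-margin band, so each
#' planted threshold is the unique boundary inside an empty band of the
#' data and tree-based rule recovery is well-posed at data resolution.
#'
#' @param n total subjects (split roughly half cases / half controls).
#' @param d log-odds effect of the single Gaussian feature.
#' @param seed generation seed.
#' @param window assessment-to-index window in years.
#' @return a [cohort_config()].
#' @export
gaussian_signal_config <- function(n = 5000L, d = 1.19, seed = 1L,
                                   window = c(0, 5)) {
  n_cases <- as.integer(round(n / 2))
  pi_case <- n_cases / n
  x <- feature_spec("x", "continuous", effect = d,
                    mixture = list(means = c(0, d), sds = c(1, 1),
                                   weights = c(1 - pi_case, pi_case)))
  cohort_config(n_cases = n_cases, n_controls = n - n_cases,
                features = list(x), archetypes = list(), missing_rate = 0,
                assessment_to_index_years = window, seed = seed)
}

#' @rdname gaussian_signal_config
#' @param n_archetypes number of planted subgroups (default 4).
#' @param risk_shift log-odds shift for archetype members (default 2).
#' @param threshold rule threshold magnitude on the N(0,1) features
#'   (default 1.6).
#' @param prevalence per-archetype population fraction (default 0.10).
#' @export
planted_archetype_config <- function(n = 4000L, n_archetypes = 4L,
                                     risk_shift = 2, threshold = 1.6,
                                     prevalence = 0.10, seed = 1L,
                                     window = c(0, 5)) {
  stopifnot(n_archetypes >= 1L, n_archetypes * prevalence < 1)
  features <- list()
  archetypes <- list()
  for (k in seq_len(n_archetypes)) {
    fa <- sprintf("z%d_hi", k)
    fb <- sprintf("z%d_lo", k)
    features <- c(features, list(feature_spec(fa, "continuous"),
                                 feature_spec(fb, "continuous")))
    archetypes <- c(archetypes, list(archetype_spec(
      id = k,
      rule = list(list(feature = fa, op = ">", threshold = threshold),
                  list(feature = fb, op = "<=", threshold = -threshold)),
      risk_shift = risk_shift, prevalence = prevalence, margin = 0.25,
      reject_buffer = 0.15, coerce_width = 0.2)))
  }
  features <- c(features, list(feature_spec("noise1", "continuous"),
                               feature_spec("noise2", "continuous")))
  n_cases <- as.integer(round(n / 2))
  cohort_config(n_cases = n_cases, n_controls = n - n_cases,
                features = features, archetypes = archetypes,
                missing_rate = 0, assessment_to_index_years = window,
                seed = seed)
}

#' Run the full risk-subgrouping pipeline on a cohort
#'
#' Generation (optional), nested cross-validated boosted model, out-of-fold
#' predictions and metrics, TreeSHAP explanation, PCA + Louvain SHAP-space
#' clustering across a resolution grid with cluster-score selection, and
#' per-cluster rule induction. All stochastic steps derive their seeds from
#' `seed`, so a rerun with the same inputs is bit-identical.
#'
#' @param cohort a `cohort_table` (e.g. from [generate_subjects()]).
#' @param grid hyperparameter grid (defaults to a compact desk-scale grid;
#'   pass [hyper_grid()] for the full 42-combination protocol grid).
#' @param resolutions Louvain resolution grid.
#' @param seed master seed.
#' @param pca_dim embedding dimensionality (default 10, capped at the
#'   feature count).
#' @param k_neighbors SNN neighbourhood size (default 20).
#' @param n_subsamples silhouette subsamples (default 30).
#' @return a `pipeline_result` list: folds, bundle, oof probabilities,
#'   metrics, shap, ranking, embedding, scan (all solutions), solution
#'   (selected), imputed feature table, ruleset.
#' @export
run_pipeline <- function(cohort,
                         grid = hyper_grid(eta = c(0.1, 0.3),
                                           nrounds = c(50, 100, 200)),
                         resolutions = c(0.002, 0.005, 0.01, 0.02, 0.05,
                                         0.1, 0.2, 0.5, 1.0),
                         seed = 1L, pca_dim = 10L, k_neighbors = 20L,
                         n_subsamples = 30L) {
  X <- cohort_features(cohort)
  y <- cohort$is_case
  folds <- make_nested_folds(y, seed = seed)
  bundle <- tune_and_train(folds, X, y, grid)
  probs <- predict_oof(bundle, X)
  metrics <- evaluate(y, probs, folds)
  shap <- shap_values(bundle, X)
  ranking <- global_ranking(shap, top_k = ncol(shap$values))
  emb <- embed_pca(shap, d = min(pca_dim, ncol(shap$values) - 1L))
  scan <- scan_resolutions(emb, probs, y, resolutions = resolutions,
                           k_neighbors = k_neighbors,
                           n_subsamples = n_subsamples, seed = seed)
  solution <- scan$selected
  # rules are induced on the (imputed) original inputs, pooled medians
  imp <- fit_impute(X, seq_len(nrow(X)))
  Xi <- apply_impute(imp, X)
  ruleset <- induce_cluster_rules(Xi, solution$labels, seed = seed)
  structure(list(cohort = cohort, folds = folds, bundle = bundle,
                 probs = probs, metrics = metrics, shap = shap,
                 ranking = ranking, embedding = emb, scan = scan,
                 solution = solution, features_imputed = Xi,
                 ruleset = ruleset, seed = seed),
            class = "pipeline_result")
}

#' Validate a pipeline's rule set on a holdout cohort
#'
#' Applies the discovery rule set to an independent cohort (no retraining),
#' resolving ambiguous matches by discovery case percentage, and reports the
#' assignment-category fractions and discovery/holdout concordance.
#'
#' @param pipeline a `pipeline_result`.
#' @param holdout_cohort a `cohort_table` from the same generator family
#'   (typically a longer assessment-to-index window).
#' @return list with `assignment` and `concordance`.
#' @export
validate_holdout <- function(pipeline, holdout_cohort) {
  ct <- pipeline$solution$clusters
  case_pct <- stats::setNames(ct$case_fraction, ct$cluster)
  sizes <- stats::setNames(ct$size, ct$cluster)
  Xh <- cohort_features(holdout_cohort)
  assignment <- assign_clusters(pipeline$ruleset, Xh, case_pct, sizes)
  keep <- if (assignment$n_excluded_missing > 0L) {
    vars <- unique(unlist(lapply(Filter(Negate(is.null),
                                        pipeline$ruleset$rules),
                                 function(r) r$conditions$feature)))
    stats::complete.cases(Xh[, vars, drop = FALSE])
  } else rep(TRUE, nrow(Xh))
  concordance <- compare_populations(ct, assignment,
                                     holdout_cohort$is_case[keep])
  list(assignment = assignment, concordance = concordance)
}

#' Serialize the headline pipeline outputs as deterministic text
#'
#' Fixed-format JSON/TSV renderings of the fold metrics, cluster labels,
#' selected rules and score table; used both by the analysis drivers and to
#' check that pipeline reruns are byte-identical.
#'
#' @param pipeline a `pipeline_result`.
#' @return named character vector of serialized documents.
#' @export
serialize_pipeline <- function(pipeline) {
  met <- jsonlite::toJSON(list(
    mean = as.list(round(pipeline$metrics$mean, 10)),
    ci_lower = as.list(round(pipeline$metrics$ci_lower, 10)),
    ci_upper = as.list(round(pipeline$metrics$ci_upper, 10)),
    counts = as.list(pipeline$metrics$counts)),
    auto_unbox = TRUE, digits = NA)
  labels <- paste(pipeline$solution$labels, collapse = "\n")
  rules <- jsonlite::toJSON(lapply(names(pipeline$ruleset$rules), function(cid) {
    r <- pipeline$ruleset$rules[[cid]]
    if (is.null(r)) list(cluster = as.integer(cid)) else
      list(cluster = as.integer(cid), rule = format(r),
           oob_precision = round(r$oob_precision, 10),
           oob_recall = round(r$oob_recall, 10),
           tree_count = r$tree_count)
  }), auto_unbox = TRUE, digits = NA)
  scores <- paste(utils::capture.output(
    utils::write.table(format(pipeline$scan$score_table, digits = 12),
                       sep = "\t", quote = FALSE, row.names = FALSE)),
    collapse = "\n")
  c(metrics_json = as.character(met), labels_tsv = labels,
    rules_json = as.character(rules), score_table_tsv = scores)
}
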