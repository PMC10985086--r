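#' Construct nested stratified cross-validation folds
#'
#' Two-level, case-control stratified: outer folds partition all subjects;
#' within each outer training set, inner folds partition its subjects. Per
#' fold, the number of members of each class is within one subject of the
#' stratified target.
#'
#' @param labels binary 0/1 vector.
#' @param k_outer,k_inner fold counts (default 5 and 5).
#' @param seed integer seed.
#' @return a `nested_folds` list: `outer` (fold id per subject), `inner`
#'   (list over outer folds; fold id per subject, NA on the outer test set),
#'   `seed`.
#' @export
make_nested_folds <- function(labels, k_outer = 5L, k_inner = 5L, seed = 1L) {
  stopifnot(all(labels %in% c(0, 1)))
  if (min(table(labels)) < k_outer * k_inner)
    stop("a class has fewer members than k_outer * k_inner")
  set.seed(as.integer(seed))
  strat_assign <- function(idx, k) {
    out <- integer(length(idx))
    for (cls in unique(labels[idx])) {
      rows <- idx[labels[idx] == cls]
      out[match(sample(rows), idx)] <- rep_len(seq_len(k), length(rows))
    }
    out
  }
  n <- length(labels)
  outer <- strat_assign(seq_len(n), k_outer)
  inner <- lapply(seq_len(k_outer), function(o) {
    tr <- which(outer != o)
    v <- rep(NA_integer_, n)
    v[tr] <- strat_assign(tr, k_inner)
    v
  })
  structure(list(outer = outer, inner = inner, seed = as.integer(seed),
                 k_outer = k_outer, k_inner = k_inner),
            class = "nested_folds")
}

#' The hyperparameter grid of the boosted risk model
#'
#' Full default grid: learning rates 0.05-0.30 by 0.05 crossed with boosting
#' round counts (50, 100, 200, 300, 500, 700, 1000); 42 combinations.
#'
#' @param eta,nrounds grid axes.
#' @return data.frame with columns `eta`, `nrounds`.
#' @export
hyper_grid <- function(eta = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30),
                       nrounds = c(50, 100, 200, 300, 500, 700, 1000)) {
  stopifnot(all(eta > 0), all(nrounds >= 1))
  expand.grid(eta = eta, nrounds = as.integer(nrounds),
              KEEP.OUT.ATTRS = FALSE)
}

xgb_params <- function(eta, has_omics = FALSE, nthread = 1L) {
  p <- list(booster = "gbtree", objective = "binary:logistic",
            eval_metric = "logloss", eta = eta, max_depth = 10,
            min_child_weight = 50, subsample = 0.8,
            sampling_method = "uniform", nthread = nthread)
  if (has_omics) p$colsample_bytree <- 0.8
  p
}

fit_booster <- function(X, y, eta, nrounds, has_omics, seed, nthread = 1L) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = nthread)
  xgboost::xgb.train(params = xgb_params(eta, has_omics, nthread),
                     data = dtrain, nrounds = nrounds, verbose = 0)
}

predict_at <- function(bst, X, nrounds = NULL, contrib = FALSE,
                       nthread = 1L) {
  dm <- xgboost::xgb.DMatrix(as.matrix(X), nthread = nthread)
  if (is.null(nrounds))
    return(stats::predict(bst, dm, predcontrib = contrib))
  stats::predict(bst, dm, iterationrange = c(1, nrounds),
                 predcontrib = contrib)
}

# fold-internal preprocessing: filter + median imputation fitted on train rows
fit_fold_preprocess <- function(X, train_rows) {
  flt <- filter_features(X, train_rows)
  imp <- fit_impute(flt$table, train_rows)
  list(features = names(flt$table), imputation = imp,
       exclusions = flt$exclusions)
}

apply_fold_preprocess <- function(prep, X) {
  apply_impute(prep$imputation, X[, prep$features, drop = FALSE])
}

#' Grid-search and train the nested cross-validated boosted model
#'
#' For each outer fold, every (eta, nrounds) combination is scored by mean
#' inner-CV ROC-AUC — with feature filtering and median imputation refitted
#' inside each inner training partition so no held-out row influences
#' preprocessing — and the winner is refit on the full outer training set.
#' Per learning rate, a single booster is grown to the largest round count
#' and intermediate round counts are scored by truncated prediction, which
#' is equivalent to separate fits because boosting is sequential. Ties are
#' broken by fewer rounds, then smaller eta. When the grid has a single
#' combination the inner search is skipped.
#'
#' @param folds a `nested_folds`.
#' @param table raw feature data.frame (may contain missing values).
#' @param labels binary 0/1 vector.
#' @param grid data.frame from [hyper_grid()].
#' @param has_omics adds `colsample_bytree = 0.8` when TRUE.
#' @param nthread xgboost threads (default 1 for determinism).
#' @return a `model_bundle`: per outer fold the trained booster, chosen
#'   parameters, fold preprocessing, and feature list.
#' @export
tune_and_train <- function(folds, table, labels, grid = hyper_grid(),
                           has_omics = FALSE, nthread = 1L) {
  stopifnot(inherits(folds, "nested_folds"), nrow(table) == length(labels))
  etas <- sort(unique(grid$eta))
  rounds <- sort(unique(grid$nrounds))
  fold_models <- vector("list", folds$k_outer)
  for (o in seq_len(folds$k_outer)) {
    tr <- which(folds$outer != o)
    if (nrow(grid) > 1L) {
      cvauc <- matrix(0, length(etas), length(rounds),
                      dimnames = list(etas, rounds))
      for (i in seq_len(folds$k_inner)) {
        itr <- which(folds$inner[[o]] != i & !is.na(folds$inner[[o]]))
        ite <- which(folds$inner[[o]] == i)
        prep <- fit_fold_preprocess(table, itr)
        Xi <- apply_fold_preprocess(prep, table)
        for (e in seq_along(etas)) {
          bst <- fit_booster(Xi[itr, , drop = FALSE], labels[itr], etas[e],
                             max(rounds), has_omics,
                             seed = folds$seed + 1000L * o + 10L * i + e,
                             nthread = nthread)
          for (r in seq_along(rounds)) {
            p <- predict_at(bst, Xi[ite, , drop = FALSE], rounds[r],
                            nthread = nthread)
            a <- auc_rank(labels[ite], p)
            if (!is.finite(a))
              stop("non-finite inner AUC in outer fold ", o)
            cvauc[e, r] <- cvauc[e, r] + a / folds$k_inner
          }
        }
      }
      keep <- mapply(function(e, r) {
        any(grid$eta == e & grid$nrounds == r)
      }, rep(etas, times = length(rounds)),
         rep(rounds, each = length(etas)))
      flat <- data.frame(eta = rep(etas, times = length(rounds)),
                         nrounds = rep(rounds, each = length(etas)),
                         auc = as.vector(cvauc))[keep, ]
      flat <- flat[order(-flat$auc, flat$nrounds, flat$eta), ]
      best <- flat[1L, ]
    } else {
      best <- data.frame(eta = grid$eta[1], nrounds = grid$nrounds[1],
                         auc = NA_real_)
    }
    prep <- fit_fold_preprocess(table, tr)
    Xo <- apply_fold_preprocess(prep, table)
    bst <- fit_booster(Xo[tr, , drop = FALSE], labels[tr], best$eta,
                       best$nrounds, has_omics,
                       seed = folds$seed + 1000L * o, nthread = nthread)
    fold_models[[o]] <- list(booster = bst, eta = best$eta,
                             nrounds = best$nrounds,
                             inner_auc = best$auc, preprocess = prep)
  }
  structure(list(folds = folds, models = fold_models,
                 has_omics = has_omics, nthread = nthread),
            class = "model_bundle")
}

#' Out-of-fold predicted probabilities
#'
#' Every subject is predicted by the model of the outer fold whose training
#' set excluded that subject, using that fold's own imputation.
#'
#' @param bundle a `model_bundle`.
#' @param table the raw feature table the bundle was trained on.
#' @return numeric vector of probabilities, one per subject.
#' @export
predict_oof <- function(bundle, table) {
  stopifnot(inherits(bundle, "model_bundle"),
            nrow(table) == length(bundle$folds$outer))
  p <- rep(NA_real_, nrow(table))
  for (o in seq_len(bundle$folds$k_outer)) {
    te <- which(bundle$folds$outer == o)
    fm <- bundle$models[[o]]
    Xte <- apply_fold_preprocess(fm$preprocess, table[te, , drop = FALSE])
    p[te] <- predict_at(fm$booster, Xte, fm$nrounds,
                        nthread = bundle$nthread)
  }
  if (anyNA(p)) stop("subjects missing from the outer fold partition")
  p
}

#' Out-of-fold AUC of the full nested pipeline on a table
#'
#' Convenience wrapper: folds, tuning, training and out-of-fold evaluation in
#' one call.
#'
#' @inheritParams tune_and_train
#' @param seed fold seed.
#' @return list with `folds`, `bundle`, `probs`, `auc`.
#' @export
nested_cv_auc <- function(table, labels, grid = hyper_grid(), seed = 1L,
                          k_outer = 5L, k_inner = 5L, has_omics = FALSE,
                          nthread = 1L) {
  folds <- make_nested_folds(labels, k_outer, k_inner, seed)
  bundle <- tune_and_train(folds, table, labels, grid, has_omics, nthread)
  probs <- predict_oof(bundle, table)
  list(folds = folds, bundle = bundle, probs = probs,
       auc = auc_rank(labels, probs))
}

#' Permuted-label null distribution of the cross-validated AUC
#'
#' Each repetition permutes the outcome labels before fold construction and
#' runs the full nested pipeline, yielding an empirical null for the
#' out-of-fold AUC; the observed AUC is compared by one-sided rank.
#'
#' @inheritParams nested_cv_auc
#' @param n_reps number of permutation repetitions (>= 2).
#' @return list with `null_auc` (vector) and, given `observed_auc`, the
#'   one-sided empirical `p_value` = (1 + #\{null >= observed\}) / (n_reps + 1).
#' @param observed_auc optional observed AUC to rank against the null.
#' @export
permutation_null <- function(table, labels, n_reps = 100L,
                             grid = hyper_grid(), seed = 1L,
                             observed_auc = NULL, k_outer = 5L,
                             k_inner = 5L, nthread = 1L) {
  if (n_reps < 2L) stop("n_reps must be at least 2")
  null_auc <- vapply(seq_len(n_reps), function(r) {
    set.seed(seed + 7919L * r)
    perm <- sample(labels)
    nested_cv_auc(table, perm, grid, seed = seed + 7919L * r + 1L,
                  k_outer = k_outer, k_inner = k_inner,
                  nthread = nthread)$auc
  }, numeric(1))
  out <- list(null_auc = null_auc)
  if (!is.null(observed_auc))
    out$p_value <- (1 + sum(null_auc >= observed_auc)) / (n_reps + 1)
  out
}

#' Cross-validated AUC spread across random initialisations
#'
#' Re-runs the nested pipeline under `n_inits` different seeds (fold
#' assignment and booster subsampling both reseeded) and reports the AUC per
#' run, quantifying robustness to random initialisation.
#'
#' @inheritParams nested_cv_auc
#' @param n_inits number of reseeded runs.
#' @return numeric vector of AUCs, one per initialisation.
#' @export
robustness <- function(table, labels, n_inits = 100L, grid = hyper_grid(),
                       seed = 1L, k_outer = 5L, k_inner = 5L, nthread = 1L) {
  vapply(seq_len(n_inits), function(r) {
    nested_cv_auc(table, labels, grid, seed = seed + 104729L * r,
                  k_outer = k_outer, k_inner = k_inner,
                  nthread = nthread)$auc
  }, numeric(1))
}
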