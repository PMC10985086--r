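#' Per-subject TreeSHAP attributions on the log-odds scale
#'
#' Attributions for each subject come from the model of the outer fold that
#' held that subject out (path-dependent TreeSHAP, truncated to the fold's
#' chosen round count), so explanations carry no training optimism. The
#' additivity contract holds: base value + row sum of attributions equals the
#' logit of the out-of-fold predicted probability.
#'
#' @param bundle a `model_bundle`.
#' @param table the raw feature table the bundle was trained on.
#' @return a `shap_matrix`: list with `values` (subjects x features matrix,
#'   zero columns for fold-specific exclusions), `base` (per-subject base
#'   value), `fold` (outer fold id per subject).
#' @export
shap_values <- function(bundle, table) {
  stopifnot(inherits(bundle, "model_bundle"),
            nrow(table) == length(bundle$folds$outer))
  feats <- sort(unique(unlist(lapply(bundle$models,
                                     function(m) m$preprocess$features))))
  if (!all(feats %in% names(table)))
    stop("feature mismatch between bundle and table")
  n <- nrow(table)
  vals <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
  base <- rep(NA_real_, n)
  for (o in seq_len(bundle$folds$k_outer)) {
    te <- which(bundle$folds$outer == o)
    fm <- bundle$models[[o]]
    Xte <- apply_fold_preprocess(fm$preprocess, table[te, , drop = FALSE])
    ct <- predict_at(fm$booster, Xte, fm$nrounds, contrib = TRUE,
                     nthread = bundle$nthread)
    vals[te, fm$preprocess$features] <- ct[, seq_along(fm$preprocess$features),
                                           drop = FALSE]
    base[te] <- ct[, ncol(ct)]
  }
  structure(list(values = vals, base = base, fold = bundle$folds$outer),
            class = "shap_matrix")
}

#' Global feature ranking by mean absolute attribution
#'
#' @param shap a `shap_matrix`.
#' @param top_k how many features to keep (default 40).
#' @return data.frame (feature, mean_abs_shap), non-increasing; ties broken
#'   alphabetically.
#' @export
global_ranking <- function(shap, top_k = 40L) {
  stopifnot(inherits(shap, "shap_matrix"), nrow(shap$values) >= 1L)
  m <- colMeans(abs(shap$values))
  ord <- order(-m, names(m))
  out <- data.frame(feature = names(m)[ord], mean_abs_shap = unname(m[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, top_k)
}

#' Individual risk profile (waterfall decomposition)
#'
#' The `top_k` features by absolute attribution for one subject, signed, plus
#' a single remainder term aggregating all other features so that base +
#' bars + remainder reproduces the logit of the predicted probability.
#'
#' @param shap a `shap_matrix`.
#' @param subject row index of the subject.
#' @param table raw feature table (input values shown next to each bar).
#' @param top_k bars to keep (default 15).
#' @return list with `profile` (feature, input_value, attribution),
#'   `remainder`, `base`, `predicted_prob`.
#' @export
waterfall_profile <- function(shap, subject, table, top_k = 15L) {
  stopifnot(inherits(shap, "shap_matrix"))
  if (!(is.numeric(subject) && subject >= 1 && subject <= nrow(shap$values)))
    stop("unknown subject: ", subject)
  phi <- shap$values[subject, ]
  ord <- order(-abs(phi), names(phi))
  k <- min(top_k, length(phi))
  top <- ord[seq_len(k)]
  remainder <- sum(phi[-top])
  logit_p <- shap$base[subject] + sum(phi)
  list(profile = data.frame(
         feature = names(phi)[top],
         input_value = as.numeric(table[subject, names(phi)[top]]),
         attribution = unname(phi[top]),
         stringsAsFactors = FALSE),
       remainder = remainder,
       base = shap$base[subject],
       predicted_prob = stats::plogis(logit_p))
}

#' Predicted probability with one attribution removed
#'
#' Attribution arithmetic for the "risk without this feature" counterfactual:
#' the feature's SHAP value is subtracted from the predicted logit before the
#' sigmoid. This quantifies the feature's additive contribution, not a causal
#' effect.
#'
#' @param shap a `shap_matrix`.
#' @param subject row index.
#' @param feature feature name.
#' @return probability.
#' @export
prob_without_feature <- function(shap, subject, feature) {
  stopifnot(feature %in% colnames(shap$values))
  logit_p <- shap$base[subject] + sum(shap$values[subject, ])
  stats::plogis(logit_p - shap$values[subject, feature])
}
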