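#' One-vs-rest differential-abundance testing of omics features
#'
#' For each cluster and feature, a likelihood-ratio test (chi-squared, 1 df)
#' between nested logistic regressions of cluster membership on the
#' covariates with and without the feature. No minimum-detection filter is
#' applied and both directions are reported; p-values are Bonferroni-adjusted
#' within each cluster. Rows with missing omics values are dropped (counted
#' in the result attributes).
#'
#' @param omics numeric data.frame/matrix (subjects x features).
#' @param labels integer cluster labels.
#' @param covariates data.frame of adjustment covariates (default: none;
#'   typically a single `sex` column).
#' @param case_labels binary 0/1 outcome, required unless `subset = "all"`.
#' @param subset which subjects to test: `"cases_only"` (default),
#'   `"controls_only"` or `"all"`.
#' @return data.frame of `marker_result` rows: cluster, feature, coef,
#'   p_value, p_adjusted, direction (`up`/`down`/`none`), converged.
#' @export
de_markers <- function(omics, labels, covariates = NULL, case_labels = NULL,
                       subset = c("cases_only", "controls_only", "all")) {
  subset <- match.arg(subset)
  omics <- as.data.frame(omics)
  stopifnot(nrow(omics) == length(labels))
  if (subset != "all") {
    if (is.null(case_labels)) stop("case_labels required for subset ", subset)
    keep <- if (subset == "cases_only") case_labels == 1 else case_labels == 0
    omics <- omics[keep, , drop = FALSE]
    labels <- labels[keep]
    if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  }
  complete <- stats::complete.cases(omics)
  n_dropped <- sum(!complete)
  omics <- omics[complete, , drop = FALSE]
  labels <- labels[complete]
  if (!is.null(covariates)) covariates <- covariates[complete, , drop = FALSE]
  M0 <- if (is.null(covariates)) matrix(1, nrow(omics), 1L) else
    cbind(1, as.matrix(covariates))
  n_feat <- ncol(omics)
  fam <- stats::binomial()
  out <- list()
  for (c2 in sort(unique(labels))) {
    y <- as.numeric(labels == c2)
    fit0 <- stats::glm.fit(M0, y, family = fam)
    for (j in seq_len(n_feat)) {
      f <- omics[[j]]
      fit1 <- suppressWarnings(
        stats::glm.fit(cbind(M0, f), y, family = fam,
                       control = stats::glm.control(maxit = 50)))
      lr <- max(fit0$deviance - fit1$deviance, 0)
      p <- stats::pchisq(lr, df = 1L, lower.tail = FALSE)
      coef_f <- fit1$coefficients[ncol(M0) + 1L]
      if (is.na(coef_f)) coef_f <- 0
      out[[length(out) + 1L]] <- data.frame(
        cluster = c2, feature = names(omics)[j],
        coef = unname(coef_f), p_value = p,
        p_adjusted = min(1, p * n_feat),
        direction = if (lr <= 0 || coef_f == 0) "none"
                    else if (coef_f > 0) "up" else "down",
        converged = fit1$converged,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "n_dropped_missing") <- n_dropped
  res
}

#' Top up/down marker panel per cluster
#'
#' Per cluster, the `k` most significant up- and down-regulated features by
#' adjusted p-value; the union over clusters (deduplicated) forms the heatmap
#' panel. A feature is flagged significant at adjusted p <= 0.05.
#'
#' @param results output of [de_markers()].
#' @param k markers per direction per cluster (default 2).
#' @return list with `per_cluster` (data.frame incl. `significant` flag) and
#'   `panel` (unique feature names).
#' @export
top_markers <- function(results, k = 2L) {
  picks <- list()
  for (c2 in sort(unique(results$cluster))) {
    sub <- results[results$cluster == c2 & results$direction != "none", ,
                   drop = FALSE]
    for (dir in c("up", "down")) {
      d <- sub[sub$direction == dir, , drop = FALSE]
      d <- d[order(d$p_adjusted, d$p_value, d$feature), , drop = FALSE]
      picks[[length(picks) + 1L]] <- utils::head(d, k)
    }
  }
  per_cluster <- do.call(rbind, picks)
  if (is.null(per_cluster) || !nrow(per_cluster)) {
    return(list(per_cluster = data.frame(), panel = character(0)))
  }
  per_cluster$significant <- per_cluster$p_adjusted <= 0.05
  rownames(per_cluster) <- NULL
  list(per_cluster = per_cluster, panel = unique(per_cluster$feature))
}
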