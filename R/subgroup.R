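#' PCA embedding of the SHAP matrix
#'
#' Centered principal-component scores (no scaling). Component signs are
#' fixed by making each component's largest-magnitude loading positive, so
#' the embedding is deterministic.
#'
#' @param shap a `shap_matrix` or a plain numeric matrix.
#' @param d target dimensionality (default 10).
#' @return an `embedding` list: `scores` (subjects x d), `var_explained`.
#' @export
embed_pca <- function(shap, d = 10L) {
  X <- if (inherits(shap, "shap_matrix")) shap$values else as.matrix(shap)
  stopifnot(nrow(X) > d)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (rank < d) {
    warning("matrix rank ", rank, " < requested ", d,
            " dimensions; returning ", rank, " components")
    d <- rank
  }
  flip <- vapply(seq_len(d), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(d), drop = FALSE], 2, flip, `*`)
  structure(list(scores = scores,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2)),
            class = "embedding")
}

#' Shared-nearest-neighbour graph of an embedding
#'
#' Each subject is connected to others by the Jaccard similarity of their
#' k-nearest-neighbour sets (Euclidean distance in the embedding); edges with
#' weight below `prune` are removed.
#'
#' @param embedding an `embedding` or score matrix.
#' @param k_neighbors neighbourhood size (default 20).
#' @param prune minimum retained Jaccard weight (default 1/15).
#' @param dist_matrix optional precomputed distance matrix (reused across
#'   resolutions and silhouette subsamples).
#' @return list with igraph `graph` and the `dist_matrix` used.
#' @export
snn_graph <- function(embedding, k_neighbors = 20L, prune = 1 / 15,
                      dist_matrix = NULL) {
  S <- if (inherits(embedding, "embedding")) embedding$scores else
    as.matrix(embedding)
  n <- nrow(S)
  stopifnot(n > k_neighbors)
  if (is.null(dist_matrix)) dist_matrix <- as.matrix(stats::dist(S))
  nn <- t(apply(dist_matrix, 1L, function(row) {
    order(row)[2:(k_neighbors + 1L)]   # nearest first; position 1 is self
  }))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- A %*% Matrix::t(A)
  shared <- methods::as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j
  i <- shared@i[keep] + 1L
  j <- shared@j[keep] + 1L
  w <- shared@x[keep] / (2 * k_neighbors - shared@x[keep])
  ok <- w >= prune
  g <- igraph::graph_from_edgelist(cbind(i[ok], j[ok]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[ok]
  list(graph = g, dist_matrix = dist_matrix)
}

#' Louvain clustering of the SNN graph at a resolution
#'
#' Modularity optimization at the given resolution; isolated subjects (all
#' their SNN edges pruned) are assigned to the cluster with the nearest
#' centroid in the embedding.
#'
#' @inheritParams snn_graph
#' @param resolution Louvain resolution parameter.
#' @param seed seed for the stochastic modularity optimization.
#' @param graph optional precomputed result of [snn_graph()].
#' @return integer cluster labels (1-based).
#' @export
cluster_graph <- function(embedding, resolution, k_neighbors = 20L,
                          seed = 1L, graph = NULL) {
  S <- if (inherits(embedding, "embedding")) embedding$scores else
    as.matrix(embedding)
  if (is.null(graph)) graph <- snn_graph(embedding, k_neighbors)
  g <- graph$graph
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(cl))
  iso <- which(igraph::degree(g) == 0)
  if (length(iso)) {
    real <- setdiff(sort(unique(labels[-iso])), labels[iso])
    cent <- t(vapply(real, function(c2)
      colMeans(S[setdiff(which(labels == c2), iso), , drop = FALSE]),
      numeric(ncol(S))))
    for (v in iso) {
      d2 <- rowSums(sweep(cent, 2, S[v, ], `-`)^2)
      labels[v] <- real[which.min(d2)]
    }
  }
  match(labels, sort(unique(labels)))
}

#' Weighted median (midpoint at exact half-mass)
#'
#' Sorts values, accumulates weights, and returns the first value whose
#' cumulative weight reaches half the total; when the cumulative weight hits
#' exactly half, the midpoint with the next value is returned (so the
#' equal-weight two-value case gives their average, as for the ordinary
#' median).
#'
#' @param x numeric values.
#' @param w positive weights.
#' @return the weighted median.
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w)
  half <- sum(w) / 2
  i <- which(cw >= half)[1L]
  if (cw[i] == half && i < length(x)) (x[i] + x[i + 1L]) / 2 else x[i]
}

#' The cluster-resolution score
#'
#' Ratio of cluster robustness to per-cluster prediction quality: weighted
#' mean of per-cluster silhouette summaries divided by one minus the weighted
#' median of per-cluster prediction values (F1). The resolution scan uses
#' equal per-cluster weights — every subgroup counts the same toward
#' resolution selection, so the score asks whether the *typical* cluster is
#' both robust and predictive; size weighting instead rewards splitting
#' poorly predicted mass into many small clusters below the weighted median,
#' i.e. fragmentation rather than resolution. When the weighted median F1
#' reaches 1 the score is the +Inf sentinel (such solutions win only via the
#' tie-break chain).
#'
#' @param silhouettes per-cluster silhouette summaries.
#' @param prediction_values per-cluster prediction values (F1).
#' @param weights per-cluster weights (default: equal).
#' @return the score (possibly `Inf`).
#' @export
cluster_score <- function(silhouettes, prediction_values, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(silhouettes))
  wmed <- weighted_median(prediction_values, weights)
  if (wmed >= 1 - 1e-9) return(Inf)
  stats::weighted.mean(silhouettes, weights) / (1 - wmed)
}

#' Score one clustering solution at a resolution
#'
#' Combines (i) subsampled silhouette widths — `n_subsamples` random
#' fractions of the subjects, Euclidean distance in the embedding, per-cluster
#' mean widths summarized by the median over subsamples; (ii) per-cluster
#' prediction metrics (F1/PPV/sensitivity at threshold 0.5 from out-of-fold
#' probabilities); and (iii) the [cluster_score()].
#'
#' @param embedding an `embedding`.
#' @param labels cluster labels from [cluster_graph()] on the same embedding.
#' @param oof_probs out-of-fold predicted probabilities.
#' @param case_labels binary 0/1 outcome.
#' @param resolution resolution the labels came from (bookkeeping).
#' @param n_subsamples,frac subsampling scheme (defaults 30 and 0.8).
#' @param seed subsampling seed.
#' @param dist_matrix optional precomputed distance matrix.
#' @return a `cluster_solution` list; `valid = FALSE` (score `NA`) when the
#'   solution has a single cluster.
#' @export
score_resolution <- function(embedding, labels, oof_probs, case_labels,
                             resolution = NA_real_, n_subsamples = 30L,
                             frac = 0.8, seed = 1L, dist_matrix = NULL) {
  S <- if (inherits(embedding, "embedding")) embedding$scores else
    as.matrix(embedding)
  n <- nrow(S)
  stopifnot(length(labels) == n, length(oof_probs) == n,
            length(case_labels) == n)
  ids <- sort(unique(labels))
  if (length(ids) < 2L) {
    return(structure(list(resolution = resolution, labels = labels,
                          clusters = NULL, score = NA_real_, valid = FALSE),
                     class = "cluster_solution"))
  }
  if (is.null(dist_matrix)) dist_matrix <- as.matrix(stats::dist(S))
  set.seed(as.integer(seed))
  sil <- matrix(NA_real_, n_subsamples, length(ids),
                dimnames = list(NULL, ids))
  m <- max(2L, floor(frac * n))
  for (s in seq_len(n_subsamples)) {
    idx <- sample.int(n, m)
    if (length(unique(labels[idx])) < 2L) next
    sw <- cluster::silhouette(labels[idx], dmatrix = dist_matrix[idx, idx])
    means <- tapply(sw[, "sil_width"], labels[idx], mean)
    sil[s, names(means)] <- means
  }
  med_sil <- apply(sil, 2L, stats::median, na.rm = TRUE)

  tab <- do.call(rbind, lapply(ids, function(c2) {
    sel <- labels == c2
    cc <- confusion_counts(case_labels[sel], oof_probs[sel])
    sens <- if (cc["TP"] + cc["FN"] == 0) 0 else cc["TP"] / (cc["TP"] + cc["FN"])
    ppv <- if (cc["TP"] + cc["FP"] == 0) 0 else cc["TP"] / (cc["TP"] + cc["FP"])
    f1 <- if (sens + ppv == 0) 0 else 2 * sens * ppv / (sens + ppv)
    data.frame(cluster = c2, size = sum(sel),
               size_fraction = mean(sel),
               case_fraction = mean(case_labels[sel]),
               mean_prob = mean(oof_probs[sel]),
               sensitivity = unname(sens), PPV = unname(ppv),
               F1 = unname(f1),
               silhouette = unname(med_sil[as.character(c2)]))
  }))
  score <- cluster_score(tab$silhouette, tab$F1)
  structure(list(resolution = resolution, labels = labels, clusters = tab,
                 score = score, valid = is.finite(score) || is.infinite(score)),
            class = "cluster_solution")
}

#' Scan resolutions and select the best clustering solution
#'
#' Clusters the embedding at each resolution of the grid (one SNN graph,
#' reused), scores each solution, and returns the argmax of the cluster
#' score; ties are broken by more clusters, then by lower resolution. The
#' full score table is kept for inspection.
#'
#' @inheritParams score_resolution
#' @param resolutions resolution grid; the default spans two orders of
#'   magnitude so the score maximum is bracketed at desk-scale cohort sizes.
#' @param k_neighbors SNN neighbourhood size.
#' @return list with `selected` (a `cluster_solution`), `solutions` (all),
#'   `score_table` (data.frame: resolution, n_clusters, score).
#' @export
scan_resolutions <- function(embedding, oof_probs, case_labels,
                             resolutions = c(0.002, 0.005, 0.01, 0.02,
                                             0.05, 0.1, 0.2, 0.5, 1.0),
                             k_neighbors = 20L, n_subsamples = 30L,
                             frac = 0.8, seed = 1L) {
  graph <- snn_graph(embedding, k_neighbors)
  solutions <- lapply(resolutions, function(r) {
    labels <- cluster_graph(embedding, r, k_neighbors, seed = seed,
                            graph = graph)
    score_resolution(embedding, labels, oof_probs, case_labels,
                     resolution = r, n_subsamples = n_subsamples,
                     frac = frac, seed = seed,
                     dist_matrix = graph$dist_matrix)
  })
  selected <- select_resolution(solutions)
  score_table <- do.call(rbind, lapply(solutions, function(s) data.frame(
    resolution = s$resolution,
    n_clusters = length(unique(s$labels)),
    score = s$score, valid = s$valid)))
  list(selected = selected, solutions = solutions,
       score_table = score_table)
}

#' Select the best of several scored cluster solutions
#'
#' @param solutions list of `cluster_solution` objects.
#' @return the winning solution (highest score; ties broken by more
#'   clusters, then lower resolution).
#' @export
select_resolution <- function(solutions) {
  valid <- Filter(function(s) isTRUE(s$valid) && !is.na(s$score), solutions)
  if (!length(valid)) stop("no valid cluster solution")
  key <- vapply(valid, function(s)
    c(s$score, length(unique(s$labels)), -s$resolution), numeric(3))
  best <- which(key[1, ] == max(key[1, ]))
  if (length(best) > 1L)
    best <- best[order(-key[2, best], -key[3, best])][1L] else best <- best[1L]
  valid[[best]]
}

#' Characterize clusters by recoded top-feature means
#'
#' Per-cluster mean of the top-k globally ranked features: binary features
#' stay on \{0,1\}, ordinal features are rescaled to \[0,1\] over their
#' declared level range, continuous features are Z-scored over all subjects.
#' The mean out-of-fold predicted probability per cluster is appended.
#'
#' @param solution a `cluster_solution`.
#' @param table raw (or imputed) feature table.
#' @param ranking output of [global_ranking()].
#' @param feature_meta list of [feature_spec()] (kinds and ordinal ranges);
#'   features absent from it are treated as continuous.
#' @param oof_probs out-of-fold probabilities.
#' @param top_k number of profile features (default 6).
#' @return data.frame: one row per cluster, recoded feature means +
#'   `mean_prob`.
#' @export
characterize <- function(solution, table, ranking, feature_meta = list(),
                         oof_probs = NULL, top_k = 6L) {
  feats <- utils::head(ranking$feature, top_k)
  meta <- stats::setNames(feature_meta,
                          vapply(feature_meta, function(f) f$name,
                                 character(1)))
  recoded <- lapply(feats, function(f) {
    v <- table[[f]]
    fm <- meta[[f]]
    kind <- if (is.null(fm)) "continuous" else fm$kind
    switch(kind,
           binary = v,
           ordinal = v / (fm$n_levels - 1L),
           (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE))
  })
  names(recoded) <- feats
  labels <- solution$labels
  out <- do.call(rbind, lapply(sort(unique(labels)), function(c2) {
    row <- vapply(recoded, function(v) mean(v[labels == c2], na.rm = TRUE),
                  numeric(1))
    df <- as.data.frame(as.list(row))
    names(df) <- feats
    df$cluster <- c2
    if (!is.null(oof_probs)) df$mean_prob <- mean(oof_probs[labels == c2])
    df
  }))
  out[, c("cluster", setdiff(names(out), "cluster"))]
}
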