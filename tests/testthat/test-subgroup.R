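test_that("PCA embedding is deterministic, ordered and rank-aware", {
  set.seed(41)
  X <- matrix(rnorm(200 * 6), 200, 6)
  emb <- embed_pca(X, d = 4)
  expect_identical(emb$scores, embed_pca(X, d = 4)$scores)
  v <- apply(emb$scores, 2, var)
  expect_true(all(diff(v) <= 1e-12))
  # eigen-decomposition oracle for the component variances
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(unname(v), ev[1:4], tolerance = 1e-8)
  # duplicated subjects embed identically
  Xd <- rbind(X, X[1, , drop = FALSE])
  embd <- embed_pca(Xd, d = 4)
  expect_equal(embd$scores[201, ], embd$scores[1, ], tolerance = 1e-10)
  # rank-deficient input degrades with a warning
  Xr <- cbind(X[, 1], X[, 1] * 2, X[, 1] + 1)
  expect_warning(er <- embed_pca(Xr, d = 2), "rank")
  expect_lt(ncol(er$scores), 2L)
})

test_that("graph clustering separates well-separated blobs and is seeded", {
  blobs <- blob_embedding()
  # a coarse resolution consistent with the graph size (community counts
  # scale with n at fixed resolution; see the resolution-grid discussion in
  # the methods vignette)
  labels <- cluster_graph(blobs$scores, resolution = 0.1, seed = 6L)
  expect_equal(length(unique(labels)), 2L)
  expect_equal(mclust::adjustedRandIndex(labels, blobs$truth), 1)
  expect_identical(labels, cluster_graph(blobs$scores, 0.1, seed = 6L))

  # labels invariant to subject order up to permutation
  perm <- sample(nrow(blobs$scores))
  lp <- cluster_graph(blobs$scores[perm, ], resolution = 0.1, seed = 6L)
  expect_equal(mclust::adjustedRandIndex(lp, labels[perm]), 1)
})

test_that("identical points collapse to one cluster", {
  pts <- matrix(1, 60, 3)
  labels <- cluster_graph(pts, resolution = 0.5, k_neighbors = 10L, seed = 2L)
  expect_equal(length(unique(labels)), 1L)
})

test_that("the cluster score matches its arithmetic oracle", {
  # worked instance: sizes {2,2}, silhouettes {0.5,0.3}, F1 {0.8,0.4} -> 1.0
  expect_equal(cluster_score(c(0.5, 0.3), c(0.8, 0.4), c(2, 2)), 1.0)

  # independent 10-line weighted-mean / weighted-median oracle
  oracle <- function(sil, f1, w) {
    wm <- sum(sil * w) / sum(w)
    o <- order(f1); f <- f1[o]; ww <- w[o]
    acc <- 0; med <- NA
    for (i in seq_along(f)) {
      acc <- acc + ww[i]
      if (acc > sum(w) / 2) { med <- f[i]; break }
      if (acc == sum(w) / 2) { med <- (f[i] + f[i + 1]) / 2; break }
    }
    wm / (1 - med)
  }
  set.seed(43)
  for (i in 1:200) {
    k <- sample(2:8, 1)
    sil <- runif(k, -0.2, 0.9)
    f1 <- runif(k, 0, 0.95)
    w <- sample(1:50, k, replace = TRUE)
    expect_equal(cluster_score(sil, f1, w), oracle(sil, f1, w),
                 tolerance = 1e-12)
  }
  # capped sentinel when the weighted median F1 reaches 1
  expect_identical(cluster_score(c(0.5, 0.5), c(1, 1), c(3, 3)), Inf)
})

test_that("resolution scoring summarises silhouettes and per-cluster metrics", {
  blobs <- blob_embedding()
  labels <- blobs$truth
  # perfect prediction in blob 2, none in blob 1
  case <- as.integer(labels == 2)
  probs <- ifelse(labels == 2, 0.9, 0.1)
  sol <- score_resolution(blobs$scores, labels, probs, case,
                          resolution = 0.5, seed = 3L)
  expect_true(sol$valid)
  expect_equal(sol$clusters$F1[sol$clusters$cluster == 2], 1)
  expect_true(all(sol$clusters$silhouette > 0.8))
  expect_equal(sum(sol$clusters$size_fraction), 1)
  # one-cluster solutions are invalid
  sol1 <- score_resolution(blobs$scores, rep(1L, nrow(blobs$scores)),
                           probs, case, seed = 3L)
  expect_false(sol1$valid)
  expect_true(is.na(sol1$score))
})

test_that("resolution selection takes the score argmax with stated tie-breaks", {
  mk <- function(score, k, res) {
    structure(list(resolution = res, labels = rep(1:k, each = 4),
                   clusters = NULL, score = score, valid = TRUE),
              class = "cluster_solution")
  }
  a <- mk(1.2, 3, 0.5); b <- mk(0.9, 6, 0.3)
  expect_identical(select_resolution(list(a, b)), a)
  expect_identical(select_resolution(list(b)), b)
  # score tie: more clusters wins, then lower resolution
  c1 <- mk(1.0, 4, 0.5); c2 <- mk(1.0, 5, 0.8); c3 <- mk(1.0, 5, 0.4)
  expect_identical(select_resolution(list(c1, c2, c3)), c3)
  expect_error(select_resolution(list(
    structure(list(valid = FALSE, score = NA), class = "cluster_solution"))),
    "no valid")
})

test_that("cluster profiles recode features and honour weighted-mean identities", {
  labels <- rep(1:2, each = 30)
  tab <- data.frame(age = c(rnorm(30, 50), rnorm(30, 70)),
                    drug = rep(c(0, 1), each = 30),
                    pace = rep(c(0L, 3L), each = 30))
  ranking <- data.frame(feature = c("age", "drug", "pace"),
                        mean_abs_shap = c(3, 2, 1))
  meta <- list(feature_spec("drug", "binary"),
               feature_spec("pace", "ordinal", n_levels = 4L))
  sol <- structure(list(labels = labels), class = "cluster_solution")
  prof <- characterize(sol, tab, ranking, meta, oof_probs = runif(60),
                       top_k = 3L)
  expect_equal(prof$drug, c(0, 1))           # binary kept on {0,1}
  expect_equal(prof$pace, c(0, 1))           # ordinal rescaled to [0,1]
  # z-scored continuous: size-weighted cluster means average to ~0
  expect_lt(abs(weighted.mean(prof$age, c(30, 30))), 1e-10)
  # a cluster of identical subjects profiles to that subject's recoded row
  tab2 <- tab; tab2[31:60, ] <- tab2[31, ]
  prof2 <- characterize(sol, tab2, ranking, meta, top_k = 3L)
  expect_equal(prof2$drug[2], tab2$drug[31])
})
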