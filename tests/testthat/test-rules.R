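test_that("condition normalization intersects same-feature intervals", {
  conds <- data.frame(feature = c("x", "x", "y"),
                      op = c("<=", "<=", ">"),
                      threshold = c(5, 3, 1))
  norm <- shapclust:::normalize_conditions(conds)
  expect_equal(norm$threshold[norm$feature == "x" & norm$op == "<="], 3)
  expect_equal(nrow(norm), 2L)
  both <- data.frame(feature = c("x", "x", "x"),
                     op = c(">", "<=", ">"),
                     threshold = c(1, 9, 2))
  nb <- shapclust:::normalize_conditions(both)
  expect_equal(nb$threshold[nb$op == ">"], 2)  # max of lower bounds
  expect_equal(nb$threshold[nb$op == "<="], 9)
})

test_that("a planted single-condition cluster is recovered with its threshold", {
  set.seed(47)
  n <- 500L
  tab <- data.frame(x1 = runif(n, 0, 4), x2 = rnorm(n))
  target <- as.integer(tab$x1 > 2)
  rules <- induce_rules(tab, target, seed = 5L)
  expect_gt(length(rules), 0L)
  sel <- select_cluster_rule(deduplicate(rules))
  expect_equal(nrow(sel$conditions), 1L)
  expect_equal(sel$conditions$feature, "x1")
  expect_equal(sel$conditions$op, ">")
  lo <- max(tab$x1[tab$x1 <= 2])
  hi <- min(tab$x1[tab$x1 > 2])
  expect_gte(sel$conditions$threshold, lo)
  expect_lt(sel$conditions$threshold, hi)
  expect_equal(sel$oob_precision, 1)

  # unsatisfiable recall filter empties the candidate list
  expect_equal(length(induce_rules(tab, target, recall_min = 1.01,
                                   seed = 5L)), 0L)
  expect_error(induce_rules(tab, rep(1L, n), seed = 1L), "both classes")
  tab_na <- tab; tab_na$x1[1] <- NA
  expect_error(induce_rules(tab_na, target, seed = 1L), "imputed")
})

test_that("deduplication merges semantically equal rules and counts trees", {
  r1 <- make_rule(list(list("x", ">", 1.5)), precision = 0.9, recall = 0.8)
  r2 <- make_rule(list(list("x", ">", 1.5)), precision = 0.95, recall = 0.7)
  r2$tree <- 2L
  r3 <- make_rule(list(list("y", "<=", 0)), precision = 0.8, recall = 0.9)
  r3$tree <- 3L
  out <- deduplicate(list(r1, r2, r3))
  expect_equal(length(out), 2L)
  merged <- out[[which(vapply(out, function(r)
    r$conditions$feature[1] == "x", logical(1)))]]
  expect_equal(merged$tree_count, 2L)
  expect_equal(merged$oob_precision, 0.95)  # keeper is best (precision, recall)

  # thresholds differing below 6 significant digits merge
  r4 <- make_rule(list(list("x", ">", 1.5 + 1e-9)))
  r4$tree <- 4L
  expect_equal(length(deduplicate(list(r1, r4))), 1L)
  # clearly different thresholds stay distinct
  r5 <- make_rule(list(list("x", ">", 1.6)))
  expect_equal(length(deduplicate(list(r1, r5))), 2L)
})

test_that("rule selection is a total order over the stated keys", {
  a <- make_rule(list(list("x", ">", 1)), precision = 0.7, recall = 0.5,
                 trees = 3L)
  b <- make_rule(list(list("y", ">", 2)), precision = 0.9, recall = 0.9,
                 trees = 1L)
  expect_identical(select_cluster_rule(list(a, b)), a)   # tree count first
  c1 <- make_rule(list(list("x", ">", 1)), precision = 0.9, recall = 0.4,
                  trees = 2L)
  c2 <- make_rule(list(list("y", ">", 2)), precision = 0.7, recall = 0.9,
                  trees = 2L)
  expect_identical(select_cluster_rule(list(c1, c2)), c1) # then precision
  d1 <- make_rule(list(list("b", ">", 1)), trees = 2L)
  d2 <- make_rule(list(list("a", ">", 1)), trees = 2L)
  expect_identical(select_cluster_rule(list(d1, d2)), d2) # string fallback
  expect_null(select_cluster_rule(list()))

  # permuting the candidate list never changes the winner
  set.seed(53)
  cands <- list(a, b, c1, c2, d1, d2)
  winner <- select_cluster_rule(cands)
  for (i in 1:10) {
    expect_identical(select_cluster_rule(sample(cands)), winner)
  }
})

test_that("rule application is a missing-aware conjunction with count oracles", {
  rule <- make_rule(list(list("age", ">", 60), list("nsaid", ">", 0.5)))
  tab <- data.frame(age = c(65, 65, 50, NA), nsaid = c(1, 0, 1, 1))
  expect_identical(apply_rule(rule, tab), c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(apply_rule(rule, tab[0, ]), logical(0))
  expect_error(apply_rule(make_rule(list(list("ghost", ">", 0))), tab),
               "unknown feature")

  set.seed(59)
  big <- data.frame(age = runif(500, 40, 80), nsaid = rbinom(500, 1, 0.4))
  labels <- rbinom(500, 1, 0.5)
  m <- rule_metrics(rule, big, labels)
  fired <- big$age > 60 & big$nsaid == 1
  expect_equal(unname(m["precision"]), sum(labels == 1 & fired) / sum(fired))
  expect_equal(unname(m["recall"]), sum(labels == 1 & fired) / sum(labels == 1))
})

test_that("rule evaluation is monotone in threshold relaxation", {
  set.seed(61)
  tab <- data.frame(a = rnorm(300), b = rnorm(300))
  for (i in 1:20) {
    rule <- make_rule(list(list("a", "<=", rnorm(1)),
                           list("b", ">", rnorm(1))))
    fired <- apply_rule(rule, tab)
    relaxed <- rule
    relaxed$conditions$threshold[relaxed$conditions$op == "<="] <-
      relaxed$conditions$threshold[relaxed$conditions$op == "<="] + abs(rnorm(1))
    fired2 <- apply_rule(relaxed, tab)
    expect_true(all(fired2[fired]))      # relaxing never shrinks the set
  }
})

test_that("planted conjunctive archetype rules are recovered from true labels", {
  coh <- generate_subjects(planted_archetype_config(n = 3000L,
                                                    n_archetypes = 2L,
                                                    seed = 67L))
  X <- cohort_features(coh)
  for (k in 1:2) {
    sel <- select_cluster_rule(deduplicate(
      induce_rules(X, as.integer(coh$true_archetype == k), seed = 67L + k)))
    expect_equal(nrow(sel$conditions), 2L)
    expect_setequal(sel$conditions$feature,
                    c(sprintf("z%d_hi", k), sprintf("z%d_lo", k)))
    expect_gte(sel$oob_precision, 0.9)
    fired <- apply_rule(sel, X)
    expect_gte(mean(fired[coh$true_archetype == k]), 0.9)
  }
})
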