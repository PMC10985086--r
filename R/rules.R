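#' @title Conjunctive threshold rules from bagged decision trees
#' @description
#' Rule induction for one cluster (one-vs-rest): shallow classification
#' trees (Gini impurity) are fitted on bootstrap bags; every root-to-leaf
#' path ending in a majority-positive leaf becomes a candidate conjunctive
#' rule; conditions on the same feature are intersected; each rule is scored
#' on its source tree's out-of-bag samples and filtered on out-of-bag recall
#' and precision.
#' @name rules
NULL

new_rule <- function(conditions, oob_precision = NA_real_,
                     oob_recall = NA_real_, tree = NA_integer_,
                     tree_count = 1L) {
  conditions <- conditions[order(conditions$feature, conditions$op), ,
                           drop = FALSE]
  rownames(conditions) <- NULL
  structure(list(conditions = conditions, oob_precision = oob_precision,
                 oob_recall = oob_recall, tree = tree,
                 tree_count = tree_count),
            class = "rule")
}

#' @export
format.rule <- function(x, ...) {
  paste(sprintf("%s %s %.6g", x$conditions$feature, x$conditions$op,
                x$conditions$threshold), collapse = " & ")
}

#' @export
print.rule <- function(x, ...) {
  cat(format(x), sprintf("  [oob precision %.3f, recall %.3f, trees %d]\n",
                         x$oob_precision, x$oob_recall, x$tree_count))
  invisible(x)
}

# Intersect same-feature conditions: keep the tightest <= and > bounds.
normalize_conditions <- function(conditions) {
  parts <- split(conditions, conditions$feature)
  out <- do.call(rbind, lapply(parts, function(p) {
    res <- list()
    le <- p$threshold[p$op == "<="]
    gt <- p$threshold[p$op == ">"]
    if (length(le)) res[[length(res) + 1L]] <-
      data.frame(feature = p$feature[1], op = "<=", threshold = min(le))
    if (length(gt)) res[[length(res) + 1L]] <-
      data.frame(feature = p$feature[1], op = ">", threshold = max(gt))
    do.call(rbind, res)
  }))
  rownames(out) <- NULL
  out
}

# Parse the split strings of path.rpart ("x>=1.5", "x< 2.5") into (feature,
# op, threshold). rpart splits continuous features at midpoints between
# observed values, so "x < c" and "x <= c" classify the data identically.
parse_rpart_path <- function(path_strings) {
  conds <- lapply(path_strings, function(s) {
    if (grepl(">=", s, fixed = TRUE)) {
      at <- regexpr(">=", s, fixed = TRUE)
      data.frame(feature = trimws(substr(s, 1, at - 1)), op = ">",
                 threshold = as.numeric(substr(s, at + 2, nchar(s))))
    } else if (grepl("< ", s, fixed = TRUE) || grepl("<", s, fixed = TRUE)) {
      at <- regexpr("<", s, fixed = TRUE)
      data.frame(feature = trimws(substr(s, 1, at - 1)), op = "<=",
                 threshold = as.numeric(substr(s, at + 1, nchar(s))))
    } else {
      stop("unparseable split: ", s)
    }
  })
  normalize_conditions(do.call(rbind, conds))
}

#' Evaluate a rule on a table
#'
#' Row-wise conjunction of the rule's conditions; a missing value in any
#' condition feature makes the rule not fire for that row.
#'
#' @param rule a `rule`.
#' @param table feature data.frame.
#' @return logical vector.
#' @export
apply_rule <- function(rule, table) {
  missing_feats <- setdiff(rule$conditions$feature, names(table))
  if (length(missing_feats))
    stop("unknown feature(s) in rule: ", paste(missing_feats, collapse = ", "))
  fired <- rep(TRUE, nrow(table))
  for (r in seq_len(nrow(rule$conditions))) {
    v <- table[[rule$conditions$feature[r]]]
    hit <- if (rule$conditions$op[r] == "<=") v <= rule$conditions$threshold[r]
           else v > rule$conditions$threshold[r]
    hit[is.na(hit)] <- FALSE
    fired <- fired & hit
  }
  fired
}

#' Precision and recall of a rule against labels
#'
#' @param rule a `rule`.
#' @param table feature data.frame.
#' @param labels binary 0/1 target.
#' @return named vector (precision, recall, n_fired).
#' @export
rule_metrics <- function(rule, table, labels) {
  fired <- apply_rule(rule, table)
  pos <- labels == 1
  c(precision = if (any(fired)) mean(pos[fired]) else NA_real_,
    recall = if (any(pos)) mean(fired[pos]) else NA_real_,
    n_fired = sum(fired))
}

#' Induce candidate rules for a binary target from bagged trees
#'
#' @param table fully imputed feature data.frame.
#' @param target binary 0/1 cluster indicator (both classes present).
#' @param n_estimators number of bootstrap-bagged trees (default 10).
#' @param max_depth tree depth cap (default 5).
#' @param recall_min minimum out-of-bag recall (default 0.2).
#' @param seed bagging seed.
#' @return list of `rule` objects (oob precision > 0.5, recall >= recall_min).
#' @export
induce_rules <- function(table, target, n_estimators = 10L, max_depth = 5L,
                         recall_min = 0.2, seed = 1L) {
  stopifnot(nrow(table) == length(target), all(target %in% c(0, 1)))
  if (length(unique(target)) < 2L)
    stop("target must contain both classes")
  if (anyNA(table)) stop("table must be fully imputed")
  set.seed(as.integer(seed))
  n <- nrow(table)
  df <- cbind(.y = factor(target, levels = c(0, 1)), table)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0.001,
                               minsplit = 20L, maxcompete = 0L,
                               maxsurrogate = 0L, usesurrogate = 0L,
                               xval = 0L)
  rules <- list()
  for (b in seq_len(n_estimators)) {
    bag <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(bag))
    if (length(unique(target[bag])) < 2L || !length(oob)) next
    fit <- rpart::rpart(.y ~ ., data = df[bag, , drop = FALSE],
                        method = "class", control = ctrl)
    if (nrow(fit$frame) < 2L) next
    counts <- fit$frame$yval2          # cols 2:3 are class counts (0, 1)
    node_ids <- as.integer(rownames(fit$frame))
    leaves <- fit$frame$var == "<leaf>"
    pos_nodes <- setdiff(node_ids[leaves & counts[, 3L] > counts[, 2L]], 1L)
    if (!length(pos_nodes)) next
    paths <- rpart::path.rpart(fit, nodes = pos_nodes, print.it = FALSE)
    oob_tab <- table[oob, , drop = FALSE]
    oob_y <- target[oob]
    for (p in paths) {
      conds <- parse_rpart_path(p[-1L])  # first element is "root"
      rule <- new_rule(conds, tree = b)
      m <- rule_metrics(rule, oob_tab, oob_y)
      if (is.na(m["precision"]) || is.na(m["recall"])) next
      if (m["recall"] < recall_min || m["precision"] <= 0.5) next
      rule$oob_precision <- unname(m["precision"])
      rule$oob_recall <- unname(m["recall"])
      rules[[length(rules) + 1L]] <- rule
    }
  }
  rules
}

rule_key <- function(rule) {
  paste(sprintf("%s%s%.6g", rule$conditions$feature, rule$conditions$op,
                signif(rule$conditions$threshold, 6)), collapse = "|")
}

#' Deduplicate semantically equal rules
#'
#' Rules whose condition sets (up to `max_depth_duplication` terms,
#' thresholds rounded to 6 significant digits) coincide are merged: the rule
#' with lexicographically highest (oob precision, oob recall) is kept and its
#' `tree_count` becomes the number of distinct source trees in the group.
#'
#' @param rules list of scored `rule` objects.
#' @param max_depth_duplication term-count cap for the grouping (default 7).
#' @return deduplicated list of rules.
#' @export
deduplicate <- function(rules, max_depth_duplication = 7L) {
  if (!length(rules)) return(rules)
  keys <- vapply(rules, function(r) {
    if (nrow(r$conditions) <= max_depth_duplication) rule_key(r)
    else paste0("long:", rule_key(r))
  }, character(1))
  out <- lapply(split(seq_along(rules), keys), function(grp) {
    members <- rules[grp]
    ord <- order(-vapply(members, `[[`, numeric(1), "oob_precision"),
                 -vapply(members, `[[`, numeric(1), "oob_recall"))
    keeper <- members[[ord[1L]]]
    keeper$tree_count <-
      length(unique(vapply(members, `[[`, integer(1), "tree")))
    keeper
  })
  unname(out)
}

#' Select the single headline rule for a cluster
#'
#' Total order: most source trees, then highest out-of-bag precision, then
#' highest out-of-bag recall, then fewest conditions, then lexicographic
#' condition string.
#'
#' @param candidates deduplicated list of rules.
#' @return the winning `rule`, or `NULL` when there are no candidates.
#' @export
select_cluster_rule <- function(candidates) {
  if (!length(candidates)) return(NULL)
  ord <- order(-vapply(candidates, `[[`, integer(1), "tree_count"),
               -vapply(candidates, `[[`, numeric(1), "oob_precision"),
               -vapply(candidates, `[[`, numeric(1), "oob_recall"),
               vapply(candidates, function(r) nrow(r$conditions), integer(1)),
               vapply(candidates, format, character(1)))
  candidates[[ord[1L]]]
}

#' Induce, filter and select one rule per cluster
#'
#' One-vs-rest rule induction on the original (imputed) model input values
#' for every cluster of a solution.
#'
#' @param table fully imputed feature data.frame.
#' @param labels integer cluster labels.
#' @param n_estimators,max_depth,recall_min,max_depth_duplication induction
#'   parameters (defaults 10, 5, 0.2, 7).
#' @param seed seed (offset per cluster).
#' @return a `rule_set`: list with `rules` (cluster id -> selected `rule` or
#'   `NULL`), `candidates` (per cluster), `clusters`.
#' @export
induce_cluster_rules <- function(table, labels, n_estimators = 10L,
                                 max_depth = 5L, recall_min = 0.2,
                                 max_depth_duplication = 7L, seed = 1L) {
  ids <- sort(unique(labels))
  candidates <- list()
  selected <- list()
  for (c2 in ids) {
    cand <- deduplicate(
      induce_rules(table, as.integer(labels == c2), n_estimators, max_depth,
                   recall_min, seed = seed + c2),
      max_depth_duplication)
    candidates[[as.character(c2)]] <- cand
    selected[[as.character(c2)]] <- select_cluster_rule(cand)
  }
  structure(list(rules = selected, candidates = candidates, clusters = ids),
            class = "rule_set")
}

#' Serialize / read a rule set as JSON
#' @param ruleset a `rule_set`.
#' @param path file path.
#' @export
write_ruleset_json <- function(ruleset, path) {
  obj <- lapply(names(ruleset$rules), function(cid) {
    r <- ruleset$rules[[cid]]
    if (is.null(r)) return(list(cluster = as.integer(cid), rule = NULL))
    list(cluster = as.integer(cid),
         conditions = r$conditions,
         oob_precision = r$oob_precision,
         oob_recall = r$oob_recall,
         tree_count = r$tree_count)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
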