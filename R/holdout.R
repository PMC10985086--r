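#' Assign holdout subjects to clusters via the rule set
#'
#' Each subject is matched against every cluster's selected rule. Firing
#' exactly one rule gives a unique assignment; firing several is resolved in
#' favour of the matched cluster with the highest discovery case percentage
#' (ties: larger discovery cluster, then lowest cluster id); firing none
#' leaves the subject unassigned. By default subjects with missing values in
#' any rule variable are excluded beforehand (non-imputed data are used for
#' validation); set `exclude_missing = FALSE` to let missing values simply
#' fail the condition instead.
#'
#' @param ruleset a `rule_set`.
#' @param holdout feature data.frame of the holdout population.
#' @param discovery_case_pct named per-cluster case percentage in the
#'   discovery population.
#' @param discovery_sizes named per-cluster discovery sizes (tie-break).
#' @param exclude_missing drop subjects missing any rule variable (default
#'   TRUE).
#' @return an `assignment_result`: `table` (per retained subject: matched
#'   clusters, category, final cluster), `fractions` (unique / ambiguous /
#'   unassigned, summing to 1), `n_excluded_missing`.
#' @export
assign_clusters <- function(ruleset, holdout, discovery_case_pct,
                            discovery_sizes = NULL, exclude_missing = TRUE) {
  stopifnot(inherits(ruleset, "rule_set"))
  have_rule <- !vapply(ruleset$rules, is.null, logical(1))
  rules <- ruleset$rules[have_rule]
  if (!length(rules)) stop("rule set has no selected rules")
  vars <- unique(unlist(lapply(rules, function(r) r$conditions$feature)))
  if (!all(vars %in% names(holdout)))
    stop("holdout table lacks rule variable(s): ",
         paste(setdiff(vars, names(holdout)), collapse = ", "))
  n_excluded <- 0L
  if (exclude_missing) {
    complete <- stats::complete.cases(holdout[, vars, drop = FALSE])
    n_excluded <- sum(!complete)
    holdout <- holdout[complete, , drop = FALSE]
  }
  fired <- vapply(rules, function(r) apply_rule(r, holdout),
                  logical(nrow(holdout)))
  if (nrow(holdout) == 1L) fired <- matrix(fired, nrow = 1L,
                                           dimnames = list(NULL, names(rules)))
  cids <- as.integer(names(rules))
  pct <- discovery_case_pct[names(rules)]
  sizes <- if (is.null(discovery_sizes)) stats::setNames(rep(0, length(rules)),
                                                         names(rules))
           else discovery_sizes[names(rules)]
  n <- nrow(holdout)
  matched <- character(n)
  category <- character(n)
  final <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    hit <- which(fired[i, ])
    matched[i] <- paste(cids[hit], collapse = ",")
    if (length(hit) == 0L) {
      category[i] <- "unassigned"
    } else if (length(hit) == 1L) {
      category[i] <- "unique"
      final[i] <- cids[hit]
    } else {
      category[i] <- "ambiguous"
      ord <- hit[order(-pct[hit], -sizes[hit], cids[hit])]
      final[i] <- cids[ord[1L]]
    }
  }
  fractions <- c(unique = mean(category == "unique"),
                 ambiguous = mean(category == "ambiguous"),
                 unassigned = mean(category == "unassigned"))
  structure(list(table = data.frame(
                   subject = rownames(holdout) %||% seq_len(n),
                   matched_clusters = matched, category = category,
                   final_cluster = final, stringsAsFactors = FALSE),
                 fractions = fractions,
                 n_excluded_missing = n_excluded),
            class = "assignment_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discovery/holdout concordance of per-cluster fractions
#'
#' Per-cluster case fraction and size fraction in both populations, compared
#' by the squared Pearson correlation across clusters. Clusters without any
#' assigned holdout subject are excluded (and reported); fewer than 3
#' comparable clusters is an error.
#'
#' @param discovery_clusters the `clusters` table of a `cluster_solution`
#'   (columns `cluster`, `case_fraction`, `size_fraction`).
#' @param assignment an `assignment_result` on the holdout population.
#' @param holdout_labels binary 0/1 case labels of the retained holdout
#'   subjects (same order as `assignment$table`).
#' @return a `concordance_report`: per-cluster fractions in both populations,
#'   `r2_case_fraction`, `r2_size_fraction`, `excluded_clusters`.
#' @export
compare_populations <- function(discovery_clusters, assignment,
                                holdout_labels) {
  stopifnot(inherits(assignment, "assignment_result"),
            length(holdout_labels) == nrow(assignment$table))
  fin <- assignment$table$final_cluster
  assigned <- !is.na(fin)
  per <- do.call(rbind, lapply(discovery_clusters$cluster, function(c2) {
    sel <- assigned & fin == c2
    data.frame(cluster = c2,
               disc_case_fraction =
                 discovery_clusters$case_fraction[
                   discovery_clusters$cluster == c2],
               disc_size_fraction =
                 discovery_clusters$size_fraction[
                   discovery_clusters$cluster == c2],
               hold_n = sum(sel),
               hold_case_fraction = if (any(sel)) mean(holdout_labels[sel])
                                    else NA_real_,
               hold_size_fraction = sum(sel) / sum(assigned))
  }))
  excluded <- per$cluster[per$hold_n == 0L]
  cmp <- per[per$hold_n > 0L, , drop = FALSE]
  if (nrow(cmp) < 3L)
    stop("fewer than 3 clusters with assigned holdout subjects")
  structure(list(per_cluster = per,
                 r2_case_fraction =
                   stats::cor(cmp$disc_case_fraction,
                              cmp$hold_case_fraction)^2,
                 r2_size_fraction =
                   stats::cor(cmp$disc_size_fraction,
                              cmp$hold_size_fraction)^2,
                 excluded_clusters = excluded),
            class = "concordance_report")
}
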