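#' Winsorize a numeric vector at percentile bounds
#'
#' Values outside the `lo_pct`/`hi_pct` percentiles (type-7 quantiles, the
#' convention used throughout the package) are clipped to those percentile
#' values. Missing entries pass through unchanged.
#'
#' @param values numeric vector with at least two non-missing entries.
#' @param lo_pct,hi_pct percentile bounds (defaults 1 and 99).
#' @return clipped vector of the same length.
#' @export
winsorize <- function(values, lo_pct = 1, hi_pct = 99) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("winsorize needs at least 2 non-missing values")
  q <- stats::quantile(values[ok], c(lo_pct, hi_pct) / 100, type = 7,
                       names = FALSE)
  out <- values
  out[ok] <- pmin(pmax(values[ok], q[1]), q[2])
  out
}

#' Bin longitudinal records into yearly pre-index features
#'
#' Records are assigned to yearly bins counted back from each subject's index
#' date (year k covers days `((k-1)*365, k*365]` before the index date).
#' Continuous codes are summarized by the median over an 11-month window: the
#' 30-day month adjacent to the index-date side of each bin is excluded,
#' leaving a time-gap between snapshots and the index date. Medication codes
#' become a binary flag: 1 if any prescription event falls anywhere in the
#' year bin. Bins with no data are missing.
#'
#' @param records long-format records (subject_id, code, value, date).
#' @param cohort `cohort_table` supplying `index_date` per subject.
#' @param med_codes character vector of codes treated as medications.
#' @param n_years number of yearly bins (default 5).
#' @param excluded_days width of the excluded month (default 30 days).
#' @return data.frame: one row per cohort subject, columns
#'   `<code>_pre<k>y`.
#' @export
bin_yearly <- function(records, cohort, med_codes = character(0),
                       n_years = 5L, excluded_days = 30L) {
  idx <- stats::setNames(cohort$index_date, cohort$subject_id)
  out <- data.frame(row.names = seq_len(nrow(cohort)))
  codes <- unique(records$code)
  offset <- idx[records$subject_id] - records$date  # days before index, > 0
  for (code in codes) {
    is_med <- code %in% med_codes
    sel <- records$code == code
    for (k in seq_len(n_years)) {
      lo <- (k - 1L) * DAYS_PER_YEAR
      hi <- k * DAYS_PER_YEAR
      inbin <- sel & offset > lo & offset <= hi
      if (!is_med) inbin <- inbin & offset > lo + excluded_days
      col <- rep(NA_real_, nrow(cohort))
      if (any(inbin)) {
        agg <- if (is_med) {
          tapply(records$value[inbin], records$subject_id[inbin],
                 function(v) as.numeric(length(v) > 0L))
        } else {
          tapply(records$value[inbin], records$subject_id[inbin],
                 stats::median)
        }
        col[match(names(agg), cohort$subject_id)] <- as.numeric(agg)
      }
      if (is_med) col[is.na(col)] <- 0
      out[[sprintf("%s_pre%dy", code, k)]] <- col
    }
  }
  out
}

#' Filter features by missingness and near-zero variance
#'
#' Evaluated on training rows only: features with a missing fraction above
#' `max_missing` are dropped, as are near-zero-variance features (frequency
#' ratio of the two most common values above 95/5 *and* fewer than 10% unique
#' values — the conventional thresholds of the filter).
#'
#' @param table data.frame of features.
#' @param train_rows integer or logical index of training rows.
#' @param max_missing missing-fraction cutoff (default 0.5).
#' @param freq_ratio,unique_cut near-zero-variance thresholds.
#' @return list with `table` (retained features, all rows) and `exclusions`
#'   data.frame (feature, reason, statistic).
#' @export
filter_features <- function(table, train_rows, max_missing = 0.5,
                            freq_ratio = 95 / 5, unique_cut = 10) {
  tr <- table[train_rows, , drop = FALSE]
  stopifnot(nrow(tr) >= 1L)
  excl <- list()
  keep <- logical(ncol(table))
  for (j in seq_along(table)) {
    v <- tr[[j]]
    miss <- mean(is.na(v))
    if (miss > max_missing) {
      excl[[length(excl) + 1L]] <- data.frame(
        feature = names(table)[j], reason = "missingness", statistic = miss)
      next
    }
    vv <- v[!is.na(v)]
    tab <- sort(table(vv), decreasing = TRUE)
    fr <- if (length(tab) == 1L) Inf else as.numeric(tab[1] / tab[2])
    uniq_pct <- 100 * length(tab) / length(vv)
    if (fr > freq_ratio && uniq_pct < unique_cut) {
      excl[[length(excl) + 1L]] <- data.frame(
        feature = names(table)[j], reason = "near_zero_variance",
        statistic = fr)
      next
    }
    keep[j] <- TRUE
  }
  if (!any(keep)) stop("all features excluded by filters")
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(feature = character(0), reason = character(0),
               statistic = numeric(0))
  list(table = table[, keep, drop = FALSE], exclusions = exclusions)
}

#' Fit and apply median imputation
#'
#' Medians are learned on the training partition only (across cases and
#' controls pooled) and fill every missing cell on application, so imputation
#' never leaks information from held-out rows.
#'
#' @param table filtered feature data.frame.
#' @param train_rows training-row index.
#' @return `fit_impute`: an `imputation_model` (named medians);
#'   `apply_impute`: the table with all missing cells filled.
#' @export
fit_impute <- function(table, train_rows) {
  med <- vapply(table, function(v) {
    vv <- v[train_rows]
    vv <- vv[!is.na(vv)]
    if (!length(vv))
      stop("feature with no non-missing training values ",
           "(should have been filtered)")
    stats::median(vv)
  }, numeric(1))
  structure(list(medians = med), class = "imputation_model")
}

#' @rdname fit_impute
#' @param model an `imputation_model`.
#' @export
apply_impute <- function(model, table) {
  stopifnot(inherits(model, "imputation_model"),
            all(names(table) %in% names(model$medians)))
  for (j in names(table)) {
    miss <- is.na(table[[j]])
    if (any(miss)) table[[j]][miss] <- model$medians[[j]]
  }
  table
}

#' Normalize omics feature tables
#'
#' Metabolite features measured as absolute concentrations are square-root
#' transformed (ratios/percentages untouched). Protein (NPX) tables are
#' subject-filtered: individuals whose mean expression falls below the 0.2th
#' or above the 99.8th percentile of the cohort's per-subject means are
#' removed as extreme outliers.
#'
#' @param table numeric omics data.frame (subjects x features).
#' @param kind `"metabolite"` or `"protein"`.
#' @param absolute for metabolites: names of features in absolute
#'   concentration units (default: all columns).
#' @return normalized table; for proteins, removed subjects are recorded in
#'   `attr(, "removed_subjects")` (row indices of the input).
#' @export
normalize_omics <- function(table, kind = c("metabolite", "protein"),
                            absolute = names(table)) {
  kind <- match.arg(kind)
  if (kind == "metabolite") {
    for (j in intersect(absolute, names(table))) {
      v <- table[[j]]
      if (any(v < 0, na.rm = TRUE))
        stop("negative concentration in metabolite feature ", j)
      table[[j]] <- sqrt(v)
    }
    return(table)
  }
  m <- rowMeans(as.matrix(table), na.rm = TRUE)
  q <- stats::quantile(m, c(0.002, 0.998), type = 7, names = FALSE)
  drop <- which(m < q[1] | m > q[2])
  out <- table[setdiff(seq_len(nrow(table)), drop), , drop = FALSE]
  attr(out, "removed_subjects") <- drop
  out
}
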