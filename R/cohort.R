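#' Declare a synthetic subgroup archetype
#'
#' An archetype is a latent subgroup planted in the synthetic cohort. It is
#' defined by a conjunctive threshold rule over declared features; members
#' receive an additional log-odds shift in the case-generating model. The
#' archetypes play the role of the ground-truth subgroup structure that the
#' SHAP-clustering stage is expected to rediscover.
#'
#' @param id integer archetype identifier (> 0; 0 is reserved for background).
#' @param rule list of conditions, each `list(feature=, op=, threshold=)` with
#'   `op` one of `"<="`, `">"`.
#' @param risk_shift log-odds added to the linear predictor for members.
#' @param prevalence target fraction of the population belonging to the
#'   archetype.
#' @param margin member coercion margin: condition features of members are
#'   drawn beyond `threshold + margin` (op `>`) or `threshold - margin`
#'   (op `<=`), while background rejection uses the threshold itself, so the
#'   planted threshold is the unique boundary inside an empty band of this
#'   width (default 0).
#' @param reject_buffer non-members are rejection-sampled out of the rule
#'   region with every condition relaxed by this amount (default 0), so the
#'   conditional observation gap around each planted threshold has at least
#'   this width.
#' @param coerce_width optional width of a uniform coercion interval for
#'   continuous condition features: members are drawn uniformly on
#'   `(threshold + margin, threshold + margin + coerce_width]` (mirrored for
#'   `<=`) instead of from the truncated base distribution. A short interval
#'   keeps background observations from interleaving with member values, so
#'   decision-tree splits recover the planted threshold at data resolution.
#' @return an `archetype_spec` list.
#' @export
archetype_spec <- function(id, rule, risk_shift, prevalence, margin = 0,
                           reject_buffer = 0, coerce_width = NULL) {
  stopifnot(is.numeric(id), length(id) == 1L, id >= 1,
            is.list(rule), length(rule) >= 1L,
            is.finite(risk_shift),
            prevalence > 0, prevalence < 1, margin >= 0, reject_buffer >= 0,
            is.null(coerce_width) || coerce_width > 0)
  for (cond in rule) {
    stopifnot(is.character(cond$feature),
              cond$op %in% c("<=", ">"),
              is.finite(cond$threshold))
  }
  structure(list(id = as.integer(id), rule = rule,
                 risk_shift = risk_shift, prevalence = prevalence,
                 margin = margin, reject_buffer = reject_buffer,
                 coerce_width = coerce_width),
            class = "archetype_spec")
}

#' Declare a feature of the synthetic cohort
#'
#' @param name feature name.
#' @param kind `"continuous"` (normal), `"binary"` (Bernoulli, coded 0/1) or
#'   `"ordinal"` (integer levels `0:(n_levels-1)`).
#' @param effect log-odds per unit in the case-generating logistic model.
#' @param mean,sd continuous parameters.
#' @param p Bernoulli success probability.
#' @param n_levels,probs ordinal level count and level probabilities.
#' @param mixture optional `list(means, sds, weights)` giving a Gaussian
#'   mixture marginal for a continuous feature (used e.g. for the binormal
#'   AUC benchmark); overrides `mean`/`sd`.
#' @return a `feature_spec` list.
#' @export
feature_spec <- function(name, kind = c("continuous", "binary", "ordinal"),
                         effect = 0, mean = 0, sd = 1, p = 0.5,
                         n_levels = 4L, probs = NULL, mixture = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, is.finite(effect))
  if (kind == "continuous") stopifnot(sd > 0)
  if (!is.null(mixture)) {
    stopifnot(kind == "continuous",
              length(mixture$means) == length(mixture$sds),
              length(mixture$means) == length(mixture$weights),
              all(mixture$sds > 0), all(mixture$weights > 0))
    mixture$weights <- mixture$weights / sum(mixture$weights)
  }
  if (kind == "binary") stopifnot(p > 0, p < 1)
  if (kind == "ordinal") {
    n_levels <- as.integer(n_levels)
    stopifnot(n_levels >= 2L)
    if (is.null(probs)) probs <- rep(1 / n_levels, n_levels)
    stopifnot(length(probs) == n_levels, all(probs > 0))
  }
  structure(list(name = name, kind = kind, effect = effect, mean = mean,
                 sd = sd, p = p, n_levels = n_levels, probs = probs,
                 mixture = mixture),
            class = "feature_spec")
}

#' Assemble a synthetic cohort configuration
#'
#' Defaults mirror the study design being emulated: roughly balanced
#' case-control sampling and a 0-5 year assessment-to-index window for the
#' discovery population (the holdout population uses a 5-11 year window).
#'
#' @param n_cases,n_controls subject counts (the generator produces exactly
#'   `n_cases + n_controls` rows; case status itself is drawn from the
#'   calibrated logistic model).
#' @param features list of [feature_spec()] objects.
#' @param archetypes list of [archetype_spec()] objects; prevalences must sum
#'   to at most 1, the remainder is unstructured background.
#' @param missing_rate scalar or named per-feature missing-completely-at-random
#'   rate in \[0, 1\].
#' @param assessment_to_index_years length-2 interval `(lo, hi]` (years) for
#'   the gap between assessment and index date.
#' @param seed integer seed controlling all generation randomness.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_cases = 19120L, n_controls = 19252L,
                          features, archetypes = list(),
                          missing_rate = 0,
                          assessment_to_index_years = c(0, 5),
                          seed = 1L) {
  stopifnot(n_cases > 0, n_controls > 0, length(features) >= 1L)
  fnames <- vapply(features, function(f) f$name, character(1))
  stopifnot(!anyDuplicated(fnames))
  if (length(archetypes)) {
    prev <- vapply(archetypes, function(a) a$prevalence, numeric(1))
    stopifnot(sum(prev) <= 1)
    for (a in archetypes) {
      used <- vapply(a$rule, function(cond) cond$feature, character(1))
      if (!all(used %in% fnames))
        stop("archetype ", a$id, " references undeclared features: ",
             paste(setdiff(used, fnames), collapse = ", "))
    }
  }
  if (length(missing_rate) == 1L && is.null(names(missing_rate)))
    missing_rate <- stats::setNames(rep(missing_rate, length(fnames)), fnames)
  stopifnot(all(missing_rate >= 0), all(missing_rate <= 1),
            all(names(missing_rate) %in% fnames))
  w <- assessment_to_index_years
  stopifnot(length(w) == 2L, w[1] >= 0, w[1] < w[2])
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 features = features, archetypes = archetypes,
                 missing_rate = missing_rate,
                 assessment_to_index_years = w,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

DAYS_PER_YEAR <- 365L

rule_satisfied <- function(rule, X, relax = 0) {
  ok <- rep(TRUE, nrow(X))
  for (cond in rule) {
    v <- X[[cond$feature]]
    hit <- if (cond$op == "<=") v <= cond$threshold + relax
           else v > cond$threshold - relax
    hit[is.na(hit)] <- FALSE
    ok <- ok & hit
  }
  ok
}

first_match_archetype <- function(archetypes, X) {
  lab <- integer(nrow(X))
  for (a in archetypes) {
    hit <- rule_satisfied(a$rule, X)
    lab[lab == 0L & hit] <- a$id
  }
  lab
}

# Draw from the base distribution of one feature, truncated to one side of a
# threshold (used to coerce archetype members into their rule region).
draw_feature <- function(fs, n, op = NULL, threshold = NULL) {
  if (is.null(op)) {
    if (!is.null(fs$mixture)) {
      comp <- sample.int(length(fs$mixture$weights), n, replace = TRUE,
                         prob = fs$mixture$weights)
      return(stats::rnorm(n, fs$mixture$means[comp], fs$mixture$sds[comp]))
    }
    return(switch(fs$kind,
      continuous = stats::rnorm(n, fs$mean, fs$sd),
      binary = stats::rbinom(n, 1L, fs$p),
      ordinal = sample(0:(fs$n_levels - 1L), n, replace = TRUE,
                       prob = fs$probs)))
  }
  if (!is.null(fs$mixture))
    stop("archetype conditions on mixture features are not supported")
  if (fs$kind == "continuous") {
    pt <- stats::pnorm(threshold, fs$mean, fs$sd)
    u <- if (op == "<=") stats::runif(n, 0, pt) else stats::runif(n, pt, 1)
    return(stats::qnorm(u, fs$mean, fs$sd))
  }
  # discrete kinds: sample from the admissible levels
  lev <- if (fs$kind == "binary") 0:1 else 0:(fs$n_levels - 1L)
  pr <- if (fs$kind == "binary") c(1 - fs$p, fs$p) else fs$probs
  keep <- if (op == "<=") lev <= threshold else lev > threshold
  if (!any(keep)) stop("archetype condition unsatisfiable for feature ", fs$name)
  lev <- lev[keep]; pr <- pr[keep]
  if (length(lev) == 1L) rep(lev, n) else sample(lev, n, TRUE, prob = pr)
}

calibrate_intercept <- function(eta, target, tol_frac = 0.01, max_iter = 100L) {
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0)
    stop("infeasible intercept calibration: effects force prevalence outside ",
         "the attainable range for target ", signif(target, 4))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) <= tol_frac * target) return(mid)
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  stop("intercept calibration did not converge within ", max_iter,
       " bisection steps")
}

#' Generate a synthetic case-control cohort
#'
#' Subjects receive mixed-type features, a latent archetype label (by
#' prevalence-driven coercion into the archetype's rule region; background
#' subjects are rejection-sampled out of every rule region so membership is
#' noiseless), a case label drawn from a logistic model whose intercept is
#' calibrated by bisection to the configured case fraction, dates (integer
#' days; index minus assessment falls in the configured window), and MCAR
#' missingness. The latent label recorded in `true_archetype` is the first
#' archetype in declaration order whose rule the final feature values satisfy.
#'
#' @param config a [cohort_config()].
#' @return a `data.frame` of class `cohort_table` with columns `subject_id`,
#'   `is_case`, `assessment_date`, `index_date`, `obs_start_date`,
#'   `obs_end_date`, `death_date`, `true_archetype`, `true_risk` and one
#'   column per feature; feature metadata in `attr(, "features")`.
#' @export
generate_subjects <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  target <- config$n_cases / n
  fs <- config$features
  fnames <- vapply(fs, function(f) f$name, character(1))

  X <- as.data.frame(lapply(fs, function(f) draw_feature(f, n)))
  names(X) <- fnames

  arch <- config$archetypes
  assigned <- integer(n)
  if (length(arch)) {
    prev <- vapply(arch, function(a) a$prevalence, numeric(1))
    assigned <- sample(c(0L, vapply(arch, `[[`, integer(1), "id")), n,
                       replace = TRUE, prob = c(1 - sum(prev), prev))
    for (a in arch) {
      rows <- which(assigned == a$id)
      for (cond in a$rule) {
        j <- match(cond$feature, fnames)
        thr <- cond$threshold + if (cond$op == ">") a$margin else -a$margin
        X[rows, j] <- if (!is.null(a$coerce_width) &&
                            fs[[j]]$kind == "continuous") {
          if (cond$op == ">") stats::runif(length(rows), thr,
                                           thr + a$coerce_width)
          else stats::runif(length(rows), thr - a$coerce_width, thr)
        } else draw_feature(fs[[j]], length(rows), cond$op, thr)
      }
    }
    # Two cleanup passes keep planted membership noiseless and the planted
    # thresholds identifiable: (a) any subject accidentally inside the rule
    # region of an archetype other than its own is redrawn on that rule's
    # features (excluding features of its own rule); (b) when an archetype
    # has a positive margin, non-members are redrawn out of the band from
    # the threshold to the midpoint of the member coercion interval on each
    # condition feature, so the band is empty in the population, no
    # non-member interleaves at the member edge, and any separating split
    # lands inside the band.
    own_feats <- stats::setNames(lapply(arch, function(a)
      vapply(a$rule, function(cond) cond$feature, character(1))),
      vapply(arch, `[[`, integer(1), "id"))
    is_protected <- function(rows, feat) {
      vapply(rows, function(r) {
        assigned[r] > 0L && feat %in% own_feats[[as.character(assigned[r])]]
      }, logical(1))
    }
    for (attempt in seq_len(20L)) {
      any_bad <- FALSE
      for (a in arch) {
        hit <- rule_satisfied(a$rule, X, relax = a$reject_buffer)
        rows <- which(hit & assigned != a$id)
        if (length(rows)) {
          any_bad <- TRUE
          for (cond in a$rule) {
            j <- match(cond$feature, fnames)
            redraw <- rows[!is_protected(rows, cond$feature)]
            X[redraw, j] <- draw_feature(fs[[j]], length(redraw))
          }
        }
        excl <- a$margin +
          if (!is.null(a$coerce_width)) a$coerce_width / 2 else 0
        if (excl > 0) {
          for (cond in a$rule) {
            j <- match(cond$feature, fnames)
            v <- X[[j]]
            in_band <- if (cond$op == ">")
              v > cond$threshold & v <= cond$threshold + excl
            else v >= cond$threshold - excl & v < cond$threshold
            rows2 <- which(in_band & assigned != a$id)
            rows2 <- rows2[!is_protected(rows2, cond$feature)]
            if (length(rows2)) {
              any_bad <- TRUE
              X[rows2, j] <- draw_feature(fs[[j]], length(rows2))
            }
          }
        }
      }
      if (!any_bad) break
    }
    assigned <- first_match_archetype(arch, X)
  }

  effects <- vapply(fs, function(f) f$effect, numeric(1))
  eta <- as.numeric(as.matrix(X) %*% effects)
  if (length(arch)) {
    shift <- stats::setNames(vapply(arch, `[[`, numeric(1), "risk_shift"),
                             vapply(arch, `[[`, integer(1), "id"))
    eta <- eta + ifelse(assigned == 0L, 0, shift[as.character(assigned)])
  }
  b0 <- calibrate_intercept(eta, target)
  p <- stats::plogis(b0 + eta)
  is_case <- stats::rbinom(n, 1L, p)

  w <- config$assessment_to_index_years
  assessment <- sample(0:(4L * DAYS_PER_YEAR), n, replace = TRUE)
  gap <- sample((floor(w[1] * DAYS_PER_YEAR) + 1L):floor(w[2] * DAYS_PER_YEAR),
                n, replace = TRUE)
  index <- assessment + gap

  out <- data.frame(subject_id = sprintf("S%06d", seq_len(n)),
                    is_case = is_case,
                    assessment_date = assessment,
                    index_date = index,
                    obs_start_date = assessment - 10L * DAYS_PER_YEAR,
                    obs_end_date = index + DAYS_PER_YEAR,
                    death_date = NA_integer_,
                    true_archetype = assigned,
                    true_risk = p,
                    stringsAsFactors = FALSE)
  for (j in seq_along(fnames)) {
    v <- X[[j]]
    mr <- config$missing_rate[fnames[j]]
    if (!is.na(mr) && mr > 0) v[stats::runif(n) < mr] <- NA
    out[[fnames[j]]] <- v
  }
  attr(out, "features") <- fs
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Feature columns of a cohort table
#' @param cohort a `cohort_table`.
#' @return data.frame of feature columns only.
#' @export
cohort_features <- function(cohort) {
  fnames <- vapply(attr(cohort, "features"), function(f) f$name, character(1))
  as.data.frame(cohort[, fnames, drop = FALSE])
}

#' Simulate longitudinal biomarker and medication records
#'
#' Continuous biomarkers are emitted as monthly values over the five years
#' before each subject's index date, generated as a subject-level mean plus
#' stationary AR(1) noise. Medications are emitted as prescription events with
#' case/control-specific yearly probabilities. All record dates are strictly
#' before the index date.
#'
#' @param cohort a `cohort_table` with index dates.
#' @param biomarker_specs list of `list(code, mean, between_sd, ar_rho, ar_sd)`.
#' @param med_specs list of `list(code, p_case, p_control)`; probabilities may
#'   be scalars or length-5 vectors (years -1 .. -5 before index).
#' @param seed integer seed.
#' @return long-format `data.frame` (subject_id, code, value, date).
#' @export
simulate_longitudinal <- function(cohort, biomarker_specs = list(),
                                  med_specs = list(), seed = 1L) {
  stopifnot(all(c("subject_id", "index_date", "is_case") %in% names(cohort)))
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  if (!length(biomarker_specs) && !length(med_specs))
    return(data.frame(subject_id = character(0), code = character(0),
                      value = numeric(0), date = integer(0)))
  parts <- list()
  months <- 0:59                       # monthly sampling, ~5y of records
  offsets <- months * 30L + 15L        # days before index, mid-month
  for (bs in biomarker_specs) {
    subj_mean <- bs$mean + stats::rnorm(n, 0, bs$between_sd)
    vals <- matrix(0, n, length(months))
    if (bs$ar_sd > 0) {
      rho <- bs$ar_rho
      e <- stats::rnorm(n, 0, bs$ar_sd / sqrt(max(1 - rho^2, 1e-12)))
      for (m in seq_along(months)) {
        vals[, m] <- e
        e <- rho * e + stats::rnorm(n, 0, bs$ar_sd)
      }
    }
    parts[[length(parts) + 1L]] <- data.frame(
      subject_id = rep(cohort$subject_id, each = length(months)),
      code = bs$code,
      value = as.numeric(t(subj_mean + vals)),
      date = rep(cohort$index_date, each = length(months)) - offsets)
  }
  for (ms in med_specs) {
    pc <- rep_len(ms$p_case, 5L)
    pk <- rep_len(ms$p_control, 5L)
    for (yr in 1:5) {
      p <- ifelse(cohort$is_case == 1L, pc[yr], pk[yr])
      ev <- which(stats::runif(n) < p)
      if (!length(ev)) next
      day_in_year <- sample(seq_len(DAYS_PER_YEAR), length(ev), replace = TRUE)
      parts[[length(parts) + 1L]] <- data.frame(
        subject_id = cohort$subject_id[ev],
        code = ms$code,
        value = 1,
        date = cohort$index_date[ev] - ((yr - 1L) * DAYS_PER_YEAR +
                                          day_in_year))
    }
  }
  rec <- do.call(rbind, parts)
  rownames(rec) <- NULL
  rec
}

#' Date-match controls to cases
#'
#' Each case is matched (without replacement, uniformly at random among the
#' eligible pool under the supplied seed) to a control that has observational
#' coverage and no registered death over the five years preceding the case's
#' diagnosis date; the matched control inherits that date as its index date.
#'
#' @param cases `cohort_table` of cases (index_date = diagnosis date).
#' @param control_pool `cohort_table` of candidate controls with
#'   `obs_start_date`, `obs_end_date`, `death_date`.
#' @param seed integer seed breaking ties among equally eligible controls.
#' @return the matched controls with assigned `index_date` and a
#'   `matched_case` column.
#' @export
match_controls <- function(cases, control_pool, seed = 1L) {
  stopifnot(nrow(control_pool) >= nrow(cases))
  set.seed(as.integer(seed))
  available <- rep(TRUE, nrow(control_pool))
  picked <- integer(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    idx <- cases$index_date[i]
    ok <- available &
      control_pool$obs_start_date <= idx - 5L * DAYS_PER_YEAR &
      control_pool$obs_end_date >= idx &
      (is.na(control_pool$death_date) |
         control_pool$death_date <= idx - 5L * DAYS_PER_YEAR |
         control_pool$death_date > idx)
    cand <- which(ok)
    if (!length(cand))
      stop("no eligible control for case ", cases$subject_id[i])
    picked[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    available[picked[i]] <- FALSE
  }
  out <- control_pool[picked, , drop = FALSE]
  out$index_date <- cases$index_date
  out$is_case <- 0L
  out$matched_case <- cases$subject_id
  rownames(out) <- NULL
  out
}

#' Split a cohort into discovery and holdout populations by time window
#'
#' Discovery subjects have an index date up to five years after assessment
#' (gap in `(0, 5]` years); holdout subjects fall in the `(5, 11]` year
#' window; everyone else is dropped. Windows are half-open below and closed
#' above, in integer days with a 365-day year.
#'
#' @param cohort a `cohort_table`.
#' @return list with `discovery`, `holdout` and `dropped` tables.
#' @export
split_populations <- function(cohort) {
  gap <- cohort$index_date - cohort$assessment_date
  disc <- gap > 0L & gap <= 5L * DAYS_PER_YEAR
  hold <- gap > 5L * DAYS_PER_YEAR & gap <= 11L * DAYS_PER_YEAR
  keep_attrs <- function(d) {
    attr(d, "features") <- attr(cohort, "features")
    class(d) <- class(cohort)
    d
  }
  list(discovery = keep_attrs(cohort[disc, , drop = FALSE]),
       holdout = keep_attrs(cohort[hold, , drop = FALSE]),
       dropped = keep_attrs(cohort[!disc & !hold, , drop = FALSE]))
}

#' Write / read a cohort as TSV (empty cell = missing)
#' @param cohort a `cohort_table`.
#' @param path file path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  d <- utils::read.delim(path, sep = "\t", na.strings = "",
                         stringsAsFactors = FALSE)
  class(d) <- c("cohort_table", "data.frame")
  d
}

#' Write longitudinal records as long-format TSV
#' @param records records data.frame.
#' @param path file path.
#' @export
write_records_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}
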