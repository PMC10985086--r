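test_that("winsorization clips to type-7 percentiles and is idempotent", {
  expect_equal(winsorize(c(5, 5, 5, 5)), c(5, 5, 5, 5))

  x <- as.numeric(1:100)
  out <- winsorize(x)
  # 20-line oracle: type-7 quantiles + clip
  q <- as.numeric(quantile(x, c(0.01, 0.99), type = 7))
  oracle <- pmin(pmax(x, q[1]), q[2])
  expect_equal(out, oracle)
  expect_equal(min(out), q[1])
  expect_equal(max(out), q[2])
  # near-idempotence: re-estimated percentiles of clipped data move inward
  # by at most an interpolation fraction of one observation spacing
  expect_lt(max(abs(winsorize(out) - out)), 0.02)

  # interior order preserved; missing entries pass through
  set.seed(1)
  y <- rnorm(200); y[c(3, 50)] <- NA
  wy <- winsorize(y)
  expect_true(all(is.na(wy[c(3, 50)])))
  inner <- !is.na(y) & y > quantile(y, 0.01, na.rm = TRUE) &
    y < quantile(y, 0.99, na.rm = TRUE)
  expect_equal(order(wy[inner]), order(y[inner]))

  expect_error(winsorize(c(NA_real_, NA_real_)), "non-missing")
})

test_that("yearly binning takes 11-month medians and binary medication flags", {
  cohort <- data.frame(subject_id = c("a", "b"), is_case = c(1L, 0L),
                       index_date = c(3650L, 3650L))
  rec <- data.frame(
    subject_id = c("a", "a", "a",   "a",          "a",        "b"),
    code       = c("crp", "crp", "crp", "crp",    "nsaid",    "crp"),
    value      = c(1, 2, 3,       99,             1,          7),
    # three values in year -1 beyond the excluded month; one inside it
    date       = c(3650L - 100L, 3650L - 200L, 3650L - 300L,
                   3650L - 15L,  3650L - 100L, 3650L - 400L))
  out <- bin_yearly(rec, cohort, med_codes = "nsaid")
  expect_equal(out$crp_pre1y, c(2, NA))      # median{1,2,3}; 99 excluded
  expect_equal(out$crp_pre2y, c(NA, 7))
  expect_equal(out$nsaid_pre1y, c(1, 0))
  expect_equal(out$nsaid_pre2y, c(0, 0))

  # boundary arithmetic: the excluded month is the 30 days adjacent to the
  # index-date side of each year bin
  rec2 <- data.frame(subject_id = "a", code = "crp", value = 5,
                     date = 3650L - 30L)           # offset exactly 30
  expect_true(is.na(bin_yearly(rec2, cohort[1, ])$crp_pre1y))
  rec3 <- data.frame(subject_id = "a", code = "crp", value = 5,
                     date = 3650L - 31L)           # first included day
  expect_equal(bin_yearly(rec3, cohort[1, ])$crp_pre1y, 5)
  # medication events inside the excluded month still count for the flag
  rec4 <- data.frame(subject_id = "a", code = "nsaid", value = 1,
                     date = 3650L - 10L)
  expect_equal(bin_yearly(rec4, cohort[1, ], med_codes = "nsaid")$nsaid_pre1y,
               1)
})

test_that("feature filters fire on missingness and near-zero variance only", {
  n <- 100L
  tab <- data.frame(
    too_missing = c(rep(NA_real_, 51), rnorm(49)),
    constant = rep(3, n),
    balanced_binary = rep(c(0, 1), 50),
    fine = rnorm(n))
  res <- filter_features(tab, train_rows = seq_len(n))
  expect_setequal(names(res$table), c("balanced_binary", "fine"))
  expect_equal(res$exclusions$reason[res$exclusions$feature == "too_missing"],
               "missingness")
  expect_equal(res$exclusions$reason[res$exclusions$feature == "constant"],
               "near_zero_variance")
  expect_error(filter_features(tab["constant"], seq_len(n)), "all features")
})

test_that("filter and imputation decisions depend on training rows only", {
  set.seed(2)
  n <- 120L
  tab <- data.frame(a = rnorm(n), b = rnorm(n))
  tab$a[sample(n, 30)] <- NA
  train <- 1:80
  model <- fit_impute(tab, train)
  base_excl <- filter_features(tab, train)$exclusions
  for (rep in 1:10) {
    perturbed <- tab
    test_rows <- 81:120
    perturbed$a[test_rows] <- rnorm(40, sd = 50)
    perturbed$b[test_rows] <- rnorm(40, sd = 50)
    expect_identical(fit_impute(perturbed, train)$medians, model$medians)
    expect_identical(filter_features(perturbed, train)$exclusions, base_excl)
  }
})

test_that("median imputation fills every cell from training medians", {
  tab <- data.frame(x = c(1, 2, 100, NA, NA))
  model <- fit_impute(tab, train_rows = 1:3)
  expect_equal(unname(model$medians["x"]), 2)
  filled <- apply_impute(model, tab)
  expect_equal(sum(is.na(filled)), 0L)
  expect_equal(filled$x[4:5], c(2, 2))
  # fold isolation: different training rows give different medians
  m2 <- fit_impute(data.frame(x = c(1, 2, 100, 50, 60)), train_rows = 3:5)
  expect_false(m2$medians["x"] == model$medians["x"])
  expect_error(fit_impute(data.frame(x = c(NA_real_, 1)), train_rows = 1L),
               "no non-missing")
})

test_that("omics normalization transforms metabolites and filters NPX outliers", {
  met <- data.frame(conc = c(9, 16), ratio = c(0.4, 0.8))
  out <- normalize_omics(met, "metabolite", absolute = "conc")
  expect_equal(out$conc, c(3, 4))
  expect_equal(out$ratio, c(0.4, 0.8))
  expect_error(normalize_omics(data.frame(conc = -1), "metabolite"),
               "negative")

  set.seed(3)
  npx <- as.data.frame(matrix(rnorm(1000 * 5), 1000, 5))
  npx[500, ] <- npx[500, ] + 100       # one extreme-mean subject
  filtered <- normalize_omics(npx, "protein")
  dropped <- attr(filtered, "removed_subjects")
  expect_true(500 %in% dropped)
  # percentile oracle: subjects outside the [0.2, 99.8] percentile band
  m <- rowMeans(as.matrix(npx))
  q <- quantile(m, c(0.002, 0.998), type = 7)
  expect_setequal(dropped, which(m < q[1] | m > q[2]))
})
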