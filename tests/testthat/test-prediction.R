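test_that("overlap exclusion removes exactly the co-eluting compounds", {
  ds <- noiseless_dataset(n_compounds = 10L)
  X <- ds$retention$values
  # window 0: only the target itself is excluded
  expect_length(exclude_overlapping(X, "cmp005", 0), 9L)
  # force a co-elution of cmp002 with cmp001 in a single run
  X2 <- X
  X2[3, 2] <- X2[3, 1] + 0.05
  cal <- exclude_overlapping(X2, "cmp001", rt_window = 0.2)
  expect_false("cmp002" %in% cal)
  # brute-force check: every excluded compound violates the window somewhere
  excluded <- setdiff(colnames(X2), c(cal, "cmp001"))
  for (e in excluded) {
    expect_true(any(abs(X2[, e] - X2[, "cmp001"]) < 0.2))
  }
  expect_error(exclude_overlapping(X, "nope", 0.2), "not found")
  expect_error(exclude_overlapping(X, "cmp001", -1), "non-negative")
})

test_that("overlap exclusion is symmetric", {
  ds <- default_dataset(n_compounds = 25L, seed = 6L)
  X <- ds$retention$values
  for (a in c("cmp003", "cmp010", "cmp017")) {
    cal_a <- exclude_overlapping(X, a, 0.3)
    for (b in setdiff(colnames(X), a)) {
      cal_b <- exclude_overlapping(X, b, 0.3)
      expect_equal(b %in% cal_a, a %in% cal_b)
    }
  }
})

test_that("PCR is exact on noiseless designed data and monotone in components", {
  ds <- noiseless_dataset(n_compounds = 20L)
  X <- ds$retention$values
  cal <- setdiff(colnames(X), "cmp010")
  m5 <- fit_pcr(X, "cmp010", cal, n_components = 5, cv = FALSE)
  expect_lt(m5$rrv_auto, 1e-8)
  rrv <- vapply(1:5, function(k) {
    fit_pcr(X, "cmp010", cal, k, cv = FALSE)$rrv_auto
  }, numeric(1))
  expect_true(all(diff(rrv) <= 1e-12))
  expect_gt(rrv[1], rrv[2])      # strictly better with a second component
  # the designed structure has rank 5: a sixth component does not exist
  expect_error(fit_pcr(X, "cmp010", cal, 6, cv = FALSE), "rank")
})

test_that("PCR guards its preconditions", {
  ds <- default_dataset(n_compounds = 8L, seed = 2L)
  X <- ds$retention$values
  cal <- setdiff(colnames(X), "cmp004")
  expect_error(fit_pcr(X, "cmp004", cal, 0), "at least 1")
  expect_error(fit_pcr(X, "cmp004", character(0), 2), "empty calibrant")
  expect_error(fit_pcr(X, "cmp004", colnames(X), 2), "must not be among")
  expect_error(fit_pcr(X, "cmp004", cal, 20), "exceeds")
})

test_that("PLS matches PCR on noiseless data and refuses zero components", {
  ds <- noiseless_dataset(n_compounds = 20L)
  X <- ds$retention$values
  cal <- setdiff(colnames(X), "cmp010")
  m <- fit_pls(X, "cmp010", cal, n_components = 5, cv = FALSE)
  expect_lt(m$rrv_auto, 1e-8)
  expect_error(fit_pls(X, "cmp010", cal, 0), "at least 1")
})

test_that("PLS agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  ds <- default_dataset(n_compounds = 12L, seed = 13L)
  X <- ds$retention$values
  cal <- setdiff(colnames(X), "cmp006")
  ours <- fit_pls(X, "cmp006", cal, n_components = 3, cv = FALSE)
  ref <- mixOmics::pls(X[, cal], X[, "cmp006"], ncomp = 3,
                       mode = "regression", scale = FALSE)
  ref_pred <- predict(ref, X[, cal])$predict[, 1, 3]
  expect_equal(unname(ours$fitted), unname(ref_pred), tolerance = 1e-6)
})

test_that("PCR and PLS cross-validated errors are practically the same", {
  # each method at its own CV-selected component count: a PLS component
  # carries more fitting capacity than a principal component, so matched
  # counts would compare the methods at unmatched complexity
  ds <- default_dataset(n_compounds = 98L, seed = 44L)
  X <- ds$retention$values
  close_enough <- logical(0)
  for (target in colnames(X)[seq(1, 98, by = 7)]) {
    cal <- exclude_overlapping(X, target, 0.2)
    pcr_cv <- min(vapply(1:8, function(k)
      fit_pcr(X, target, cal, k)$rrv_cv, numeric(1)))
    pls_cv <- min(vapply(1:8, function(k)
      fit_pls(X, target, cal, k)$rrv_cv, numeric(1)))
    close_enough <- c(close_enough,
                      abs(pcr_cv - pls_cv) <= 0.2 * max(pcr_cv, pls_cv))
  }
  expect_gte(mean(close_enough), 0.9)
})

test_that("cross-validation is never more optimistic than auto-prediction", {
  ds <- default_dataset(n_compounds = 20L, seed = 5L)
  X <- ds$retention$values
  diffs <- vapply(colnames(X), function(target) {
    cal <- exclude_overlapping(X, target, 0.2)
    m <- fit_pcr(X, target, cal, min(6, length(cal)))
    m$rrv_cv - m$rrv_auto
  }, numeric(1))
  expect_gt(mean(diffs), 0)             # optimism holds in expectation
  expect_gt(mean(diffs >= 0), 0.9)      # and for nearly every compound
})

test_that("level prediction nails strong terms and degrades on absent ones", {
  ds <- noiseless_dataset(n_compounds = 20L)
  lp <- predict_design_levels(ds$retention, ds$design, 1:5, cv = FALSE)
  for (term in c("pH", "temperature", "pH^2")) {
    expect_lt(min(lp$rmsec[term, c("k3", "k4", "k5")]),
              1e-6 * lp$term_sd[term])
  }
  # RMSEC non-increasing in component count, every term
  expect_true(all(apply(lp$rmsec, 1, function(r) all(diff(r) <= 1e-10))))
})

test_that("RMSECV of near-zero terms stays at the column SD", {
  ds <- default_dataset(n_compounds = 40L, seed = 27L)
  lp <- predict_design_levels(ds$retention, ds$design, 1:8)
  for (term in c("temperature^2", "pH:temperature")) {
    expect_true(all(lp$rmsecv[term, ] >= 0.8 * lp$term_sd[term]))
  }
  expect_true(all(lp$rmsecv >= 0))
})

test_that("center replicates are predicted at coded zero", {
  ds <- default_dataset(n_compounds = 40L, seed = 33L)
  lp <- predict_design_levels(ds$retention, ds$design, 1:6)
  reps <- ds$design$is_replicate
  k6 <- which(lp$component_range == 6)
  for (term in c("pH", "temperature")) {
    pred <- lp$cv_pred[[term]][reps, k6]
    expect_true(all(abs(pred) <= 3 * lp$rmsecv[term, k6]))
  }
})

test_that("the residual-variance table reproduces the MLR-vs-PCR contrast", {
  # no latent factor, no noise: everything predicts perfectly
  ds0 <- noiseless_dataset(n_compounds = 15L)
  tab0 <- residual_variance_comparison(ds0$retention, ds0$design,
                                       n_components = 5, cv = FALSE)
  expect_lt(max(tab0$mlr_auto), 1e-10)
  expect_lt(max(tab0$pcr_auto, na.rm = TRUE), 1e-10)

  # one latent uncontrolled factor: PCR absorbs it, MLR cannot
  ds1 <- default_dataset(n_compounds = 40L, seed = 61L)
  tab1 <- residual_variance_comparison(ds1$retention, ds1$design,
                                       n_components = 6, cv = FALSE)
  expect_lt(median(tab1$pcr_auto, na.rm = TRUE), median(tab1$mlr_auto))
})
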