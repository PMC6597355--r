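test_that("imputation leaves complete data untouched and fills all gaps", {
  tbl <- exact_linear_table()
  expect_identical(impute_missing(tbl), dplyr::mutate(
    tbl, qaly = accrue_qalys(utility_baseline, utility_followup,
                             trial_window_years())))

  holed <- tbl
  holed$cost_followup[c(2, 7)] <- NA
  holed$utility_followup[5] <- NA
  holed$qaly[5] <- NA
  done <- impute_missing(holed)
  expect_false(anyNA(done))
  # observed values never altered
  obs <- setdiff(seq_len(nrow(tbl)), c(2, 7))
  expect_equal(done$cost_followup[obs], tbl$cost_followup[obs])
})

test_that("regression imputation recovers an exact linear mechanism", {
  # follow-up outcomes are exact linear functions of the predictors, so the
  # conditional-regression prediction must reproduce the deleted value
  tbl <- exact_linear_table()
  truth_cost <- tbl$cost_followup[3]
  truth_util <- tbl$utility_followup[6]
  tbl$cost_followup[3] <- NA
  tbl$utility_followup[6] <- NA
  tbl$qaly[6] <- NA
  done <- impute_missing(tbl)
  expect_equal(done$cost_followup[3], truth_cost, tolerance = 1e-8)
  expect_equal(done$utility_followup[6], truth_util, tolerance = 1e-8)
  expect_equal(done$qaly[6],
               accrue_qalys(tbl$utility_baseline[6], truth_util,
                            trial_window_years()),
               tolerance = 1e-8)
})

test_that("imputation fails informatively when a predictor is all-missing", {
  tbl <- exact_linear_table()
  tbl$cost_followup[1] <- NA
  tbl$cost_baseline <- NA
  expect_error(impute_missing(tbl), "cost_baseline",
               class = "ptsdcea_imputation_error")
})

test_that("a pure additive arm effect is recovered exactly", {
  tbl <- exact_linear_table()
  # arms differ only by the built-in +80 cost / +0.05 utility shifts plus
  # covariate effects the model adjusts away
  expect_equal(adjust_difference(tbl, "cost"), 80, tolerance = 1e-8)
  tbl2 <- tbl
  tbl2$cost_followup <- tbl2$cost_followup + 100 * (tbl2$arm == "treatment")
  expect_equal(adjust_difference(tbl2, "cost"), 180, tolerance = 1e-8)
})

test_that("with balanced covariates the adjusted diff is the diff of means", {
  set.seed(23)
  n <- 40
  covars <- tibble::tibble(
    age = rep(sample(8:17, n / 2, replace = TRUE), 2),
    gender = factor(rep(sample(c("female", "male"), n / 2, replace = TRUE),
                        2), levels = c("female", "male")),
    cost_baseline = rep(stats::runif(n / 2, 0, 500), 2),
    utility_baseline = rep(stats::runif(n / 2, 0.6, 0.9), 2))
  tbl <- dplyr::mutate(
    covars,
    id = sprintf("P%d", seq_len(n)),
    arm = factor(rep(c("treatment", "control"), each = n / 2),
                 levels = c("treatment", "control")),
    followup_missing = FALSE,
    cost_followup = stats::rnorm(n, 300, 50),
    utility_followup = stats::runif(n, 0.6, 0.95),
    qaly = accrue_qalys(utility_baseline, utility_followup,
                        trial_window_years()))
  plain_diff <- mean(tbl$cost_followup[tbl$arm == "treatment"]) -
    mean(tbl$cost_followup[tbl$arm == "control"])
  expect_equal(adjust_difference(tbl, "cost"), plain_diff,
               tolerance = 1e-8)
})

test_that("the published imputed QALY means give a difference of .0156", {
  # arms with exactly the published mean QALYs and mirrored covariates
  n <- 10
  qalys_t <- 0.1979 + seq(-0.01, 0.01, length.out = n)
  qalys_c <- 0.1823 + seq(-0.01, 0.01, length.out = n)
  tbl <- tibble::tibble(
    id = sprintf("P%d", 1:(2 * n)),
    arm = factor(rep(c("treatment", "control"), each = n),
                 levels = c("treatment", "control")),
    age = rep(10:19, 2),
    gender = factor(rep(c("female", "male"), n),
                    levels = c("female", "male")),
    followup_missing = FALSE,
    cost_baseline = rep(c(110, 180, 140, 300, 220, 130, 260, 150, 240, 170), 2),
    utility_baseline = rep(c(0.70, 0.73, 0.71, 0.76, 0.74, 0.70, 0.75, 0.72, 0.76, 0.71), 2),
    cost_followup = rep(200, 2 * n),
    utility_followup = 0.9,
    qaly = c(qalys_t, qalys_c))
  expect_equal(mean(qalys_t) - mean(qalys_c), 0.0156, tolerance = 1e-12)
  expect_equal(adjust_difference(tbl, "qaly"), 0.0156, tolerance = 1e-8)
})

test_that("ICERs reproduce the published trial-horizon ratios", {
  imp <- compute_icer(1346, 0.0095)
  expect_equal(round_gbp(imp$icer), 141684)
  expect_equal(imp$quadrant, "NE")
  cc <- compute_icer(1284, 0.0103)
  expect_equal(round_gbp(cc$icer), 124660)
})

test_that("the cost-effectiveness plane quadrants classify dominance", {
  expect_equal(compute_icer(-10, 0.01)$quadrant, "dominant")
  expect_equal(compute_icer(10, -0.01)$quadrant, "dominated")
  expect_equal(compute_icer(-10, -0.01)$quadrant, "SW")
  expect_warning(res <- compute_icer(100, 0),
                 class = "ptsdcea_undefined_icer")
  expect_true(is.na(res$icer))
})

test_that("the ICER is scale-invariant and sign-consistent", {
  set.seed(41)
  for (i in 1:50) {
    dc <- stats::runif(1, -2000, 2000)
    de <- stats::runif(1, -0.05, 0.05)
    if (de == 0) next
    r <- compute_icer(dc, de)
    k <- stats::runif(1, 0.1, 10)
    expect_equal(compute_icer(k * dc, k * de)$icer, r$icer,
                 tolerance = 1e-10)
    expect_equal(sign(r$icer), sign(dc) * sign(de))
  }
})

test_that("complete-case and imputed analyses coincide without missingness", {
  rec <- generate_cohort(cohort_config(seed = 13, followup_missing_prob = 0))
  a <- trial_cua(rec, analysis = "imputed")
  b <- trial_cua(rec, analysis = "complete_case")
  expect_equal(glance(a)[c("cost_diff", "qaly_diff", "icer")],
               glance(b)[c("cost_diff", "qaly_diff", "icer")])
})

test_that("trial_cua returns tidy-able results on a realistic cohort", {
  rec <- generate_cohort(cohort_config(seed = 101))
  res <- trial_cua(rec, seed = 2)
  expect_s3_class(res, "cua_result")
  td <- tidy(res)
  expect_true(all(c("cost_diff", "qaly_diff", "icer") %in% td$term))
  gl <- glance(res)
  expect_equal(gl$analysis_set, "imputed")
  expect_false(anyNA(res$table))
})
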