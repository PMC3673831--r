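test_that("the spirometric COPD definition and severity bands apply strictly", {
  r <- classify_copd(c(85, 100, 45, 85, 60, 25),
                     c(0.65, 0.70, 0.60, 0.72, 0.55, 0.40))
  expect_equal(r$copd, c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(r$severity, c("mild", "none", "severe", "none", "moderate",
                             "severe"))
  expect_equal(r$below_grading_range, c(FALSE, FALSE, FALSE, FALSE, FALSE,
                                        TRUE))
  expect_error(classify_copd(-5, 0.6), class = "copdct_input_error")
  expect_error(classify_copd(90, 1.5), class = "copdct_input_error")
})

test_that("logistic fitting recovers null effects and rejects bad input", {
  df <- noise_cohort(n = 5000, seed = 3)
  fit <- fit_logistic(df, c("age", "bmi"))
  z <- fit$coefficients[-1] / fit$se[-1]
  expect_true(all(abs(z) < 3))

  df0 <- df; df0$in950[5] <- 0
  expect_error(fit_logistic(df0, c("age", "log_in950")),
               class = "copdct_precondition_error")
  expect_error(fit_logistic(df[1:10, ], "age"),
               class = "copdct_precondition_error")
  df1 <- df[1:100, ]; df1$copd <- TRUE
  expect_error(fit_logistic(df1, "age"),
               class = "copdct_degenerate_input_error")
  # perfectly separable covariate
  dfs <- df[1:200, ]
  dfs$age <- ifelse(dfs$copd, 70 + runif(200), 55 + runif(200))
  expect_error(fit_logistic(dfs, "age"), class = "copdct_separation_error")
  # missing covariates are rejected, not imputed
  dfm <- df[1:100, ]; dfm$bmi[7] <- NA
  expect_error(fit_logistic(dfm, c("age", "bmi")),
               class = "copdct_input_error")
})

test_that("the C-statistic matches enumeration, examples and pROC", {
  expect_equal(c_statistic(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(c_statistic(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1.0)
  expect_equal(c_statistic(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(c_statistic(1:4, c(1, 1, 1, 1)),
               class = "copdct_degenerate_input_error")
  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(rnorm(n), sample(0:2, 1))  # induce ties
    expect_equal(c_statistic(p, y), c_statistic_bruteforce(p, y))
  }
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- rbinom(150, 1, 0.4); p <- rnorm(150, y)
  expect_equal(c_statistic(p, y),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))))
})

test_that("the DeLong interval brackets the estimate and matches pROC", {
  set.seed(13)
  y <- rbinom(200, 1, 0.4); p <- rnorm(200, y)
  ci <- c_statistic_ci(p, y)
  expect_lte(ci$low, ci$c)
  expect_gte(ci$high, ci$c)
  # perfect separation truncates at 1
  ysep <- rep(c(0, 1), each = 30)
  ci_sep <- c_statistic_ci(c(rnorm(30, 0), rnorm(30, 20)), ysep)
  expect_equal(ci_sep$high, 1.0)
  skip_if_not_installed("pROC")
  pci <- pROC::ci.auc(pROC::roc(y, p, quiet = TRUE), method = "delong")
  expect_equal(ci$low, as.numeric(pci[1]), tolerance = 1e-10)
  expect_equal(ci$high, as.numeric(pci[3]), tolerance = 1e-10)
})

test_that("DeLong intervals have near-nominal coverage", {
  delta <- sqrt(2) * qnorm(0.8)  # binormal model with true AUC 0.8
  set.seed(14)
  cover <- mean(replicate(600, {
    y <- rep(c(0, 1), each = 100)
    x <- rnorm(200) + delta * y
    ci <- c_statistic_ci(x, y)
    ci$low <= 0.8 && 0.8 <= ci$high
  }))
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})

test_that("the optimal-accuracy cutoff maximizes tp + tn", {
  oc <- optimal_cutoff(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(oc$table$tp + oc$table$tn, 3)
  # tie broken toward the lowest threshold: the sensitive side
  expect_lt(oc$threshold, 0.3)
  # separable risks: perfect accuracy
  ocs <- optimal_cutoff(c(1, 2, 3, 8, 9), c(0, 0, 0, 1, 1))
  expect_equal(ocs$table$acc, 100)
  expect_gt(ocs$threshold, 3); expect_lt(ocs$threshold, 8)
  # constant risks: classify everyone the majority way
  occ <- optimal_cutoff(rep(0.4, 10), c(rep(0, 7), rep(1, 3)))
  expect_equal(occ$table$acc, 70)
  # brute force over every threshold on random data
  set.seed(15)
  y <- rbinom(40, 1, 0.4); p <- round(runif(40), 2)
  best <- max(vapply(c(-1, sort(unique(p)), 2), function(t)
    sum((p >= t) == y), numeric(1)))
  oc2 <- optimal_cutoff(p, y)
  expect_equal(oc2$table$tp + oc2$table$tn, best)
})

test_that("confusion metrics flag undefined cells instead of failing", {
  m <- confusion_metrics(0, 0, 50, 0)
  expect_true(is.na(m$sens))
  expect_true("sens" %in% m$undefined)
  expect_equal(m$spec, 100)
  expect_error(confusion_metrics(-1, 0, 1, 0), class = "copdct_input_error")
})

test_that("NRI identities hold: zero on self, antisymmetry, single shift", {
  set.seed(16)
  y <- rbinom(60, 1, 0.4)
  a <- rbinom(60, 1, 0.5) == 1
  b <- rbinom(60, 1, 0.5) == 1
  self <- compute_nri(a, a, y)
  expect_equal(self$total_nri, 0)
  ab <- compute_nri(a, b, y); ba <- compute_nri(b, a, y)
  expect_equal(ab$event_nri, -ba$event_nri)
  expect_equal(ab$nonevent_nri, -ba$nonevent_nri)
  # one event FN -> TP among 10 events
  y1 <- c(rep(1, 10), rep(0, 10))
  old <- rep(FALSE, 20)
  new <- old; new[1] <- TRUE
  expect_equal(compute_nri(old, new, y1)$total_nri, 10)
  expect_error(compute_nri(old[1:5], new, y1), class = "copdct_input_error")
})

test_that("calibration bins are equal-frequency and honest in-model", {
  set.seed(17)
  p <- runif(10000, 0.05, 0.95)
  y <- rbinom(10000, 1, p)
  cal <- calibration_curve(p, y, n_bins = 10)
  expect_equal(nrow(cal), 10L)
  expect_lte(diff(range(cal$n)), 1)
  expect_lte(max(abs(cal$mean_predicted - cal$observed)), 0.03)
  # constant predictions collapse to one bin at the prevalence
  yc <- rbinom(50, 1, 0.3)
  calc <- calibration_curve(rep(0.3, 50), yc)
  expect_equal(nrow(calc), 1L)
  expect_equal(calc$observed, mean(yc))
  expect_error(calibration_curve(runif(10), rbinom(10, 1, 0.5), n_bins = 8),
               class = "copdct_binning_error")
})

test_that("bootstrap validation is seeded, and shrinkage never grows slopes", {
  df <- generate_cohort(cohort_config(n = 300, seed = 21))
  v1 <- bootstrap_validate(df, model_ladder_specs()$m8, B = 40, seed = 5)
  v2 <- bootstrap_validate(df, model_ladder_specs()$m8, B = 40, seed = 5)
  expect_identical(v1$report, v2$report)
  expect_identical(v1$model$coefficients, v2$model$coefficients)
  raw <- fit_logistic(df, model_ladder_specs()$m8)
  expect_true(all(abs(v1$model$coefficients[-1]) <=
                  abs(raw$coefficients[-1]) + 1e-12))
  expect_equal(v1$report$corrected_c,
               v1$report$apparent_c - v1$report$optimism)
})

test_that("bootstrap optimism is essentially non-negative on signal data", {
  ok <- vapply(1:8, function(s) {
    df <- generate_cohort(cohort_config(n = 150, seed = 100 + s))
    v <- bootstrap_validate(df, c("age", "log_in950", "pi10"), B = 60,
                            seed = s)
    v$report$optimism >= -0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("the model ladder is complete, nested-monotone and reproducible", {
  df <- generate_cohort(cohort_config(n = 400, seed = 31))
  lad <- run_model_ladder(df, B = 20, seed = 2, stratify = TRUE)
  expect_length(lad$models, 8L)
  ll <- vapply(lad$models, function(m) m$fit$loglik, numeric(1))
  covs <- lapply(lad$models, function(m) m$covariates)
  for (i in seq_along(covs)) for (j in seq_along(covs)) {
    if (i != j && all(covs[[i]] %in% covs[[j]]))
      expect_gte(ll[j] + 1e-8, ll[i])
  }
  # biomarkers carry signal: the full model discriminates at least as well
  expect_gte(lad$models$m8$validation$apparent_c,
             lad$models$m1$validation$apparent_c)
  # air-trapping models are compared against their inspiratory-only twin
  expect_equal(lad$models$m8$inspiratory_comparator, "m7")
  expect_equal(lad$models$m6$inspiratory_comparator, "m2")
  # reproducibility of the full report
  lad2 <- run_model_ladder(df, B = 20, seed = 2, stratify = TRUE)
  expect_identical(copdct:::ladder_report_to_list(lad),
                   copdct:::ladder_report_to_list(lad2))
  # strata carry both subgroups with all eight models
  expect_named(lad$strata, c("symptomatic", "asymptomatic"))
  expect_length(lad$strata$symptomatic, 8L)
})
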