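test_that("empty cohorts and determinism behave as documented", {
  empty <- generate_cohort(cohort_config(n = 0))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("age", "bmi", "packyears", "smoking_status", "in950",
                    "ei_ratio", "pi10", "copd", "severity") %in% names(empty)))

  a <- generate_cohort(cohort_config(n = 200, seed = 42))
  b <- generate_cohort(cohort_config(n = 200, seed = 42))
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(n = 200, seed = 43))
  expect_false(identical(a$age, c$age))
})

test_that("cohort moments match the configured population", {
  co <- generate_cohort(cohort_config(n = 5000, seed = 1))
  expect_lt(abs(mean(co$age) - 62.5), 0.3)
  expect_lt(abs(mean(co$copd) - 0.383), 0.025)
  expect_lt(abs(mean(co$bmi) - 27.1), 0.3)
  expect_lt(abs(mean(co$smoking_status == "current") - 0.534), 0.03)
  expect_lt(abs(median(co$packyears) - 38), 2)
  expect_lt(abs(median(co$in950) - 0.75), 0.08)
  expect_lt(abs(median(co$ei_ratio) - 0.84), 0.01)
  expect_lt(abs(mean(co$pi10) - 2.41), 0.05)
  # physiologic bounds
  expect_true(all(co$age >= 50 & co$age <= 75))
  expect_true(all(co$bmi >= 15 & co$bmi <= 50))
  expect_true(all(co$packyears >= 16.5))
  expect_true(all(co$in950 > 0))
})

test_that("spirometry is drawn consistently with the COPD label", {
  co <- generate_cohort(cohort_config(n = 2000, seed = 5))
  cl <- classify_copd(co$fev1_pct_pred, co$fev1_fvc_ratio)
  expect_equal(cl$copd, co$copd)
  expect_equal(cl$severity, co$severity)
  # severity mix among COPD subjects roughly 63/31/6
  sev <- table(co$severity[co$copd]) / sum(co$copd)
  expect_lt(abs(sev[["mild"]] - 0.634), 0.05)
})

test_that("invalid configuration is rejected with the field named", {
  expect_error(cohort_config(age_sd = -1), class = "copdct_config_error")
  expect_error(cohort_config(symptom_p = 1.5), class = "copdct_config_error")
  expect_error(cohort_config(n = -3), class = "copdct_config_error")
  expect_error(cohort_config(true_coefficients = c(age = 1)),
               class = "copdct_config_error")
})

test_that("generating coefficients are recoverable by the full-model fit", {
  co <- generate_cohort(cohort_config(n = 5000, seed = 2))
  gen <- attr(co, "generating_coefficients")
  fit <- fit_logistic(co, model_ladder_specs()$m8)
  z <- (fit$coefficients[names(gen)] - gen) / fit$se[names(gen)]
  expect_true(all(abs(z) < 3))
})

test_that("cohorts round-trip through CSV", {
  co <- generate_cohort(cohort_config(n = 50, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$copd, co$copd)
  expect_equal(back$age, co$age, tolerance = 1e-12)
  expect_error(read_cohort(withr::local_tempfile(fileext = ".csv",
                                                 lines = "a,b\n1,2")),
               class = "copdct_input_error")
})
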