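# Bootstrap internal validation: optimism-corrected C-statistic and
# uniform shrinkage of the regression coefficients.

#' Bootstrap optimism correction and coefficient shrinkage
#'
#' Internal validation by the bootstrap optimism procedure: the model is
#' refit on each of `B` bootstrap resamples; the difference between its
#' C-statistic on the resample and on the original data estimates the
#' overoptimism of apparent performance, and the mean calibration slope of
#' the original outcomes on each resample model's linear predictor gives a
#' uniform shrinkage factor. Slopes are multiplied by the shrinkage factor
#' (clipped to (0, 1]) and the intercept re-estimated so predictions stay
#' centered.
#'
#' @param records cohort data.frame.
#' @param covariates model terms or a [model_ladder_specs()] entry.
#' @param B number of bootstrap resamples.
#' @param seed integer RNG seed; the whole procedure is reproducible.
#' @return list with `report` (class `validation_report`: `apparent_c`,
#'   `optimism`, `corrected_c`, `calibration_slope` = shrinkage factor,
#'   `c_ci_low`, `c_ci_high`, `B`, `n_redraws`) and `model` (the shrunk
#'   `copd_fit`).
#' @export
bootstrap_validate <- function(records, covariates, B = 500L, seed = 1L) {
  if (is.list(covariates) && !is.null(covariates$covariates))
    covariates <- covariates$covariates
  fit0 <- fit_logistic(records, covariates)
  y <- as.integer(records$copd)
  apparent <- c_statistic(fit0$fitted, y)
  ci <- c_statistic_ci(fit0$fitted, y)
  n <- nrow(records)

  opt <- numeric(B)
  slopes <- numeric(B)
  n_redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      for (try in seq_len(10L)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2L) break
        n_redraws <- n_redraws + 1L
        if (try == 10L)
          stop_copdct("bootstrap resample single-class after 10 redraws",
                      "copdct_degenerate_input_error")
      }
      boot <- records[idx, , drop = FALSE]
      fb <- fit_logistic(boot, covariates)
      c_boot <- c_statistic(fb$fitted, y[idx])
      lp_orig <- predict_lp(fb, records)
      c_orig <- c_statistic(lp_orig, y)
      opt[b] <- c_boot - c_orig
      slopes[b] <- calibration_slope(lp_orig, y)
    }
  })
  optimism <- mean(opt)
  shrink <- mean(slopes, na.rm = TRUE)
  shrink <- min(1, max(1e-6, shrink))

  shrunk <- fit0
  shrunk$shrinkage <- shrink
  sl <- fit0$coefficients[-1L] * shrink
  X <- model_design(records, covariates)
  lp_noint <- as.numeric(X %*% sl)
  refit_int <- suppressWarnings(
    glm(y ~ 1 + offset(lp_noint), family = binomial()))
  shrunk$coefficients <- c(intercept = unname(coef(refit_int)[1L]), sl)
  shrunk$linear_predictor <- as.numeric(shrunk$coefficients[1L] + lp_noint)
  shrunk$fitted <- plogis(shrunk$linear_predictor)

  report <- structure(list(
    apparent_c = apparent, optimism = optimism,
    corrected_c = apparent - optimism,
    calibration_slope = shrink,
    c_ci_low = ci$low, c_ci_high = ci$high,
    B = B, n_redraws = n_redraws
  ), class = "validation_report")
  list(report = report, model = shrunk)
}

# Linear predictor of a fit on new data.
predict_lp <- function(fit, newdata) {
  X <- model_design(newdata, fit$covariates)
  as.numeric(fit$coefficients[1L] + X %*% fit$coefficients[-1L])
}

# Logistic calibration slope of outcomes on a linear predictor.
calibration_slope <- function(lp, y) {
  if (sd(lp) < 1e-12) return(NA_real_)
  fit <- suppressWarnings(glm(y ~ lp, family = binomial()))
  unname(coef(fit)[2L])
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Bootstrap validation (B = %d)\n",
    "  apparent C: %.3f (95%% CI %.3f-%.3f)\n",
    "  optimism:   %.3f\n",
    "  corrected C: %.3f\n",
    "  shrinkage (calibration slope): %.3f\n"),
    x$B, x$apparent_c, x$c_ci_low, x$c_ci_high, x$optimism,
    x$corrected_c, x$calibration_slope))
  invisible(x)
}
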