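# The eight-model logistic ladder: model specifications and fitting.

#' The eight diagnostic model specifications
#'
#' The ladder starts from a demographic baseline (age, BMI, packyears,
#' smoking status) and adds the CT biomarkers stepwise: the natural log of
#' the emphysema index (`log_in950`), the air-trapping ratio (`ei_ratio`)
#' and bronchial wall thickness (`pi10`), singly and in combination, for
#' eight models in total.
#'
#' @return Named list of 8 model specs; each has `id`, `label` and
#'   `covariates` (character vector of cohort column terms).
#' @export
model_ladder_specs <- function() {
  base <- c("age", "bmi", "packyears", "smoking_current")
  mk <- function(id, label, extra)
    list(id = id, label = label, covariates = c(base, extra))
  list(
    m1 = mk(1L, "baseline", character()),
    m2 = mk(2L, "baseline + emphysema", "log_in950"),
    m3 = mk(3L, "baseline + air trapping", "ei_ratio"),
    m4 = mk(4L, "baseline + wall thickness", "pi10"),
    m5 = mk(5L, "baseline + wall thickness + air trapping",
            c("pi10", "ei_ratio")),
    m6 = mk(6L, "baseline + emphysema + air trapping",
            c("log_in950", "ei_ratio")),
    m7 = mk(7L, "baseline + emphysema + wall thickness",
            c("log_in950", "pi10")),
    m8 = mk(8L, "baseline + emphysema + wall thickness + air trapping",
            c("log_in950", "pi10", "ei_ratio"))
  )
}

# Design matrix for a model spec from a cohort data.frame.
model_design <- function(records, covariates) {
  need <- c("age", "bmi", "packyears", "smoking_status", "copd")
  if (any(c("log_in950") %in% covariates)) need <- c(need, "in950")
  need <- unique(c(need, intersect(covariates, c("ei_ratio", "pi10"))))
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_copdct(paste("records lack columns:", paste(miss, collapse = ", ")),
                "copdct_input_error")
  bad <- which(!stats::complete.cases(records[, need]))
  if (length(bad))
    stop_copdct(paste("missing covariate values in rows:",
                      paste(head(bad, 10), collapse = ", "),
                      "(complete data required; imputation is out of scope)"),
                "copdct_input_error")
  X <- matrix(0, nrow(records), length(covariates),
              dimnames = list(NULL, covariates))
  for (cv in covariates) {
    X[, cv] <- switch(cv,
      smoking_current = as.numeric(records$smoking_status == "current"),
      log_in950 = {
        if (any(records$in950 <= 0))
          stop_copdct("in950 must be > 0 for the log-transformed emphysema term",
                      "copdct_precondition_error")
        log(records$in950)
      },
      records[[cv]]
    )
  }
  X
}

#' Fit a logistic diagnostic model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]) of COPD status on the covariates of a model
#' spec. The emphysema index enters as its natural logarithm; smoking
#' status as an indicator for current smoking (reference: former).
#'
#' @param records cohort data.frame (see [generate_cohort()]); must be
#'   complete for the requested covariates.
#' @param covariates character vector of model terms, or a spec from
#'   [model_ladder_specs()].
#' @return An object of class `copd_fit`: `coefficients` (intercept +
#'   slopes, log-odds), `se`, `vcov`, `covariates`, `linear_predictor`,
#'   `fitted`, `loglik`, `n`, `converged`, and `shrinkage` (1 until
#'   [bootstrap_validate()] shrinks it).
#' @export
fit_logistic <- function(records, covariates) {
  if (is.list(covariates) && !is.null(covariates$covariates))
    covariates <- covariates$covariates
  if (nrow(records) < 25L)
    stop_copdct("need at least 25 records", "copdct_precondition_error")
  y <- as.integer(records$copd)
  if (length(unique(y)) < 2L)
    stop_copdct("both outcome classes must be present",
                "copdct_degenerate_input_error")
  X <- model_design(records, covariates)
  # standardize internally for numerical stability; report on original scale
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd); scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  fit <- suppressWarnings(glm.fit2(Xs, y))
  if (!fit$converged)
    stop_copdct(sprintf("IRLS did not converge in %d iterations", fit$iter),
                "copdct_convergence_error")
  if (any(fit$fitted > 1 - 1e-10 | fit$fitted < 1e-10) &&
      max(abs(fit$beta[-1L])) > 15)
    stop_copdct("complete separation detected (diverging coefficients)",
                "copdct_separation_error")
  beta_s <- fit$beta
  slopes <- beta_s[-1L] / scl
  intercept <- beta_s[1L] - sum(slopes * ctr)
  coefs <- c(intercept = unname(intercept), slopes)
  # linear back-transform of the covariance to the original scale
  J <- diag(c(1, 1 / scl))
  J[1L, -1L] <- -ctr / scl
  V <- J %*% fit$vcov %*% t(J)
  dimnames(V) <- list(names(coefs), names(coefs))
  lp <- as.numeric(intercept + X %*% slopes)
  structure(list(
    coefficients = coefs, se = sqrt(diag(V)), vcov = V,
    covariates = covariates,
    linear_predictor = lp, fitted = plogis(lp),
    loglik = sum(y * log(plogis(lp)) + (1 - y) * log(1 - plogis(lp))),
    n = length(y), converged = TRUE, shrinkage = 1
  ), class = "copd_fit")
}

# IRLS logistic fit on a design matrix (intercept added), returning the
# coefficient covariance from the final weighted information matrix.
glm.fit2 <- function(X, y, epsilon = 1e-8, maxit = 100L) {
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- stats::glm.fit(Xi, y, family = binomial(),
                        control = stats::glm.control(epsilon = epsilon,
                                                     maxit = maxit))
  w <- fit$weights
  info <- crossprod(Xi * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e)
    stop_copdct("singular information matrix", "copdct_convergence_error"))
  list(beta = coef(fit), vcov = vc, fitted = fit$fitted.values,
       converged = fit$converged, iter = fit$iter)
}

#' Predict COPD risk from a fitted model
#'
#' @param object a `copd_fit`.
#' @param newdata cohort data.frame.
#' @param ... unused.
#' @return numeric vector of predicted probabilities in (0, 1).
#' @export
predict.copd_fit <- function(object, newdata, ...) {
  X <- model_design(newdata, object$covariates)
  b <- object$coefficients
  plogis(as.numeric(b[1L] + X %*% b[-1L]))
}

#' @export
print.copd_fit <- function(x, ...) {
  cat(sprintf("Logistic COPD model (n = %d, shrinkage = %.3f)\n",
              x$n, x$shrinkage))
  print(round(cbind(coef = x$coefficients, se = x$se), 4))
  invisible(x)
}
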