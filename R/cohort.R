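# Synthetic screening cohorts: demographics, symptoms, spirometry and the
# three CT biomarkers, with COPD drawn from a known logistic model so that
# generating coefficients are recoverable by a correctly specified fit.

#' Configure a synthetic screening cohort
#'
#' Parameters of the cohort generator. Defaults reproduce the covariate
#' structure of a male lung-cancer-screening population: age 62.5 +/- 5.2 y
#' (bounded 50-75), BMI 27.1 +/- 3.6 kg/m2 (bounded 15-50), 53.4% current
#' smokers, packyears log-normal with median 38 and IQR 28-49 (left-truncated
#' at the 16.5-packyear screening entry criterion), and biomarker marginals
#' matching the published summaries: emphysema index median 0.75% with IQR
#' 0.40-1.46 (log-normal), air-trapping ratio 0.84 +/- 0.059, Pi10
#' 2.41 +/- 0.51 mm.
#'
#' COPD status is drawn from a logistic model over all seven covariates
#' (age, BMI, packyears, current smoking, log emphysema index, air-trapping
#' ratio, Pi10). The intercept is solved numerically on the realized linear
#' predictor so that the expected prevalence equals `target_prevalence`;
#' pass a finite `intercept` in `true_coefficients` to fix it instead.
#'
#' @param n number of subjects (>= 0).
#' @param seed integer RNG seed.
#' @param age_mean,age_sd,bmi_mean,bmi_sd normal covariate parameters.
#' @param current_smoker_p probability of current (vs former) smoking.
#' @param packyears_meanlog,packyears_sdlog log-normal packyears parameters.
#' @param packyears_min left truncation for packyears.
#' @param symptom_p prevalence of self-reported respiratory symptoms.
#' @param log_in950_mean,log_in950_sd marginal distribution of the natural
#'   log of the emphysema index (index in percent).
#' @param ei_mean,ei_sd marginal air-trapping (E/I-ratio) distribution.
#' @param pi10_mean,pi10_sd marginal Pi10 (mm) distribution.
#' @param true_coefficients named numeric vector of generating log-odds:
#'   `age`, `bmi`, `packyears`, `smoking_current`, `log_in950`, `ei_ratio`,
#'   `pi10`, and optionally `intercept` (NA = solve for prevalence).
#'   Slopes apply to covariates centered at their configured means.
#' @param target_prevalence COPD prevalence the intercept is solved for.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 1140L, seed = 1L,
                          age_mean = 62.5, age_sd = 5.2,
                          bmi_mean = 27.1, bmi_sd = 3.6,
                          current_smoker_p = 0.534,
                          packyears_meanlog = log(38),
                          packyears_sdlog = log(49 / 28) / (2 * stats::qnorm(0.75)),
                          packyears_min = 16.5,
                          symptom_p = 0.5,
                          log_in950_mean = log(0.75),
                          log_in950_sd = log(1.46 / 0.40) / (2 * stats::qnorm(0.75)),
                          ei_mean = 0.84, ei_sd = 0.08 / (2 * stats::qnorm(0.75)),
                          pi10_mean = 2.41, pi10_sd = 0.51,
                          true_coefficients = c(
                            intercept = NA_real_,
                            age = 0.055, bmi = -0.08, packyears = 0.016,
                            smoking_current = 0.40,
                            log_in950 = 1.3, ei_ratio = 18, pi10 = 1.9
                          ),
                          target_prevalence = 0.383) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    stop_copdct("invalid value for 'n': must be >= 0", "copdct_config_error",
                field = "n")
  check_number(age_sd, "age_sd", lower = 1e-9)
  check_number(bmi_sd, "bmi_sd", lower = 1e-9)
  check_number(packyears_sdlog, "packyears_sdlog", lower = 1e-9)
  check_number(log_in950_sd, "log_in950_sd", lower = 1e-9)
  check_number(ei_sd, "ei_sd", lower = 1e-9)
  check_number(pi10_sd, "pi10_sd", lower = 1e-9)
  check_number(current_smoker_p, "current_smoker_p", 0, 1)
  check_number(symptom_p, "symptom_p", 0, 1)
  check_number(target_prevalence, "target_prevalence", 1e-6, 1 - 1e-6)
  slopes <- c("age", "bmi", "packyears", "smoking_current",
              "log_in950", "ei_ratio", "pi10")
  if (!all(slopes %in% names(true_coefficients)))
    stop_copdct(paste("'true_coefficients' must name:",
                      paste(slopes, collapse = ", ")),
                "copdct_config_error", field = "true_coefficients")
  cfg <- list(n = as.integer(n), seed = as.integer(seed),
              age_mean = age_mean, age_sd = age_sd,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              current_smoker_p = current_smoker_p,
              packyears_meanlog = packyears_meanlog,
              packyears_sdlog = packyears_sdlog,
              packyears_min = packyears_min,
              symptom_p = symptom_p,
              log_in950_mean = log_in950_mean, log_in950_sd = log_in950_sd,
              ei_mean = ei_mean, ei_sd = ei_sd,
              pi10_mean = pi10_mean, pi10_sd = pi10_sd,
              true_coefficients = true_coefficients,
              target_prevalence = target_prevalence)
  class(cfg) <- "cohort_config"
  cfg
}

# Truncated-normal draw by deterministic redraw of out-of-bounds values.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad) && guard < 1000L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
    guard <- guard + 1L
  }
  pmin(upper, pmax(lower, x))
}

#' Generate a synthetic subject cohort
#'
#' Draws `config$n` complete subject records: demographics, smoking,
#' symptoms, the three CT biomarkers, COPD status from the generating
#' logistic model, and spirometry consistent with that status (FEV1/FVC
#' below 0.70 iff COPD; FEV1 percent-predicted drawn within the severity
#' band, with severities distributed 63.4 / 30.9 / 5.7 percent
#' mild/moderate/severe among COPD subjects).
#'
#' @param config a [cohort_config()].
#' @return A data.frame with one row per subject and columns `id`, `age`,
#'   `bmi`, `packyears`, `smoking_status`, `symptomatic`, `fev1_pct_pred`,
#'   `fev1_fvc_ratio`, `in950`, `ei_ratio`, `pi10`, `copd`, `severity`.
#'   The generating coefficients actually used (raw, uncentered scale) are
#'   attached as attribute `"generating_coefficients"`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  empty <- data.frame(
    id = integer(), age = numeric(), bmi = numeric(), packyears = numeric(),
    smoking_status = character(), symptomatic = logical(),
    fev1_pct_pred = numeric(), fev1_fvc_ratio = numeric(),
    in950 = numeric(), ei_ratio = numeric(), pi10 = numeric(),
    copd = logical(), severity = character(), stringsAsFactors = FALSE
  )
  if (n == 0L) return(empty)

  with_seed(config$seed, {
    age <- rnorm_trunc(n, config$age_mean, config$age_sd, 50, 75)
    bmi <- rnorm_trunc(n, config$bmi_mean, config$bmi_sd, 15, 50)
    smoking_current <- rbinom(n, 1L, config$current_smoker_p)
    packyears <- rlnorm(n, config$packyears_meanlog, config$packyears_sdlog)
    bad <- which(packyears < config$packyears_min)
    guard <- 0L
    while (length(bad) && guard < 1000L) {
      packyears[bad] <- rlnorm(length(bad), config$packyears_meanlog,
                               config$packyears_sdlog)
      bad <- bad[packyears[bad] < config$packyears_min]
      guard <- guard + 1L
    }
    symptomatic <- rbinom(n, 1L, config$symptom_p) == 1L
    log_in950 <- rnorm(n, config$log_in950_mean, config$log_in950_sd)
    ei_ratio <- rnorm_trunc(n, config$ei_mean, config$ei_sd, 0.5, 1.2)
    pi10 <- rnorm_trunc(n, config$pi10_mean, config$pi10_sd, 0.8, 5)

    b <- config$true_coefficients
    lp <- b[["age"]] * (age - config$age_mean) +
      b[["bmi"]] * (bmi - config$bmi_mean) +
      b[["packyears"]] * (packyears - exp(config$packyears_meanlog)) +
      b[["smoking_current"]] * (smoking_current - config$current_smoker_p) +
      b[["log_in950"]] * (log_in950 - config$log_in950_mean) +
      b[["ei_ratio"]] * (ei_ratio - config$ei_mean) +
      b[["pi10"]] * (pi10 - config$pi10_mean)
    b0 <- if ("intercept" %in% names(b)) b[["intercept"]] else NA_real_
    if (is.na(b0)) {
      f <- function(a) mean(plogis(a + lp)) - config$target_prevalence
      b0 <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
    }
    copd <- rbinom(n, 1L, plogis(b0 + lp)) == 1L

    # spirometry consistent with the COPD label and severity mix
    fev1_fvc_ratio <- ifelse(copd, runif(n, 0.45, 0.6999),
                             runif(n, 0.701, 0.92))
    sev_draw <- runif(n)
    severity <- rep("none", n)
    severity[copd & sev_draw < 0.634] <- "mild"
    severity[copd & sev_draw >= 0.634 & sev_draw < 0.634 + 0.309] <- "moderate"
    severity[copd & sev_draw >= 0.634 + 0.309] <- "severe"
    fev1 <- rnorm_trunc(n, 102, 13, 60, 140)
    fev1[severity == "mild"] <- runif(sum(severity == "mild"), 80, 115)
    fev1[severity == "moderate"] <- runif(sum(severity == "moderate"), 50, 79.99)
    fev1[severity == "severe"] <- runif(sum(severity == "severe"), 32, 49.99)

    out <- data.frame(
      id = seq_len(n), age = age, bmi = bmi, packyears = packyears,
      smoking_status = ifelse(smoking_current == 1L, "current", "former"),
      symptomatic = symptomatic,
      fev1_pct_pred = fev1, fev1_fvc_ratio = fev1_fvc_ratio,
      in950 = exp(log_in950), ei_ratio = ei_ratio, pi10 = pi10,
      copd = copd, severity = severity, stringsAsFactors = FALSE
    )
    # generating coefficients on the raw (uncentered) covariate scale
    raw_int <- b0 -
      b[["age"]] * config$age_mean - b[["bmi"]] * config$bmi_mean -
      b[["packyears"]] * exp(config$packyears_meanlog) -
      b[["smoking_current"]] * config$current_smoker_p -
      b[["log_in950"]] * config$log_in950_mean -
      b[["ei_ratio"]] * config$ei_mean - b[["pi10"]] * config$pi10_mean
    attr(out, "generating_coefficients") <- c(
      intercept = raw_int, age = b[["age"]], bmi = b[["bmi"]],
      packyears = b[["packyears"]], smoking_current = b[["smoking_current"]],
      log_in950 = b[["log_in950"]], ei_ratio = b[["ei_ratio"]],
      pi10 = b[["pi10"]]
    )
    out
  })
}

#' Write / read a cohort as CSV
#'
#' The CSV header is the documented column set of [generate_cohort()];
#' logical columns are stored as TRUE/FALSE strings.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the
#'   data.frame.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "bmi", "packyears", "smoking_status", "symptomatic",
            "in950", "ei_ratio", "pi10", "copd")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_copdct(paste("cohort file lacks columns:", paste(miss, collapse = ", ")),
                "copdct_input_error")
  df$symptomatic <- as.logical(df$symptomatic)
  df$copd <- as.logical(df$copd)
  df
}
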