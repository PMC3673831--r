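# End-to-end diagnostic ladder: fit, validate, cut and compare all eight
# models, overall and within symptom strata.

#' Run the eight-model diagnostic ladder
#'
#' For each of the eight model specifications ([model_ladder_specs()]):
#' fits the logistic model, performs bootstrap optimism correction and
#' shrinkage ([bootstrap_validate()]), finds the optimal-accuracy cutoff of
#' the shrunk model's predictions, tabulates confusion metrics, and
#' computes the Net Reclassification Index versus the demographic baseline
#' and -- for models containing the expiratory air-trapping term -- versus
#' the corresponding inspiratory-only model (the same model without
#' `ei_ratio`). The ladder is then repeated, without bootstrap, inside the
#' symptomatic and asymptomatic strata (refit per stratum, apparent C with
#' DeLong CI).
#'
#' @param records complete cohort data.frame (missing covariates are
#'   rejected; imputation is out of scope).
#' @param B bootstrap iterations per model.
#' @param seed integer RNG seed.
#' @param stratify also run the symptom-stratified analysis.
#' @return list of class `ladder_report`: per-model entries (`fit`,
#'   `validation`, `cutoff`, `table`, `nri_vs_baseline`,
#'   `nri_vs_inspiratory`), `strata` (per-stratum C statistics), `seed`,
#'   `B`, `n`.
#' @export
run_model_ladder <- function(records, B = 500L, seed = 1L, stratify = TRUE) {
  specs <- model_ladder_specs()
  y <- as.logical(records$copd)
  # comparator for models with the expiratory term: drop ei_ratio
  insp_comparator <- c(m3 = "m1", m5 = "m4", m6 = "m2", m8 = "m7")

  models <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    val <- bootstrap_validate(records, sp, B = B,
                              seed = seed + sp$id)
    cut <- optimal_cutoff(val$model$fitted, y)
    models[[nm]] <- list(
      id = sp$id, label = sp$label, covariates = sp$covariates,
      fit = val$model, validation = val$report,
      cutoff = cut$threshold, table = cut$table,
      classified = cut$classified
    )
  }
  for (nm in names(specs)) {
    if (nm != "m1") {
      models[[nm]]$nri_vs_baseline <- compute_nri(
        models$m1$classified, models[[nm]]$classified, y)
    }
    if (nm %in% names(insp_comparator)) {
      comp <- insp_comparator[[nm]]
      models[[nm]]$nri_vs_inspiratory <- compute_nri(
        models[[comp]]$classified, models[[nm]]$classified, y)
      models[[nm]]$inspiratory_comparator <- comp
    }
  }

  strata <- NULL
  if (stratify) {
    strata <- list()
    for (sym in c(TRUE, FALSE)) {
      sub <- records[records$symptomatic == sym, , drop = FALSE]
      lab <- if (sym) "symptomatic" else "asymptomatic"
      res <- list()
      for (nm in names(specs)) {
        sp <- specs[[nm]]
        fit <- fit_logistic(sub, sp)
        ci <- c_statistic_ci(fit$fitted, sub$copd)
        res[[nm]] <- list(id = sp$id, label = sp$label,
                          c = ci$c, c_ci_low = ci$low, c_ci_high = ci$high,
                          n = nrow(sub))
      }
      strata[[lab]] <- res
    }
  }

  structure(list(models = models, strata = strata,
                 seed = seed, B = B, n = nrow(records)),
            class = "ladder_report")
}

#' @export
print.ladder_report <- function(x, ...) {
  cat(sprintf("Diagnostic model ladder (n = %d, B = %d)\n", x$n, x$B))
  cat(sprintf("%-2s %-45s %6s %6s %6s %6s\n",
              "id", "model", "appC", "corrC", "acc", "NRIvs1"))
  for (m in x$models) {
    nri <- if (!is.null(m$nri_vs_baseline))
      sprintf("%6.1f", m$nri_vs_baseline$total_nri) else "     -"
    cat(sprintf("%-2d %-45s %6.3f %6.3f %6.1f %s\n",
                m$id, m$label, m$validation$apparent_c,
                m$validation$corrected_c, m$table$acc, nri))
  }
  invisible(x)
}

# JSON-serializable view of a ladder report.
ladder_report_to_list <- function(x) {
  mods <- lapply(x$models, function(m) {
    list(
      id = m$id, label = m$label, covariates = m$covariates,
      coefficients = as.list(m$fit$coefficients),
      shrinkage = m$fit$shrinkage,
      apparent_c = m$validation$apparent_c,
      optimism = m$validation$optimism,
      corrected_c = m$validation$corrected_c,
      c_ci = c(m$validation$c_ci_low, m$validation$c_ci_high),
      cutoff = m$cutoff,
      confusion = list(tp = m$table$tp, fn = m$table$fn, tn = m$table$tn,
                       fp = m$table$fp, acc = m$table$acc,
                       sens = m$table$sens, spec = m$table$spec,
                       ppv = m$table$ppv, npv = m$table$npv),
      nri_vs_baseline = if (!is.null(m$nri_vs_baseline))
        unclass(m$nri_vs_baseline),
      nri_vs_inspiratory = if (!is.null(m$nri_vs_inspiratory))
        unclass(m$nri_vs_inspiratory)
    )
  })
  strata <- if (!is.null(x$strata)) {
    lapply(x$strata, function(s) lapply(s, function(m)
      list(id = m$id, label = m$label, c = m$c,
           c_ci = c(m$c_ci_low, m$c_ci_high), n = m$n)))
  }
  list(schema_version = 1L, n = x$n, B = x$B, seed = x$seed,
       models = mods, strata = strata)
}
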