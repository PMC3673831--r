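# Discrimination and classification metrics: C-statistic (AUC) with DeLong
# confidence interval, optimal-accuracy cutoff, confusion metrics,
# calibration curve.

#' C-statistic (area under the ROC curve)
#'
#' The concordance probability: over all case-control pairs, the fraction
#' in which the case has the higher predicted risk, counting ties as one
#' half. Computed via midranks in O(n log n).
#'
#' @param risks numeric predicted risks (any monotone score).
#' @param outcomes binary outcomes (0/1 or logical).
#' @return the C-statistic in `[0, 1]`.
#' @export
c_statistic <- function(risks, outcomes) {
  y <- as.integer(as.logical(outcomes))
  if (length(risks) != length(y))
    stop_copdct("'risks' and 'outcomes' lengths differ", "copdct_input_error")
  n1 <- sum(y); n0 <- length(y) - n1
  if (n1 == 0L || n0 == 0L)
    stop_copdct("both outcome classes are required",
                "copdct_degenerate_input_error")
  r <- rank(risks, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong confidence interval for the C-statistic
#'
#' Normal-approximation interval based on the DeLong variance estimate
#' (placement values of cases and controls), truncated to `[0, 1]`.
#'
#' @inheritParams c_statistic
#' @param level confidence level.
#' @return list with `c` (point estimate), `se`, `low`, `high`.
#' @export
c_statistic_ci <- function(risks, outcomes, level = 0.95) {
  y <- as.integer(as.logical(outcomes))
  n1 <- sum(y); n0 <- length(y) - n1
  if (n1 == 0L || n0 == 0L)
    stop_copdct("both outcome classes are required",
                "copdct_degenerate_input_error")
  cases <- risks[y == 1L]; controls <- risks[y == 0L]
  auc <- c_statistic(risks, outcomes)
  # placement of each case among controls, and vice versa
  v10 <- vapply(cases, function(x)
    (sum(x > controls) + 0.5 * sum(x == controls)) / n0, numeric(1))
  v01 <- vapply(controls, function(x)
    (sum(cases > x) + 0.5 * sum(cases == x)) / n1, numeric(1))
  s2 <- var(v10) / n1 + var(v01) / n0
  se <- sqrt(s2)
  z <- qnorm(1 - (1 - level) / 2)
  list(c = auc, se = se,
       low = max(0, auc - z * se), high = min(1, auc + z * se))
}

#' Optimal-accuracy risk cutoff
#'
#' Scans candidate thresholds at the midpoints of adjacent sorted unique
#' risks (plus the ends) and returns the one maximizing the number of
#' true positives plus true negatives. Subjects with risk at or above the
#' threshold are classified positive; ties in the optimum are broken
#' toward the lowest threshold (maximizing sensitivity).
#'
#' @inheritParams c_statistic
#' @return list with `threshold`, `table` (a [confusion_metrics()] result)
#'   and `classified` (logical vector of positive calls).
#' @export
optimal_cutoff <- function(risks, outcomes) {
  y <- as.integer(as.logical(outcomes))
  if (length(unique(y)) < 2L)
    stop_copdct("both outcome classes are required",
                "copdct_degenerate_input_error")
  u <- sort(unique(risks))
  # ends included: classify-all-positive and classify-all-negative
  cand <- c(u[1L] - 1, (u[-length(u)] + u[-1L]) / 2, u[length(u)] + 1)
  best <- NULL
  for (th in cand) {
    pos <- risks >= th
    score <- sum(pos & y == 1L) + sum(!pos & y == 0L)
    if (is.null(best) || score > best$score) {
      best <- list(threshold = th, score = score)
    }
  }
  pos <- risks >= best$threshold
  tab <- confusion_metrics(tp = sum(pos & y == 1L), fn = sum(!pos & y == 1L),
                           tn = sum(!pos & y == 0L), fp = sum(pos & y == 0L))
  list(threshold = best$threshold, table = tab, classified = pos)
}

#' Confusion-table metrics
#'
#' Accuracy, sensitivity, specificity and predictive values (in percent)
#' from the four confusion counts. Metrics with a zero denominator are
#' returned as `NA` and flagged rather than raising an error.
#'
#' @param tp,fn,tn,fp non-negative counts.
#' @return list of class `classification_table` with the counts, `acc`,
#'   `sens`, `spec`, `ppv`, `npv` (percent, full precision; print rounds
#'   to one decimal) and `undefined` (names of undefined metrics).
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_copdct("counts must be non-negative integers", "copdct_input_error")
  n <- sum(counts)
  if (tp + fn == 0 && tn + fp == 0)
    stop_copdct("empty confusion table", "copdct_degenerate_input_error")
  sdiv <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- list(
    tp = tp, fn = fn, tn = tn, fp = fp,
    acc = sdiv(tp + tn, n),
    sens = sdiv(tp, tp + fn),
    spec = sdiv(tn, tn + fp),
    ppv = sdiv(tp, tp + fp),
    npv = sdiv(tn, tn + fn)
  )
  out$undefined <- names(which(vapply(out[c("acc", "sens", "spec", "ppv", "npv")],
                                      is.na, logical(1))))
  class(out) <- "classification_table"
  out
}

#' @export
print.classification_table <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "  NA" else sprintf("%.1f", v)
  cat(sprintf("TP %d  FN %d  TN %d  FP %d | ACC %s  SENS %s  SPEC %s  PPV %s  NPV %s\n",
              x$tp, x$fn, x$tn, x$fp, fmt(x$acc), fmt(x$sens), fmt(x$spec),
              fmt(x$ppv), fmt(x$npv)))
  invisible(x)
}

#' Calibration curve by equal-frequency bins
#'
#' Splits subjects into `n_bins` near-equal groups by sorted predicted
#' risk and reports, per bin, the mean predicted risk and the observed
#' event fraction. Constant predictions collapse to a single bin.
#'
#' @inheritParams c_statistic
#' @param n_bins number of risk bins.
#' @return data.frame with `bin`, `n`, `mean_predicted`, `observed`.
#' @export
calibration_curve <- function(risks, outcomes, n_bins = 10L) {
  y <- as.integer(as.logical(outcomes))
  n <- length(y)
  if (n_bins > n / 2)
    stop_copdct("'n_bins' must be at most n/2", "copdct_binning_error")
  if (length(unique(risks)) == 1L) {
    return(data.frame(bin = 1L, n = n, mean_predicted = risks[1L],
                      observed = mean(y)))
  }
  ord <- order(risks)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- rep(seq_len(n_bins), times = sizes)
  df <- data.frame(risk = risks[ord], y = y[ord], bin = bin)
  agg <- lapply(split(df, df$bin), function(g)
    data.frame(bin = g$bin[1L], n = nrow(g), mean_predicted = mean(g$risk),
               observed = mean(g$y)))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
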