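# Net Reclassification Index for binary classifications.

#' Net Reclassification Index between two classifiers
#'
#' Compares per-subject binary classifications under an old and a new
#' model. The event component is the net fraction of events moved from
#' false negative to true positive; the non-event component the net
#' fraction of non-events moved from false positive to true negative;
#' the total NRI is their sum. All components in percent.
#'
#' @param old,new logical (or 0/1) positive calls per subject.
#' @param outcomes binary outcomes for the same subjects.
#' @return list of class `nri_result`: `event_nri`, `nonevent_nri`,
#'   `total_nri` (percent).
#' @export
compute_nri <- function(old, new, outcomes) {
  old <- as.logical(old); new <- as.logical(new)
  y <- as.logical(outcomes)
  if (length(old) != length(new) || length(old) != length(y))
    stop_copdct("'old', 'new' and 'outcomes' must have equal length",
                "copdct_input_error")
  n_ev <- sum(y); n_ne <- sum(!y)
  if (n_ev == 0L || n_ne == 0L)
    stop_copdct("both outcome classes are required",
                "copdct_degenerate_input_error")
  up_ev <- sum(y & !old & new)    # FN -> TP
  down_ev <- sum(y & old & !new)  # TP -> FN
  up_ne <- sum(!y & old & !new)   # FP -> TN
  down_ne <- sum(!y & !old & new) # TN -> FP
  structure(list(
    event_nri = 100 * (up_ev - down_ev) / n_ev,
    nonevent_nri = 100 * (up_ne - down_ne) / n_ne,
    total_nri = 100 * ((up_ev - down_ev) / n_ev + (up_ne - down_ne) / n_ne)
  ), class = "nri_result")
}

#' Marginal NRI from two confusion tables
#'
#' When only the aggregate confusion counts of each model are available
#' (not the per-subject crossing), the net shifts can still be computed
#' from the marginal TP and TN changes.
#'
#' @param old,new `classification_table` objects ([confusion_metrics()]).
#' @return an `nri_result`.
#' @export
compute_nri_marginal <- function(old, new) {
  n_ev <- old$tp + old$fn
  n_ne <- old$tn + old$fp
  if (n_ev != new$tp + new$fn || n_ne != new$tn + new$fp)
    stop_copdct("confusion tables describe different populations",
                "copdct_input_error")
  structure(list(
    event_nri = 100 * (new$tp - old$tp) / n_ev,
    nonevent_nri = 100 * (new$tn - old$tn) / n_ne,
    total_nri = 100 * ((new$tp - old$tp) / n_ev + (new$tn - old$tn) / n_ne)
  ), class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("NRI: events %+.1f%%, non-events %+.1f%%, total %+.1f%%\n",
              x$event_nri, x$nonevent_nri, x$total_nri))
  invisible(x)
}
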