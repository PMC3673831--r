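# Spirometric COPD definition and severity grading.

#' Classify COPD from spirometry
#'
#' COPD is present when the prebronchodilator FEV1/FVC ratio is strictly
#' below 0.70. Severity is graded from FEV1 percent-predicted: mild
#' (FEV1 >= 80), moderate (80 > FEV1 >= 50), severe (FEV1 < 50). The
#' published bands leave FEV1 < 30 unassigned; it is mapped to severe and
#' flagged in the result.
#'
#' @param fev1_pct_pred FEV1 as percent of predicted (> 0); vectorized.
#' @param fev1_fvc_ratio FEV1/FVC as a fraction in (0, 1.2].
#' @return data.frame with columns `copd` (logical), `severity`
#'   (`"none"`, `"mild"`, `"moderate"`, `"severe"`) and
#'   `below_grading_range` (logical, FEV1 < 30 among COPD subjects).
#' @export
classify_copd <- function(fev1_pct_pred, fev1_fvc_ratio) {
  if (any(!is.finite(fev1_pct_pred)) || any(fev1_pct_pred <= 0))
    stop_copdct("'fev1_pct_pred' must be positive", "copdct_input_error")
  if (any(!is.finite(fev1_fvc_ratio)) || any(fev1_fvc_ratio <= 0) ||
      any(fev1_fvc_ratio > 1.2))
    stop_copdct("'fev1_fvc_ratio' must lie in (0, 1.2]", "copdct_input_error")
  copd <- fev1_fvc_ratio < 0.70
  severity <- rep("none", length(copd))
  severity[copd & fev1_pct_pred >= 80] <- "mild"
  severity[copd & fev1_pct_pred < 80 & fev1_pct_pred >= 50] <- "moderate"
  severity[copd & fev1_pct_pred < 50] <- "severe"
  data.frame(copd = copd, severity = severity,
             below_grading_range = copd & fev1_pct_pred < 30)
}
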