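#' Stage cardiovascular autonomic neuropathy from reflex-test results
#'
#' The three cardiovascular autonomic reflex tests (postural change 30:15
#' ratio, deep breathing E:I ratio, Valsalva maneuver) are each classified
#' abnormal/normal; the CAN stage follows the abnormal count: 0 abnormal =
#' none, exactly 1 = early CAN, 2 or more = manifest CAN.
#'
#' @param cart_abnormal logical vector of length 3 (postural, deep
#'   breathing, Valsalva), TRUE = abnormal.
#' @return `"none"`, `"early"` or `"manifest"`.
#' @export
stage_can <- function(cart_abnormal) {
  if (length(cart_abnormal) != 3L || anyNA(cart_abnormal))
    stop("cart_abnormal must be 3 non-missing logical values")
  n <- sum(as.logical(cart_abnormal))
  if (n == 0L) "none" else if (n == 1L) "early" else "manifest"
}

#' Classify orthostatic intolerance from a 10-minute standing test
#'
#' Orthostatic intolerance is a systolic drop >= 20 mmHg or a diastolic
#' drop >= 10 mmHg relative to baseline. The first reading meeting the
#' criterion fixes the category by its time: initial hypotension within the
#' first minute, classic between the first and third minute, delayed from
#' the fourth to the tenth minute (readings in the unlabelled 3-4 minute
#' interval are classified classic). `"none"` if the criterion is never met.
#'
#' @param baseline_bp numeric `c(sys, dia)` in mmHg.
#' @param readings data frame with columns `minute`, `sys`, `dia`, times in
#'   \[0, 10\] minutes.
#' @return one of `"none"`, `"initial"`, `"classic"`, `"delayed"`.
#' @export
classify_orthostatic <- function(baseline_bp, readings) {
  if (nrow(readings) == 0L) stop("no standing readings supplied")
  if (any(readings$minute < 0 | readings$minute > 10))
    stop("readings must lie within 0-10 minutes")
  readings <- readings[order(readings$minute), ]
  drop_sys <- baseline_bp[1L] - readings$sys
  drop_dia <- baseline_bp[2L] - readings$dia
  hit <- which(drop_sys >= 20 | drop_dia >= 10)
  if (length(hit) == 0L) return("none")
  m <- readings$minute[hit[1L]]
  if (m < 1) "initial" else if (m < 4) "classic" else "delayed"
}

#' Identify reverse dipping of nocturnal blood pressure
#'
#' A reverse dipper's nocturnal blood pressure rises at least 10% above the
#' daytime level in either the systolic or the diastolic component.
#'
#' @param day_mean,night_mean numeric `c(sys, dia)` in mmHg, all > 0.
#' @return logical.
#' @export
is_reverse_dipper <- function(day_mean, night_mean) {
  if (any(day_mean <= 0) || any(night_mean <= 0))
    stop("blood pressures must be positive")
  night_mean[1L] / day_mean[1L] >= 1.10 || night_mean[2L] / day_mean[2L] >= 1.10
}
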