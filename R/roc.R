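#' Empirical ROC curve
#'
#' Thresholds are the distinct observed score values plus a sentinel giving
#' the (0, 0) corner. With `direction = "lower"` (the default for CVT, which
#' falls with autonomic neuropathy) a subject is classified positive iff
#' their score is at or below the threshold; with `direction = "higher"`,
#' at or above. The resulting points are monotone non-decreasing in both
#' false-positive and true-positive rate.
#'
#' @param scores numeric biomarker values.
#' @param labels logical (TRUE = case) or 0/1 vector, aligned with `scores`.
#' @param direction `"lower"` if lower scores indicate disease, `"higher"`
#'   otherwise.
#' @return data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels))
    stop("need at least one case and one control")
  x <- scores[labels]; y <- scores[!labels]
  thr <- sort(unique(scores))
  if (direction == "lower") {
    sentinel <- -Inf
    tpr <- vapply(thr, function(c) mean(x <= c), 0)
    fpr <- vapply(thr, function(c) mean(y <= c), 0)
  } else {
    thr <- rev(thr)
    sentinel <- Inf
    tpr <- vapply(thr, function(c) mean(x >= c), 0)
    fpr <- vapply(thr, function(c) mean(y >= c), 0)
  }
  data.frame(threshold = c(sentinel, thr),
             fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Area under the ROC curve
#'
#' Trapezoidal area over the empirical ROC curve; numerically identical to
#' the tie-corrected Mann-Whitney statistic, the probability that a random
#' case scores more extreme than a random control plus half the probability
#' of a tie.
#'
#' @inheritParams roc_points
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, direction = c("lower", "higher")) {
  pts <- roc_points(scores, labels, direction)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

# orient scores so that higher = more case-like
orient_scores <- function(scores, direction) {
  if (direction == "lower") -scores else scores
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance of the empirical AUC from DeLong's structural
#' components: per-case and per-control placement values (via the
#' tie-corrected kernel), whose sample variances divided by the respective
#' class sizes sum to the AUC variance. The normal-approximation interval
#' is clipped to \[0, 1\]. With perfect separation the variance is 0 and
#' the interval degenerates to the point estimate.
#'
#' @inheritParams roc_points
#' @param level confidence level (default 0.95).
#' @return list with `auc`, `var`, `ci` (length-2 numeric), `level`.
#' @export
delong_ci <- function(scores, labels, direction = c("lower", "higher"),
                      level = 0.95) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  m <- sum(labels); n <- sum(!labels)
  if (m < 2L || n < 2L)
    stop("DeLong interval needs >= 2 cases and >= 2 controls")
  z <- orient_scores(scores, direction)
  x <- z[labels]; y <- z[!labels]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)   # per-case placements
  v01 <- colMeans(psi)   # per-control placements
  v <- stats::var(v10) / m + stats::var(v01) / n
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- auc + c(-1, 1) * zq * sqrt(v)
  list(auc = auc, var = v,
       ci = pmin(1, pmax(0, ci)), level = level)
}

#' Youden-index optimal cut-off
#'
#' Scans the observed score values as candidate cut-offs and returns the one
#' maximizing J = sensitivity + specificity - 1 under the classification
#' rule score <= cutoff (`direction = "lower"`) or score >= cutoff
#' (`"higher"`). Ties in J are broken toward higher specificity, then toward
#' the more conservative cut-off (lower for `"lower"`, higher for
#' `"higher"`); all tied cut-offs are also reported.
#'
#' @inheritParams roc_points
#' @return list with `cutoff`, `sensitivity`, `specificity`, `j` and
#'   `tied_cutoffs` (all cut-offs attaining the maximal J).
#' @export
youden_cutoff <- function(scores, labels, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels))
    stop("need at least one case and one control")
  x <- scores[labels]; y <- scores[!labels]
  thr <- sort(unique(scores))
  if (direction == "lower") {
    sens <- vapply(thr, function(c) mean(x <= c), 0)
    spec <- vapply(thr, function(c) mean(y > c), 0)
  } else {
    sens <- vapply(thr, function(c) mean(x >= c), 0)
    spec <- vapply(thr, function(c) mean(y < c), 0)
  }
  j <- sens + spec - 1
  jmax <- max(j)
  tied <- which(abs(j - jmax) < 1e-12)
  # higher specificity first, then the more conservative cut-off
  ord <- order(-spec[tied],
               if (direction == "lower") thr[tied] else -thr[tied])
  best <- tied[ord[1L]]
  list(cutoff = thr[best], sensitivity = sens[best], specificity = spec[best],
       j = j[best], tied_cutoffs = thr[tied])
}

#' Confusion-matrix metrics at a fixed cut-off
#'
#' Sensitivity, specificity, false/true positive rates and predictive values
#' from the 2x2 table at the given cut-off, with predictive values at the
#' sample prevalence. A predictive value whose margin is empty (no predicted
#' positives or no predicted negatives) is reported as `NA` (undefined), not
#' as 0.
#'
#' @inheritParams roc_points
#' @param cutoff classification threshold (positive iff score <= cutoff for
#'   `direction = "lower"`, >= cutoff for `"higher"`).
#' @return list with `sensitivity`, `specificity`, `fpr`, `tpr`, `ppv`,
#'   `npv`, and counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff,
                                direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pred <- if (direction == "lower") scores <= cutoff else scores >= cutoff
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(sensitivity = sens, specificity = spec,
       fpr = 1 - spec, tpr = sens,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}
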