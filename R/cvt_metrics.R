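#' CVT capacity of a processed series
#'
#' Parasympathetic capacity during sleep, defined as the mean absolute
#' difference between the whole-series mean CVT and the 20 most extreme
#' values: the 10 with the most elevated CVT and the 10 with the most
#' reduced CVT. Requires at least 20 points. Ties at the 10th largest or
#' smallest value are broken by earliest index (stable sort order), and the
#' elevated/reduced sets are disjoint index sets taken from the two ends of
#' the sorted order.
#'
#' Capacity is translation-invariant and scales linearly under
#' multiplication by a positive constant.
#'
#' @param cvt processed CVT series (numeric).
#' @param n_extreme points taken from each end (default 10).
#' @return capacity in LVS units (>= 0).
#' @export
cvt_capacity <- function(cvt, n_extreme = 10L) {
  n <- length(cvt)
  if (n < 2L * n_extreme)
    stop(sprintf("capacity undefined: need >= %d points, got %d", 2L * n_extreme, n))
  m <- mean(cvt)
  o <- order(cvt)  # stable: ties keep earliest index first
  reduced <- o[seq_len(n_extreme)]
  elevated <- o[(n - n_extreme + 1L):n]
  mean(abs(cvt[c(elevated, reduced)] - m))
}

#' Summarize a processed CVT series
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and CVT
#' capacity. Capacity is reported as `NA` when fewer than 20 points are
#' available.
#'
#' @param cvt processed CVT series (numeric, >= 2 points).
#' @param source `"long_term"` (overnight) or `"short_term"` (awake).
#' @return list of class `cvt_summary` with `mean_cvt`, `sd_cvt`,
#'   `capacity`, `n_points`, `source`.
#' @export
summarize_cvt <- function(cvt, source = c("long_term", "short_term")) {
  source <- match.arg(source)
  if (length(cvt) == 0L) stop("empty CVT series")
  if (length(cvt) < 2L) stop("need >= 2 points to summarize")
  structure(list(
    mean_cvt = mean(cvt),
    sd_cvt = stats::sd(cvt),
    capacity = if (length(cvt) >= 20L) cvt_capacity(cvt) else NA_real_,
    n_points = length(cvt),
    source = source), class = "cvt_summary")
}

#' Tabulate CVT summaries for a set of processed recordings
#'
#' @param processed list of `processed_recording`s.
#' @return data frame with one row per recording: `subject_id`,
#'   `recording_index`, `source`, `mean_cvt`, `sd_cvt`, `capacity`,
#'   `n_points`, `accepted`.
#' @export
summarize_recordings <- function(processed) {
  rows <- lapply(processed, function(p) {
    src <- if (identical(p$kind, "short_term")) "short_term" else "long_term"
    if (p$n_retained >= 2L) {
      s <- summarize_cvt(p$cvt$cvt, src)
      data.frame(subject_id = p$subject_id,
                 recording_index = p$recording_index,
                 source = src, mean_cvt = s$mean_cvt, sd_cvt = s$sd_cvt,
                 capacity = s$capacity, n_points = s$n_points,
                 accepted = p$accepted)
    } else {
      data.frame(subject_id = p$subject_id,
                 recording_index = p$recording_index,
                 source = src, mean_cvt = NA_real_, sd_cvt = NA_real_,
                 capacity = NA_real_, n_points = p$n_retained,
                 accepted = p$accepted)
    }
  })
  do.call(rbind, rows)
}
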