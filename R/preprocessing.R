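#' Instantaneous heart rate from RR intervals
#'
#' @param rr_ms RR intervals in milliseconds, all > 0.
#' @return heart rate in bpm, same length and order (`60000 / rr`).
#' @export
instantaneous_hr <- function(rr_ms) {
  if (any(rr_ms <= 0)) stop("rr intervals must be > 0")
  60000 / rr_ms
}

#' Estimate the missing-data fraction of a recording
#'
#' The expected beat count assumes at least one R-peak per second when the
#' mean heart rate is >= 60 bpm; below 60 bpm the expectation is scaled by
#' the mean heart rate (one beat per second no longer holds and would
#' overstate missingness). The fraction is clipped at 0 when observed beats
#' exceed expectation (mean HR > 60 yields more than one beat per second).
#'
#' @param rec a `night_recording` with at least 2 beats.
#' @return fraction of the session estimated missing, in \[0, 1\].
#' @export
estimate_missing_fraction <- function(rec) {
  b <- rec$beats
  if (nrow(b) < 2L) stop("insufficient beats (need >= 2)")
  duration <- rec$session_end - rec$session_start
  mean_hr <- mean(instantaneous_hr(b$rr))
  expected <- if (mean_hr >= 60) duration else duration * mean_hr / 60
  max(0, 1 - nrow(b) / expected)
}

#' Rolling-average CVT from raw vagal tone
#'
#' Each CVT value is the mean of a full window of `window` consecutive raw
#' values ending at the current beat; output is emitted only where a full
#' window exists, so the result has length `n - window + 1`.
#'
#' @param raw raw vagal-tone series.
#' @param window window length in beats (default 10).
#' @return rolled series of length `length(raw) - window + 1`; an empty
#'   vector with attribute `flagged = TRUE` if the input is too short.
#' @export
rolling_cvt <- function(raw, window = 10L) {
  n <- length(raw)
  if (n < window)
    return(structure(numeric(0), flagged = TRUE))
  cs <- cumsum(c(0, raw))
  (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
}

#' Trim edge points of a CVT series
#'
#' Drops exactly the first `n_trim` and last `n_trim` points, removing edge
#' artifacts of the rolling average.
#'
#' @param x series.
#' @param n_trim points to drop at each end (default 10).
#' @return trimmed series; empty with attribute `flagged = TRUE` if
#'   `length(x) <= 2 * n_trim`.
#' @export
trim_edges <- function(x, n_trim = 10L) {
  n <- length(x)
  if (n <= 2L * n_trim)
    return(structure(numeric(0), flagged = TRUE))
  x[(n_trim + 1L):(n - n_trim)]
}

#' Detect artifact beats from the heart-rate series
#'
#' A beat is an artifact iff its instantaneous heart rate exceeds the
#' previous beat's by strictly more than `jump` bpm. Decreases are never
#' flagged; an increase of exactly `jump` is not flagged.
#'
#' @param hr bpm series, length >= 2.
#' @param jump threshold in bpm (default 15).
#' @return 1-based indices of flagged beats (all >= 2).
#' @export
detect_artifacts <- function(hr, jump = 15) {
  if (length(hr) < 2L) return(integer(0))
  which(diff(hr) > jump) + 1L
}

#' Excise artifact windows from a series
#'
#' Removes, for each artifact index i, the window \[i - flank, i + flank\]
#' (the artifact itself, the `flank` preceding and the `flank` following
#' points), truncated at the series bounds; overlapping windows are unioned
#' so each point is removed once. Surviving order is preserved.
#'
#' @param x series.
#' @param idx artifact indices (1-based, within `x`); indices whose window
#'   falls entirely outside the series have no effect.
#' @param flank half-width of the excision window (default 7).
#' @return `x` with the excision union removed; attribute `n_removed` gives
#'   the count of removed points.
#' @export
excise_artifacts <- function(x, idx, flank = 7L) {
  n <- length(x)
  if (n == 0L || length(idx) == 0L)
    return(structure(x, n_removed = 0L))
  drop <- rep(FALSE, n)
  for (i in idx) {
    lo <- max(1L, i - flank)
    hi <- min(n, i + flank)
    if (lo <= hi) drop[lo:hi] <- TRUE
  }
  structure(x[!drop], n_removed = sum(drop))
}

#' Filter beats on the device signal-quality score
#'
#' Keeps exactly the beats whose quality score is at or above `threshold`
#' (the device rates each point 0..15; points scoring below 10 are removed
#' by default).
#'
#' @param x series (or data frame of beats) to filter.
#' @param quality integer quality scores aligned with `x`.
#' @param threshold minimum score kept (default 10).
#' @return the surviving elements/rows of `x`.
#' @export
quality_filter <- function(x, quality, threshold = 10L) {
  keep <- quality >= threshold
  if (is.data.frame(x)) x[keep, , drop = FALSE] else x[keep]
}

#' Process a recording through the full CVT cleaning pipeline
#'
#' Pipeline (in order of statement of the underlying protocol): 10-point
#' rolling average of the raw vagal tone; exclusion of the first and last 10
#' points; excision of artifact windows (artifacts detected on the raw
#' beat-to-beat heart-rate series as increases > `artifact_jump` bpm, mapped
#' to the surviving CVT positions, each removed with `excision_flank` points
#' on either side, overlapping windows unioned); removal of points whose
#' underlying beat has quality < `quality_min`; finally the retention
#' fraction is computed against the rolled-and-trimmed length and the
#' recording is accepted iff retention >= `retention_min`.
#'
#' @param rec a `night_recording`.
#' @param roll_window rolling-average window (default 10 beats).
#' @param edge_trim points dropped at each end after rolling (default 10).
#' @param artifact_jump artifact threshold in bpm (default 15).
#' @param excision_flank points removed on each side of an artifact
#'   (default 7).
#' @param quality_min minimum quality score kept (default 10).
#' @param retention_min minimum retained fraction for acceptance
#'   (default 0.70).
#' @return list of class `processed_recording` with the cleaned `cvt`
#'   series (`t`, `cvt`), counts (`n_raw`, `n_original`, `n_retained`),
#'   `retention`, `missing_fraction`, `accepted` and a per-stage
#'   `removal_log`.
#' @export
process_recording <- function(rec,
                              roll_window = 10L,
                              edge_trim = 10L,
                              artifact_jump = 15,
                              excision_flank = 7L,
                              quality_min = 10L,
                              retention_min = 0.70) {
  b <- rec$beats
  n_raw <- nrow(b)
  out <- list(subject_id = rec$subject_id,
              recording_index = rec$recording_index,
              kind = rec$kind %||% "night",
              n_raw = n_raw)
  min_len <- roll_window + 2L * edge_trim  # need > this many beats for any output

  if (n_raw < 2L) {
    out <- c(out, list(cvt = data.frame(t = numeric(0), cvt = numeric(0)),
                       n_original = 0L, n_retained = 0L, retention = 0,
                       missing_fraction = NA_real_, accepted = FALSE,
                       removal_log = c(rolling = 0L, edge = 0L,
                                       artifact = 0L, quality = 0L),
                       reject_reason = "too few beats"))
    class(out) <- "processed_recording"
    return(out)
  }
  out$missing_fraction <- estimate_missing_fraction(rec)

  rolled <- rolling_cvt(b$raw_lvs, roll_window)
  trimmed <- trim_edges(rolled, edge_trim)
  if (length(trimmed) == 0L) {
    out <- c(out, list(cvt = data.frame(t = numeric(0), cvt = numeric(0)),
                       n_original = 0L, n_retained = 0L, retention = 0,
                       accepted = FALSE,
                       removal_log = c(rolling = min(n_raw, roll_window - 1L),
                                       edge = max(0L, n_raw - roll_window + 1L),
                                       artifact = 0L, quality = 0L),
                       reject_reason = sprintf("recording too short (< %d beats)",
                                               min_len + 1L)))
    class(out) <- "processed_recording"
    return(out)
  }
  # position bookkeeping: trimmed position p corresponds to raw beat index
  # p + roll_window - 1 + edge_trim (the current beat of the rolling window)
  offset <- roll_window - 1L + edge_trim
  raw_idx <- seq_along(trimmed) + offset
  n_original <- length(trimmed)

  # artifacts are raw-beat phenomena: detect on the raw HR stream, map to
  # surviving CVT positions, excise with flanks
  art_raw <- detect_artifacts(instantaneous_hr(b$rr), artifact_jump)
  art_pos <- art_raw - offset
  art_pos <- art_pos[art_pos + excision_flank >= 1L &
                     art_pos - excision_flank <= n_original]
  keep1 <- rep(TRUE, n_original)
  for (p in art_pos) {
    lo <- max(1L, p - excision_flank)
    hi <- min(n_original, p + excision_flank)
    keep1[lo:hi] <- FALSE
  }
  n_art_removed <- sum(!keep1)
  surv <- trimmed[keep1]
  surv_raw_idx <- raw_idx[keep1]

  keep2 <- b$quality[surv_raw_idx] >= quality_min
  n_q_removed <- sum(!keep2)
  final <- surv[keep2]
  final_raw_idx <- surv_raw_idx[keep2]

  n_retained <- length(final)
  retention <- n_retained / n_original
  removal_log <- c(rolling = roll_window - 1L,
                   edge = 2L * edge_trim,
                   artifact = n_art_removed,
                   quality = n_q_removed)
  out <- c(out, list(
    cvt = data.frame(t = b$t[final_raw_idx], cvt = final),
    n_original = n_original,
    n_retained = n_retained,
    retention = retention,
    accepted = retention >= retention_min,
    removal_log = removal_log,
    reject_reason = if (retention >= retention_min) NA_character_
                    else sprintf("retention %.3f below %.2f", retention, retention_min)))
  class(out) <- "processed_recording"
  out
}

#' Raw-data quality report across recordings
#'
#' Descriptive statistics of the raw recordings before processing: number of
#' recordings, recording length, points per recording, estimated missing
#' data (%), and the percentage of beats at high signal quality (>= 13).
#'
#' @param recordings list of `night_recording`s (at least one).
#' @return list of class `raw_quality_report` with `n_recordings` and
#'   mean/SD pairs for each descriptive.
#' @export
summarize_raw <- function(recordings) {
  if (length(recordings) == 0L) stop("no recordings to summarize")
  len_s <- vapply(recordings, function(r) r$session_end - r$session_start, 0)
  pts <- vapply(recordings, function(r) nrow(r$beats), 0)
  miss <- vapply(recordings, function(r) {
    if (nrow(r$beats) < 2L) return(NA_real_)
    100 * estimate_missing_fraction(r)
  }, 0)
  hq <- vapply(recordings, function(r) {
    if (!nrow(r$beats)) return(NA_real_)
    100 * mean(r$beats$quality >= 13)
  }, 0)
  msd <- function(x) c(mean = mean(x, na.rm = TRUE),
                       sd = if (sum(!is.na(x)) > 1L) stats::sd(x, na.rm = TRUE) else 0)
  structure(list(
    n_recordings = length(recordings),
    length_s = msd(len_s),
    points = msd(pts),
    missing_pct = msd(miss),
    quality13_pct = msd(hq)), class = "raw_quality_report")
}

#' Select the best processed recording for a subject
#'
#' Deterministic proxy for manual best-recording selection: among accepted
#' recordings, choose the highest retention; break ties by the longest
#' retained series, then by the lowest recording index.
#'
#' @param processed list of `processed_recording`s for one subject.
#' @return the chosen `processed_recording`.
#' @export
select_best_recording <- function(processed) {
  acc <- Filter(function(p) isTRUE(p$accepted), processed)
  if (length(acc) == 0L) stop("no usable recording (none accepted)")
  ret <- vapply(acc, function(p) p$retention, 0)
  len <- vapply(acc, function(p) as.numeric(p$n_retained), 0)
  idx <- vapply(acc, function(p) as.numeric(p$recording_index), 0)
  acc[[order(-ret, -len, idx)[1L]]]
}
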