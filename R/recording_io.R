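#' Beat-series file dialect
#'
#' Recordings are stored as UTF-8, LF-terminated CSV with a `#key=value`
#' comment preamble carrying session metadata, followed by the header
#' `t_s,rr_ms,raw_lvs,quality` and one row per beat. Times are seconds from
#' session start (0-based, anonymizable), RR intervals are milliseconds,
#' raw vagal tone is in linear-vagal-scale units, quality is an integer
#' 0..15. Formatting is locale-independent and deterministic: t to 3
#' decimals (ms), rr to 1 decimal (0.1 ms), raw_lvs to 3 decimals.
#'
#' @name beat_series_dialect
#' @keywords internal
NULL

RECORDING_HEADER <- "t_s,rr_ms,raw_lvs,quality"

#' Write a recording to the beat-series CSV dialect
#'
#' Byte output is deterministic for a given recording (fixed column order,
#' fixed decimal formatting, "." decimal point regardless of locale).
#'
#' @param rec a `night_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  b <- rec$beats
  meta <- c(
    sprintf("#subject_id=%s", rec$subject_id),
    sprintf("#recording_index=%d", as.integer(rec$recording_index)),
    sprintf("#kind=%s", rec$kind %||% "night"),
    sprintf("#session_start=%.3f", rec$session_start),
    sprintf("#session_end=%.3f", rec$session_end),
    sprintf("#device_id=%s", rec$device_id %||% "unknown"))
  rows <- if (nrow(b)) {
    sprintf("%.3f,%.1f,%.3f,%d", b$t, b$rr, b$raw_lvs, as.integer(b$quality))
  } else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(meta, RECORDING_HEADER, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a recording from the beat-series CSV dialect
#'
#' Parses the `#key=value` preamble and the beat table, validating the type
#' invariants (rr > 0, quality in 0..15, raw_lvs >= 0, strictly increasing
#' timestamps within the declared session bounds). Malformed rows are
#' reported with their 1-based file line numbers.
#'
#' @param path file path.
#' @return a `night_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- startsWith(lines, "#")
  n_meta <- if (any(!is_meta)) which(!is_meta)[1L] - 1L else length(lines)
  meta_lines <- lines[seq_len(n_meta)]
  kv <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
  meta <- as.list(setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
                           vapply(kv, `[[`, "", 1L)))
  hdr_line <- n_meta + 1L
  if (hdr_line > length(lines) || lines[hdr_line] != RECORDING_HEADER)
    stop(sprintf("line %d: expected header '%s'", hdr_line, RECORDING_HEADER))
  body <- lines[-seq_len(hdr_line)]
  body <- body[nzchar(body)]
  if (length(body)) {
    beats <- utils::read.csv(text = paste(body, collapse = "\n"),
                             header = FALSE,
                             col.names = c("t", "rr", "raw_lvs", "quality"),
                             colClasses = c("numeric", "numeric", "numeric", "integer"))
  } else {
    beats <- data.frame(t = numeric(0), rr = numeric(0),
                        raw_lvs = numeric(0), quality = integer(0))
  }
  # validation with file line numbers (body row i is file line hdr_line + i)
  bad <- function(i) hdr_line + i
  if (nrow(beats)) {
    i <- which(!(beats$rr > 0))
    if (length(i)) stop(sprintf("line %d: rr_ms must be > 0", bad(i[1L])))
    i <- which(beats$quality < 0 | beats$quality > 15)
    if (length(i)) stop(sprintf("line %d: quality outside 0-15", bad(i[1L])))
    i <- which(beats$raw_lvs < 0)
    if (length(i)) stop(sprintf("line %d: raw_lvs must be >= 0", bad(i[1L])))
    if (nrow(beats) > 1L) {
      i <- which(diff(beats$t) <= 0)
      if (length(i)) stop(sprintf("line %d: timestamps not strictly increasing", bad(i[1L] + 1L)))
    }
  }
  sess_start <- as.numeric(meta[["session_start"]] %||% "0")
  sess_end <- as.numeric(meta[["session_end"]] %||% NA)
  if (is.na(sess_end)) sess_end <- if (nrow(beats)) max(beats$t) else 0
  if (nrow(beats) && (min(beats$t) < sess_start || max(beats$t) > sess_end))
    stop("beat timestamps outside declared session bounds")
  structure(list(
    subject_id = meta[["subject_id"]] %||% NA_character_,
    recording_index = as.integer(meta[["recording_index"]] %||% "1"),
    kind = meta[["kind"]] %||% "night",
    session_start = sess_start,
    session_end = sess_end,
    device_id = meta[["device_id"]] %||% "unknown",
    beats = beats,
    ground_truth = NULL), class = "night_recording")
}

#' Write / read the cohort metadata table
#'
#' Columns: `subject_id`, `group`, `cart_postural`, `cart_breathing`,
#' `cart_valsalva`, plus any optional extras (e.g. blood-pressure summaries
#' consumed by the clinical rules).
#'
#' @param meta data frame of subject metadata.
#' @param path file path.
#' @return `path` invisibly (write) or the parsed data frame (read).
#' @export
write_cohort_metadata <- function(meta, path) {
  required <- c("subject_id", "group", "cart_postural", "cart_breathing",
                "cart_valsalva")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop(sprintf("metadata missing column(s): %s", paste(missing, collapse = ", ")))
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_cohort_metadata
#' @export
read_cohort_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "cart_postural", "cart_breathing",
                "cart_valsalva")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop(sprintf("metadata missing column(s): %s", paste(missing, collapse = ", ")))
  for (cc in c("cart_postural", "cart_breathing", "cart_valsalva"))
    meta[[cc]] <- as.logical(meta[[cc]])
  meta
}

#' Write the ground-truth sidecar for a simulated recording
#'
#' JSON sidecar holding artifact indices/times, dropout spans and the sleep
#' stage track, used as an oracle by the preprocessing tests.
#'
#' @param rec a simulated `night_recording` carrying `ground_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(rec, path) {
  gt <- rec$ground_truth
  if (is.null(gt)) stop("recording carries no ground truth")
  jsonlite::write_json(list(
    subject_id = rec$subject_id,
    recording_index = rec$recording_index,
    artifact_idx = gt$artifact_idx,
    artifact_t = gt$artifact_t,
    dropout_spans = gt$dropout_spans,
    stage = gt$stage,
    night_level = gt$night_level
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
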