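#' Simulation configuration for a synthetic CVT screening cohort
#'
#' Builds and validates the parameter set governing cohort simulation. The
#' defaults describe the study design the package emulates: 20 controls and
#' 40 participants with type 2 diabetes, up to three overnight recordings
#' per subject (~7 h 14 min each), roughly 21% of each session lost to
#' contiguous dropouts (rolling off the sensor sheet), ~94% of beats at
#' signal quality >= 13, sparse heart-rate artifact beats, sleep-cycle
#' modulation of CVT (REM lowers parasympathetic tone, brief wake bouts
#' raise it), and night-to-night reliability of mean CVT near ICC 0.91.
#'
#' @param n_control,n_t2d number of control / type-2-diabetes subjects.
#' @param stage_probs named list (`control`, `t2d`) of probability vectors
#'   over CAN stages `none`, `early`, `manifest`; each must sum to 1.
#' @param group_mean_cvt named list (`control`, `t2d`) of mean overnight CVT
#'   levels (LVS) per CAN stage.
#' @param between_sd between-subject SD of the latent CVT intercept (LVS).
#' @param within_night_sd SD of the night-level offset (LVS); together with
#'   `between_sd` this sets the night-to-night ICC of mean CVT.
#' @param beat_noise_sd per-beat noise SD on the raw vagal tone (LVS).
#' @param sleep_cycle_minutes length of one non-REM/REM cycle.
#' @param rem_fraction fraction of each cycle spent in REM (end of cycle).
#' @param rem_cvt_reduction CVT drop during REM (LVS), floored at 0.
#' @param wake_cvt_elevation CVT elevation during wake bouts (LVS).
#' @param wake_bout_minutes length of the wake bout opening each sleep cycle
#'   after the first; 0 disables wake bouts.
#' @param base_hr resting heart rate (bpm) at `hr_cvt_ref` LVS.
#' @param hr_cvt_slope bpm decrease per LVS above `hr_cvt_ref` (heart rate
#'   falls as vagal tone rises).
#' @param hr_cvt_ref CVT level (LVS) at which heart rate equals `base_hr`.
#' @param artifact_rate per-beat probability of an artifact beat (a
#'   transiently shortened RR interval producing a >15 bpm jump).
#' @param dropout_rate expected fraction of the session lost to contiguous
#'   gaps.
#' @param n_dropout_gaps number of contiguous dropout gaps per night.
#' @param quality_high_frac fraction of beats with quality score in 13..15.
#' @param low_quality_burst_length typical run length (beats) of low-quality
#'   bursts.
#' @param session_length overnight session length in minutes.
#' @param nights_per_subject maximum night recordings per subject.
#' @param night_missing_rate probability that a scheduled night is missing
#'   entirely (device not used / failed).
#' @param short_term_offset LVS offset of the awake short-term level
#'   relative to the overnight intercept (negative: sleep CVT runs higher
#'   than awake CVT).
#' @param short_term_minutes length of the awake short-term recording.
#' @param seed master integer seed; all subject/night substreams derive
#'   from it deterministically.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_control = 20,
                       n_t2d = 40,
                       stage_probs = list(
                         control = c(none = 0.80, early = 0.15, manifest = 0.05),
                         t2d     = c(none = 0.475, early = 0.25, manifest = 0.275)),
                       group_mean_cvt = list(
                         control = c(none = 8.0, early = 5.5, manifest = 4.0),
                         t2d     = c(none = 7.1, early = 5.5, manifest = 4.0)),
                       between_sd = 2.0,
                       within_night_sd = 0.8,
                       beat_noise_sd = 1.5,
                       sleep_cycle_minutes = 90,
                       rem_fraction = 0.25,
                       rem_cvt_reduction = 2.0,
                       wake_cvt_elevation = 3.0,
                       wake_bout_minutes = 2,
                       base_hr = 60,
                       hr_cvt_slope = 0.5,
                       hr_cvt_ref = 8,
                       artifact_rate = 0.002,
                       dropout_rate = 0.208,
                       n_dropout_gaps = 3,
                       quality_high_frac = 0.937,
                       low_quality_burst_length = 20,
                       session_length = 434,
                       nights_per_subject = 3,
                       night_missing_rate = 0.089,
                       short_term_offset = -3.0,
                       short_term_minutes = 5,
                       seed = 20230214L) {
  cfg <- list(
    n_control = as.integer(n_control), n_t2d = as.integer(n_t2d),
    stage_probs = stage_probs, group_mean_cvt = group_mean_cvt,
    between_sd = between_sd, within_night_sd = within_night_sd,
    beat_noise_sd = beat_noise_sd,
    sleep_cycle_minutes = sleep_cycle_minutes, rem_fraction = rem_fraction,
    rem_cvt_reduction = rem_cvt_reduction,
    wake_cvt_elevation = wake_cvt_elevation,
    wake_bout_minutes = wake_bout_minutes,
    base_hr = base_hr, hr_cvt_slope = hr_cvt_slope, hr_cvt_ref = hr_cvt_ref,
    artifact_rate = artifact_rate, dropout_rate = dropout_rate,
    n_dropout_gaps = as.integer(n_dropout_gaps),
    quality_high_frac = quality_high_frac,
    low_quality_burst_length = as.integer(low_quality_burst_length),
    session_length = session_length,
    nights_per_subject = as.integer(nights_per_subject),
    night_missing_rate = night_missing_rate,
    short_term_offset = short_term_offset,
    short_term_minutes = short_term_minutes,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_control >= 0, cfg$n_t2d >= 0)
  nonneg <- c("between_sd", "within_night_sd", "beat_noise_sd",
              "rem_cvt_reduction", "wake_cvt_elevation", "wake_bout_minutes",
              "hr_cvt_slope", "artifact_rate", "dropout_rate",
              "quality_high_frac", "night_missing_rate")
  for (f in nonneg) {
    if (cfg[[f]] < 0) stop(sprintf("sim_config: '%s' must be >= 0", f))
  }
  for (f in c("artifact_rate", "dropout_rate", "quality_high_frac",
              "rem_fraction", "night_missing_rate")) {
    if (cfg[[f]] > 1) stop(sprintf("sim_config: '%s' must be <= 1", f))
  }
  for (g in c("control", "t2d")) {
    p <- cfg$stage_probs[[g]]
    if (is.null(p) || !all(c("none", "early", "manifest") %in% names(p)))
      stop("sim_config: stage_probs must name none/early/manifest per group")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(sprintf("sim_config: stage_probs for '%s' must be >= 0 and sum to 1", g))
    m <- cfg$group_mean_cvt[[g]]
    if (is.null(m) || any(m < 0))
      stop("sim_config: group_mean_cvt must be >= 0 (the LVS has an absolute zero)")
  }
  stopifnot(cfg$session_length > 0, cfg$sleep_cycle_minutes > 0,
            cfg$base_hr > 0, cfg$nights_per_subject >= 1)
  invisible(cfg)
}

CAN_STAGES <- c("none", "early", "manifest")
CART_NAMES <- c("cart_postural", "cart_breathing", "cart_valsalva")

#' Generate one subject profile
#'
#' Draws a CAN stage from the group's stage probabilities, a latent overnight
#' CVT intercept from a normal distribution around the group-by-stage mean
#' (hard-floored at 0: the linear vagal scale has an absolute zero), and a
#' set of cardiovascular autonomic reflex test (CART) abnormality flags whose
#' count is consistent with the stage (0 abnormal = none, 1 = early,
#' >= 2 = manifest).
#'
#' Uses the current R random stream; callers wanting reproducibility set the
#' seed (as [generate_cohort()] does per subject).
#'
#' @param config a [sim_config()].
#' @param group `"control"` or `"t2d"`.
#' @param subject_id identifier; autogenerated if `NULL`.
#' @param stage optional fixed CAN stage overriding the stage draw.
#' @return list of class `subject_profile`.
#' @export
generate_subject <- function(config, group, subject_id = NULL, stage = NULL) {
  validate_sim_config(config)
  if (!group %in% c("control", "t2d"))
    stop(sprintf("unknown group label '%s' (expected 'control' or 't2d')", group))
  if (is.null(stage)) {
    p <- config$stage_probs[[group]][CAN_STAGES]
    stage <- sample(CAN_STAGES, 1L, prob = p)
  }
  stage <- match.arg(stage, CAN_STAGES)
  mu <- config$group_mean_cvt[[group]][[stage]]
  intercept <- max(0, rnorm(1L, mu, config$between_sd))
  n_abn <- switch(stage, none = 0L, early = 1L, manifest = sample(2:3, 1L))
  cart <- rep(FALSE, 3L)
  if (n_abn > 0) cart[sample.int(3L, n_abn)] <- TRUE
  names(cart) <- CART_NAMES
  if (is.null(subject_id)) subject_id <- sprintf("S%04d", sample.int(9999L, 1L))
  structure(list(
    subject_id = subject_id, group = group, can_stage = stage,
    cart_abnormal = cart,
    subject_intercept = intercept,
    assigned_mean_cvt = mu), class = "subject_profile")
}

# Sleep stage at each time point (seconds): cycles of non-REM then REM, a
# wake bout opening every cycle after the first. Deterministic template --
# stage-dependent CVT levels are what the analysis needs, not a realistic
# hypnogram.
stage_at_time <- function(t_s, config) {
  cyc <- config$sleep_cycle_minutes * 60
  wake <- config$wake_bout_minutes * 60
  pos <- t_s %% cyc
  cycle_idx <- floor(t_s / cyc)
  rem_start <- cyc * (1 - config$rem_fraction)
  stage <- rep("nrem", length(t_s))
  stage[pos >= rem_start] <- "rem"
  stage[cycle_idx >= 1 & pos < wake] <- "wake"
  stage
}

# Beat-level series construction shared by night and short-term generators.
# Levels drive both the raw vagal tone and (inversely, small slope) the RR
# intervals; timestamps are the cumulative sum of RR.
build_beat_series <- function(level, config) {
  n <- length(level)
  raw_lvs <- pmax(0, level + rnorm(n, 0, config$beat_noise_sd))
  hr <- pmax(30, config$base_hr - config$hr_cvt_slope * (level - config$hr_cvt_ref))
  rr <- 60000 / hr
  list(raw_lvs = raw_lvs, hr = hr, rr = rr)
}

#' Generate one overnight recording for a subject
#'
#' Produces an ordered beat series over the configured session length with:
#' a night-level offset on the subject's latent CVT intercept; alternating
#' non-REM / REM sleep architecture (REM lowers CVT by `rem_cvt_reduction`,
#' floored at 0) plus brief wake bouts at `+wake_cvt_elevation`; per-beat
#' Gaussian noise floored at 0; RR intervals inversely coupled to the CVT
#' level around `base_hr`; artifact beats (single shortened RR intervals
#' giving beat-to-beat heart-rate jumps > 15 bpm) injected at
#' `artifact_rate`; contiguous dropout gaps totalling about `dropout_rate`
#' of the session; and quality scores with `quality_high_frac` of beats in
#' 13..15 and the remainder spread over 0..12 in bursts.
#'
#' Ground truth (artifact positions, dropout spans, stage track) is attached
#' for use as a test oracle.
#'
#' @param subject a `subject_profile`.
#' @param config a [sim_config()].
#' @param night_index recording number, >= 1.
#' @return list of class `night_recording` with a `beats` data frame
#'   (`t`, `rr`, `raw_lvs`, `quality`) and a `ground_truth` list.
#' @export
generate_night <- function(subject, config, night_index = 1L) {
  validate_sim_config(config)
  if (night_index < 1) stop("night_index must be >= 1")
  if (config$session_length < config$sleep_cycle_minutes)
    stop("session shorter than one sleep cycle")
  sess_s <- config$session_length * 60

  night_offset <- rnorm(1L, 0, config$within_night_sd)
  base_level <- max(0, subject$subject_intercept + night_offset)

  # provisional evenly spaced beat grid to assign sleep stages; final
  # timestamps are recomputed from the level-dependent RR intervals
  hr0 <- max(30, config$base_hr - config$hr_cvt_slope * (base_level - config$hr_cvt_ref))
  n0 <- ceiling(sess_s * hr0 / 60 * 1.25) + 30L
  t_prelim <- (seq_len(n0) - 1) * (60 / hr0)
  stage <- stage_at_time(t_prelim, config)
  level <- base_level +
    (stage == "wake") * config$wake_cvt_elevation -
    (stage == "rem") * config$rem_cvt_reduction
  level <- pmax(0, level)

  series <- build_beat_series(level, config)
  rr <- series$rr

  # artifacts: isolated shortened RR intervals; the jump is drawn strictly
  # above the 15 bpm rule so every injected artifact is detectable
  is_art <- runif(n0) < config$artifact_rate
  is_art[1L] <- FALSE
  w <- which(is_art)
  if (length(w) > 1L) is_art[w[which(diff(w) == 1L) + 1L]] <- FALSE  # no adjacent pairs
  art_idx <- which(is_art)
  if (length(art_idx)) {
    hr_prev <- series$hr[art_idx - 1L]
    hr_art <- hr_prev + 15 + runif(length(art_idx), 1, 20)
    rr[art_idx] <- 60000 / hr_art
  }

  t <- cumsum(rr) / 1000
  keep <- t <= sess_s
  t <- t[keep]
  n <- length(t)
  raw_lvs <- series$raw_lvs[seq_len(n)]
  rr <- rr[seq_len(n)]
  stage <- stage[seq_len(n)]
  is_art <- is_art[seq_len(n)]

  # contiguous dropout gaps: one gap per equal segment of the session, so
  # gaps never overlap and total ~= dropout_rate * session
  dropout_spans <- NULL
  if (config$dropout_rate > 0 && config$n_dropout_gaps > 0) {
    ng <- config$n_dropout_gaps
    gap_len <- config$dropout_rate * sess_s / ng
    seg <- sess_s / ng
    starts <- (seq_len(ng) - 1) * seg + runif(ng, 0, pmax(0, seg - gap_len))
    dropout_spans <- data.frame(start = starts, end = starts + gap_len)
    in_gap <- rep(FALSE, n)
    for (g in seq_len(ng))
      in_gap <- in_gap | (t >= dropout_spans$start[g] & t < dropout_spans$end[g])
    t <- t[!in_gap]; raw_lvs <- raw_lvs[!in_gap]; rr <- rr[!in_gap]
    stage <- stage[!in_gap]; is_art <- is_art[!in_gap]
    n <- length(t)
  }

  quality <- draw_quality(n, config)

  beats <- data.frame(t = t, rr = rr, raw_lvs = raw_lvs, quality = quality)
  gt <- list(
    artifact_idx = which(is_art),
    artifact_t = t[is_art],
    dropout_spans = dropout_spans,
    stage = stage,
    night_level = base_level)
  structure(list(
    subject_id = subject$subject_id,
    recording_index = as.integer(night_index),
    kind = "night",
    session_start = 0,
    session_end = sess_s,
    device_id = "sim-sheet-1",
    beats = beats,
    ground_truth = gt), class = "night_recording")
}

# quality scores: high fraction in 13..15, remainder in 0..12 placed in
# contiguous bursts (poor sheet contact is episodic, not white noise)
draw_quality <- function(n, config) {
  if (n == 0L) return(integer(0))
  quality <- sample(13:15, n, replace = TRUE)
  n_low <- round((1 - config$quality_high_frac) * n)
  if (n_low > 0) {
    low <- logical(n)
    guard <- 0L
    while (sum(low) < n_low && guard < 10000L) {
      s <- sample.int(n, 1L)
      len <- min(config$low_quality_burst_length, n_low - sum(low))
      idx <- s:min(n, s + len - 1L)
      low[idx] <- TRUE
      guard <- guard + 1L
    }
    quality[low] <- sample(0:12, sum(low), replace = TRUE)
  }
  quality
}

#' Generate a short-term awake recording
#'
#' A 5-minute (by default) awake resting beat series with no sleep
#' architecture, artifacts or dropouts. The awake level is the subject's
#' latent intercept plus `short_term_offset` (negative by default: overnight
#' CVT runs higher than awake CVT because parasympathetic activity rises
#' during sleep).
#'
#' @inheritParams generate_night
#' @return a `night_recording` with `kind = "short_term"`.
#' @export
generate_short_term <- function(subject, config) {
  validate_sim_config(config)
  sess_s <- config$short_term_minutes * 60
  level0 <- max(0, subject$subject_intercept + config$short_term_offset)
  hr0 <- max(30, config$base_hr - config$hr_cvt_slope * (level0 - config$hr_cvt_ref))
  n0 <- ceiling(sess_s * hr0 / 60 * 1.25) + 30L
  series <- build_beat_series(rep(level0, n0), config)
  t <- cumsum(series$rr) / 1000
  keep <- t <= sess_s
  n <- sum(keep)
  beats <- data.frame(t = t[keep], rr = series$rr[keep],
                      raw_lvs = series$raw_lvs[keep],
                      quality = draw_quality(n, config))
  structure(list(
    subject_id = subject$subject_id,
    recording_index = 0L,
    kind = "short_term",
    session_start = 0,
    session_end = sess_s,
    device_id = "sim-monitor-1",
    beats = beats,
    ground_truth = list(artifact_idx = integer(0), artifact_t = numeric(0),
                        dropout_spans = NULL, stage = rep("wake", n),
                        night_level = level0)), class = "night_recording")
}

#' Generate a full synthetic cohort
#'
#' Deterministic given `config$seed`: each subject (and each of their
#' recordings) is generated from a substream seeded by a fixed function of
#' the master seed and the subject index, so cohorts are reproducible
#' beat-for-beat. Each subject receives up to `nights_per_subject` overnight
#' recordings (scheduled nights are independently missing with probability
#' `night_missing_rate`, emulating real-world attrition) and one short-term
#' awake recording.
#'
#' @param config a [sim_config()].
#' @return list of class `cohort` with elements `subjects` (data frame of
#'   profiles), `recordings` (list of overnight `night_recording`s),
#'   `short_term` (list of short-term recordings) and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  groups <- c(rep("control", config$n_control), rep("t2d", config$n_t2d))
  ids <- c(sprintf("C%03d", seq_len(config$n_control)),
           sprintf("D%03d", seq_len(config$n_t2d)))
  subjects <- vector("list", length(groups))
  recordings <- list()
  short_term <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    set.seed(subseed(config$seed, i))
    subj <- generate_subject(config, groups[i], subject_id = ids[i])
    subjects[[i]] <- subj
    for (k in seq_len(config$nights_per_subject)) {
      if (runif(1) < config$night_missing_rate) next
      recordings[[length(recordings) + 1L]] <- generate_night(subj, config, k)
    }
    short_term[[i]] <- generate_short_term(subj, config)
  }
  meta <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group,
               can_stage = s$can_stage,
               cart_postural = s$cart_abnormal[["cart_postural"]],
               cart_breathing = s$cart_abnormal[["cart_breathing"]],
               cart_valsalva = s$cart_abnormal[["cart_valsalva"]],
               subject_intercept = s$subject_intercept)
  }))
  structure(list(subjects = meta, profiles = subjects,
                 recordings = recordings, short_term = short_term,
                 config = config), class = "cohort")
}

# deterministic per-subject substream seed, kept below 2^31
subseed <- function(master, i) {
  as.integer((as.numeric(master) + 7919 * as.numeric(i)) %% 2147483647)
}
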