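test_that("instantaneous_hr converts RR intervals elementwise", {
  expect_identical(instantaneous_hr(1000), 60)
  expect_identical(instantaneous_hr(800), 75)
  expect_identical(instantaneous_hr(c(1000, 750)), c(60, 80))
  expect_error(instantaneous_hr(c(1000, 0)), "> 0")
})

test_that("estimate_missing_fraction reproduces both HR branches", {
  mk <- function(duration, rr_ms, n_beats) {
    structure(list(session_start = 0, session_end = duration,
                   beats = data.frame(t = seq_len(n_beats) * rr_ms / 1000,
                                      rr = rep(rr_ms, n_beats),
                                      raw_lvs = rep(5, n_beats),
                                      quality = rep(15L, n_beats))),
              class = "night_recording")
  }
  expect_equal(estimate_missing_fraction(mk(3600, 1000, 3600)), 0)
  # mean HR 72 >= 60 -> expected = D = 7200; 5760 observed -> 0.20
  expect_equal(estimate_missing_fraction(mk(7200, 60000 / 72, 5760)), 0.20)
  # mean HR 50 < 60 -> expected = 3600 * 50/60 = 3000; 2400 observed -> 0.20
  expect_equal(estimate_missing_fraction(mk(3600, 1200, 2400)), 0.20)
  # more beats than expected clips at 0
  expect_equal(estimate_missing_fraction(mk(3600, 800, 4500)), 0)
  expect_error(estimate_missing_fraction(mk(10, 1000, 1)), "insufficient beats")
})

test_that("rolling_cvt equals full-window means", {
  expect_equal(rolling_cvt(rep(5, 50)), rep(5, 41))
  expect_equal(rolling_cvt(1:20)[1], 5.5)
  set.seed(31)
  x <- rnorm(200)
  brute <- sapply(10:200, function(i) mean(x[(i - 9):i]))
  expect_equal(rolling_cvt(x), brute)
  short <- rolling_cvt(rnorm(5))
  expect_length(short, 0)
  expect_true(attr(short, "flagged"))
})

test_that("trim_edges drops exactly 10 points at each end", {
  expect_length(trim_edges(1:100), 80)
  expect_identical(trim_edges(1:100), 11:90)
  expect_identical(trim_edges(1:21), 11L)
  out <- trim_edges(1:20)
  expect_length(out, 0)
  expect_true(attr(out, "flagged"))
})

test_that("artifact rule is strict >15 bpm on increases only", {
  expect_identical(detect_artifacts(c(60, 76, 60)), 2L)
  expect_identical(detect_artifacts(c(60, 75)), integer(0))
  expect_identical(detect_artifacts(c(80, 60, 80)), 3L)
  expect_identical(detect_artifacts(c(60, 75.0001)), 2L)
})

test_that("excise_artifacts removes ±7 windows with union semantics", {
  x <- 1:100
  out <- excise_artifacts(x, 51L)  # 0-based index 50
  expect_length(out, 85)
  expect_identical(attr(out, "n_removed"), 15L)
  expect_false(any(44:58 %in% out))

  out2 <- excise_artifacts(x, c(51L, 56L))
  expect_length(out2, 80)
  expect_false(any(44:63 %in% out2))

  out3 <- excise_artifacts(x, 4L)  # 0-based index 3: boundary truncation
  expect_length(out3, 89)
  expect_identical(out3[1], 12L)

  # idempotence: re-excising with no indices changes nothing
  expect_identical(as.integer(excise_artifacts(out2, integer(0))),
                   as.integer(out2))
})

test_that("quality_filter keeps exactly scores >= 10 and is idempotent", {
  q <- c(15L, 14L, 9L, 10L, 3L)
  expect_identical(quality_filter(q, q), c(15L, 14L, 10L))
  expect_identical(quality_filter(1:5, rep(15L, 5)), 1:5)
  expect_length(quality_filter(1:5, rep(0L, 5)), 0)
  once <- quality_filter(q, q)
  expect_identical(quality_filter(once, once), once)
})

test_that("process_recording on clean input removes exactly the edges", {
  n <- 200L
  rec <- structure(list(subject_id = "clean", recording_index = 1L,
                        kind = "night", session_start = 0, session_end = n + 1,
                        beats = data.frame(t = 1:n, rr = rep(1000, n),
                                           raw_lvs = rep(6, n),
                                           quality = rep(15L, n))),
                   class = "night_recording")
  p <- process_recording(rec)
  expect_identical(p$n_original, n - 9L - 20L)
  expect_identical(p$n_retained, p$n_original)
  expect_identical(p$retention, 1)
  expect_true(p$accepted)
  expect_identical(unname(p$removal_log), c(9L, 20L, 0L, 0L))
  expect_true(all(p$cvt$cvt == 6))
})

test_that("bookkeeping conservation and ground-truth artifact exclusion hold", {
  cfg <- tiny_config(artifact_rate = 0.004)
  co <- generate_cohort(cfg)
  for (rec in co$recordings[1:4]) {
    p <- process_recording(rec)
    expect_identical(p$n_raw - sum(p$removal_log), p$n_retained)
    # no retained CVT point coincides with a ground-truth artifact beat
    expect_false(any(rec$ground_truth$artifact_t %in% p$cvt$t))
  }
})

test_that("the 70% retention rule is a strict boundary", {
  # engineer retention via low-quality beats: n_original = 71 from n_raw = 100
  mk <- function(n_bad) {
    n <- 100L
    q <- rep(15L, n)
    if (n_bad > 0) q[20 + seq_len(n_bad)] <- 5L  # inside the surviving window
    structure(list(subject_id = "B", recording_index = 1L, kind = "night",
                   session_start = 0, session_end = n + 1,
                   beats = data.frame(t = 1:n, rr = rep(1000, n),
                                      raw_lvs = rep(6, n), quality = q)),
              class = "night_recording")
  }
  p_pass <- process_recording(mk(21L))  # 50/71 = 0.704 >= 0.70
  expect_true(p_pass$accepted)
  p_fail <- process_recording(mk(22L))  # 49/71 = 0.690 < 0.70
  expect_false(p_fail$accepted)
  expect_match(p_fail$reject_reason, "retention")
})

test_that("too-short recordings are rejected with a reason", {
  rec <- make_small_recording(25)
  p <- process_recording(rec)
  expect_false(p$accepted)
  expect_match(p$reject_reason, "too short")
})

test_that("summarize_raw aggregates descriptives correctly", {
  mk <- function(rr_ms, n, dur, q) {
    structure(list(session_start = 0, session_end = dur,
                   beats = data.frame(t = seq_len(n) * rr_ms / 1000,
                                      rr = rep(rr_ms, n), raw_lvs = rep(5, n),
                                      quality = q)),
              class = "night_recording")
  }
  r1 <- mk(1000, 3240, 3600, rep(15L, 3240))              # missing 10%
  r2 <- mk(1000, 2520, 3600, rep(c(15L, 5L), 1260))        # missing 30%, 50% hq
  rep_ <- summarize_raw(list(r1, r2))
  expect_identical(rep_$n_recordings, 2L)
  expect_equal(unname(rep_$missing_pct["mean"]), 20)
  expect_equal(unname(rep_$quality13_pct["mean"]), 75)
  expect_equal(unname(rep_$points["mean"]), 2880)
  expect_error(summarize_raw(list()), "no recordings")
})

test_that("full-length synthetic nights reproduce the configured missing-data regime", {
  cfg <- sim_config(n_control = 4, n_t2d = 4, nights_per_subject = 2,
                    night_missing_rate = 0, seed = 88L)  # dropout_rate 0.208
  co <- generate_cohort(cfg)
  rep_ <- summarize_raw(co$recordings)
  expect_lt(abs(rep_$missing_pct[["mean"]] - 20.8), 3)
  expect_gt(rep_$quality13_pct[["mean"]], 88)
})

test_that("select_best_recording applies the deterministic tie-breaks", {
  mk <- function(ret, n_ret, idx, acc = TRUE)
    structure(list(subject_id = "S", recording_index = as.integer(idx), retention = ret,
                   n_retained = n_ret, accepted = acc),
              class = "processed_recording")
  expect_identical(select_best_recording(list(mk(0.8, 100, 1)))$recording_index, 1L)
  expect_identical(select_best_recording(
    list(mk(0.80, 100, 1), mk(0.95, 90, 2)))$recording_index, 2L)
  expect_identical(select_best_recording(
    list(mk(0.9, 18000, 1), mk(0.9, 20000, 2)))$recording_index, 2L)
  expect_identical(select_best_recording(
    list(mk(0.9, 100, 2), mk(0.9, 100, 1)))$recording_index, 1L)
  expect_error(select_best_recording(list(mk(0.5, 10, 1, acc = FALSE))),
               "no usable recording")
})
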