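test_that("stage_can counts abnormal reflex tests", {
  expect_identical(stage_can(c(FALSE, FALSE, FALSE)), "none")
  expect_identical(stage_can(c(TRUE, FALSE, FALSE)), "early")
  expect_identical(stage_can(c(FALSE, TRUE, FALSE)), "early")
  expect_identical(stage_can(c(TRUE, TRUE, FALSE)), "manifest")
  expect_identical(stage_can(c(TRUE, TRUE, TRUE)), "manifest")
  expect_error(stage_can(c(TRUE, NA, FALSE)), "non-missing")
})

test_that("orthostatic classification follows drop thresholds and windows", {
  base <- c(130, 80)
  rd <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(minute = m[, 1], sys = m[, 2], dia = m[, 3])
  }
  expect_identical(classify_orthostatic(base, rd(0.5, 105, 78)), "initial")
  expect_identical(classify_orthostatic(base, rd(2, 108, 75)), "classic")
  expect_identical(classify_orthostatic(base, rd(5, 125, 68)), "delayed")
  expect_identical(classify_orthostatic(base, rd(1, 140, 82, 9, 108, 79)), "delayed")
  # boundaries: drops of exactly 20/10 qualify; 15/8 does not
  expect_identical(classify_orthostatic(base, rd(2, 110, 79)), "classic")
  expect_identical(classify_orthostatic(base, rd(2, 115, 72)), "none")
  # earliest qualifying reading wins even if supplied out of order
  expect_identical(classify_orthostatic(base, rd(5, 105, 70, 0.4, 104, 78)), "initial")
  expect_error(classify_orthostatic(base, rd(11, 100, 70)), "0-10")
  expect_error(classify_orthostatic(base, rd(numeric(0))), "no standing readings")
})

test_that("reverse dipping uses the >=10% rise rule in either component", {
  expect_true(is_reverse_dipper(c(120, 80), c(133, 78)))
  expect_true(is_reverse_dipper(c(120, 80), c(132, 80)))   # exactly +10%
  expect_false(is_reverse_dipper(c(120, 80), c(125, 82)))
  expect_true(is_reverse_dipper(c(120, 80), c(110, 88)))   # diastolic route
  expect_error(is_reverse_dipper(c(0, 80), c(110, 88)), "positive")
})

test_that("roc_points spans (0,0)-(1,1) monotonically, both orientations", {
  pts <- roc_points(c(2, 3, 6, 7), c(TRUE, TRUE, FALSE, FALSE), "lower")
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  expect_true(any(pts$fpr == 0 & pts$tpr == 1))  # perfect separation corner
  expect_error(roc_points(1:3, c(TRUE, TRUE, TRUE)), "case and one control")
})

test_that("roc_auc matches hand-worked values and symmetries", {
  expect_equal(roc_auc(c(2, 3, 6, 7), c(TRUE, TRUE, FALSE, FALSE), "lower"), 1)
  expect_equal(roc_auc(rep(4, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), "lower"), 0.5)
  # cases {3,4,5} vs controls {1,2,3}, higher-is-positive: 8.5/9 by pair counting
  expect_equal(roc_auc(c(3, 4, 5, 1, 2, 3),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), "higher"),
               8.5 / 9)
  set.seed(61)
  for (i in 1:20) {
    sc <- sample(1:8, 12, replace = TRUE)
    lb <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    if (!any(lb) || all(lb)) next
    expect_equal(roc_auc(sc, lb, "lower"), 1 - roc_auc(sc, lb, "higher"))
    expect_equal(roc_auc(sc, lb, "lower"), pair_auc(sc, lb, "lower"))
  }
})

test_that("delong_ci: zero variance at perfect separation, brute-force equality", {
  d <- delong_ci(c(1, 2, 8, 9), c(TRUE, TRUE, FALSE, FALSE), "lower")
  expect_equal(d$auc, 1)
  expect_equal(d$var, 0)
  expect_equal(d$ci, c(1, 1))
  set.seed(62)
  for (i in 1:30) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    sc <- c(rnorm(m, 4, 2), rnorm(n, 6, 2))
    sc[sample(m + n, 2)] <- 5  # inject ties
    lb <- c(rep(TRUE, m), rep(FALSE, n))
    got <- delong_ci(sc, lb, "lower")
    want <- delong_brute(sc, lb, "lower")
    expect_equal(got$auc, want$auc, tolerance = 1e-12)
    expect_equal(got$var, want$var, tolerance = 1e-12)
  }
  expect_error(delong_ci(c(1, 5, 6), c(TRUE, FALSE, FALSE)), ">= 2 cases")
})

test_that("youden_cutoff attains the exhaustive-scan maximum", {
  y <- youden_cutoff(c(2, 3, 6, 7), c(TRUE, TRUE, FALSE, FALSE), "lower")
  expect_equal(y$cutoff, 3)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 1)
  u <- youden_cutoff(rep(4, 4), c(TRUE, TRUE, FALSE, FALSE), "lower")
  expect_equal(u$j, 0)
  set.seed(63)
  for (i in 1:40) {
    sc <- sample(seq(1, 5, 0.5), 12, replace = TRUE)
    lb <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    if (!any(lb) || all(lb)) next
    got <- youden_cutoff(sc, lb, "lower")
    expect_equal(got$j, youden_brute(sc, lb, "lower"), tolerance = 1e-12)
    expect_true(got$cutoff %in% got$tied_cutoffs)
  }
})

test_that("confusion_at_cutoff reproduces 2x2 table arithmetic", {
  # TP=5 FN=1 FP=7 TN=18 at cutoff 0 with lower orientation
  sc <- c(rep(-1, 5), rep(1, 1), rep(-1, 7), rep(1, 18))
  lb <- c(rep(TRUE, 6), rep(FALSE, 25))
  cm <- confusion_at_cutoff(sc, lb, 0, "lower")
  expect_equal(cm$sensitivity, 5 / 6)
  expect_equal(cm$specificity, 18 / 25)
  expect_equal(cm$ppv, 5 / 12)
  expect_equal(cm$npv, 18 / 19)
  expect_equal(cm$fpr, 1 - 18 / 25)
  expect_equal(cm$tpr, 5 / 6)

  perfect <- confusion_at_cutoff(c(1, 2, 8, 9), c(TRUE, TRUE, FALSE, FALSE), 3, "lower")
  expect_true(all(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv")]) == 1))

  none_pos <- confusion_at_cutoff(c(5, 6, 7, 8), c(TRUE, FALSE, FALSE, FALSE), 1, "lower")
  expect_true(is.na(none_pos$ppv))
  expect_equal(none_pos$npv, 3 / 4)
})

test_that("orientation reversal swaps the roles of the classes", {
  set.seed(64)
  sc <- rnorm(20); lb <- rep(c(TRUE, FALSE), 10)
  expect_equal(delong_ci(sc, lb, "lower")$auc, 1 - delong_ci(sc, lb, "higher")$auc)
  cml <- confusion_at_cutoff(sc, lb, 0.3, "lower")
  cmh <- confusion_at_cutoff(sc, !lb, 0.3, "lower")
  expect_equal(cml$sensitivity, 1 - cmh$specificity)
})

test_that("evaluate_biomarkers builds the ROC table with correct contrasts", {
  staging <- data.frame(
    subject_id = sprintf("S%02d", 1:12),
    can_stage = c(rep("none", 6), rep("early", 3), rep("manifest", 3)))
  set.seed(65)
  bm <- data.frame(
    subject_id = staging$subject_id,
    short_mean = c(rnorm(6, 5), rnorm(3, 4), rnorm(3, 2)),
    long_mean = c(rnorm(6, 8), rnorm(3, 6), rnorm(3, 4)),
    long_capacity = c(rnorm(6, 19), rnorm(3, 15), rnorm(3, 12)))
  res <- evaluate_biomarkers(bm, staging)
  expect_identical(nrow(res), 9L)
  expect_identical(res$n_cases[res$outcome == "any_can"], rep(6L, 3))
  # early contrast excludes manifest subjects from both sides
  expect_identical(res$n_cases[res$outcome == "early_can"], rep(3L, 3))
  expect_identical(res$n_controls[res$outcome == "early_can"], rep(6L, 3))
  expect_true(all(res$ci_low <= res$auc & res$auc <= res$ci_high))
  expect_equal(res$fpr, 1 - res$specificity)
  expect_equal(res$tpr, res$sensitivity)
  # manually recompute one cell
  manifest <- bm$long_mean[staging$can_stage %in% c("none", "manifest")]
  mlab <- staging$can_stage[staging$can_stage %in% c("none", "manifest")] == "manifest"
  expect_equal(res$auc[res$outcome == "manifest_can" & res$biomarker == "long_mean"],
               roc_auc(manifest, mlab, "lower"))
})

test_that("evaluate_biomarkers flags thin outcomes and drops NA pairwise", {
  staging <- data.frame(subject_id = sprintf("S%02d", 1:8),
                        can_stage = c(rep("none", 6), "early", "manifest"))
  bm <- data.frame(subject_id = staging$subject_id,
                   short_mean = c(1:5, NA, 2, 1),
                   long_mean = c(6:11, 4, 3),
                   long_capacity = rep(NA_real_, 8))
  res <- evaluate_biomarkers(bm, staging)
  early_row <- res[res$outcome == "early_can" & res$biomarker == "short_mean", ]
  expect_true(early_row$unreliable)
  expect_identical(early_row$n_controls, 5L)  # NA dropped pairwise
  expect_false(is.na(early_row$auc))          # still computed, not dropped
  cap_row <- res[res$outcome == "any_can" & res$biomarker == "long_capacity", ]
  expect_true(cap_row$unreliable)
  expect_true(is.na(cap_row$auc))
})
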