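#' Per-subject biomarker table from recording summaries
#'
#' Assembles one row per subject with the short-term mean CVT and the
#' long-term (overnight) mean CVT and CVT capacity of the subject's best
#' accepted recording.
#'
#' @param summary_table output of [summarize_recordings()] for the
#'   *selected* long-term recordings plus the short-term recordings (one
#'   row per subject per source).
#' @return data frame with columns `subject_id`, `short_mean`, `long_mean`,
#'   `long_capacity`.
#' @export
build_biomarker_table <- function(summary_table) {
  ids <- unique(summary_table$subject_id)
  pick <- function(id, src, col) {
    r <- summary_table[summary_table$subject_id == id &
                       summary_table$source == src, col]
    if (length(r) == 0L) NA_real_ else r[1L]
  }
  data.frame(
    subject_id = ids,
    short_mean = vapply(ids, pick, 0, src = "short_term", col = "mean_cvt"),
    long_mean = vapply(ids, pick, 0, src = "long_term", col = "mean_cvt"),
    long_capacity = vapply(ids, pick, 0, src = "long_term", col = "capacity"))
}

#' Diagnostic performance of CVT biomarkers against CAN staging
#'
#' For each biomarker (short-term mean, long-term mean, long-term capacity)
#' and each outcome contrast — any CAN (early or manifest vs none), early
#' CAN (early vs none, manifest subjects excluded from both sides) and
#' manifest CAN (manifest vs none, early excluded) — computes the AUC with
#' its DeLong 95% confidence interval, the Youden-index cut-off and the
#' confusion metrics at that cut-off (predictive values at sample
#' prevalence). CVT biomarkers use the lower-is-positive orientation:
#' autonomic neuropathy lowers vagal tone. Missing biomarker values are
#' dropped pairwise per model. An outcome with fewer than 2 cases or 2
#' controls is flagged `unreliable` (AUC still reported when computable)
#' rather than dropped.
#'
#' @param biomarker_table data frame from [build_biomarker_table()].
#' @param staging data frame with columns `subject_id`, `can_stage`
#'   (`none` / `early` / `manifest`).
#' @param biomarkers biomarker columns to evaluate.
#' @param outcomes outcome contrasts to evaluate.
#' @param direction score orientation passed to the ROC machinery.
#' @return data frame, one row per biomarker x outcome, with AUC, CI,
#'   cut-off, sensitivity, specificity, FPR, TPR, PPV, NPV, class sizes and
#'   the `unreliable` flag.
#' @export
evaluate_biomarkers <- function(biomarker_table, staging,
                                biomarkers = c("short_mean", "long_mean",
                                               "long_capacity"),
                                outcomes = c("any_can", "early_can",
                                             "manifest_can"),
                                direction = "lower") {
  tab <- merge(biomarker_table, staging[, c("subject_id", "can_stage")],
               by = "subject_id")
  rows <- list()
  for (out in outcomes) {
    sub <- switch(out,
      any_can = tab[tab$can_stage %in% c("none", "early", "manifest"), ],
      early_can = tab[tab$can_stage %in% c("none", "early"), ],
      manifest_can = tab[tab$can_stage %in% c("none", "manifest"), ],
      stop(sprintf("unknown outcome '%s'", out)))
    label <- sub$can_stage != "none"
    for (bm in biomarkers) {
      scores <- sub[[bm]]
      ok <- !is.na(scores)
      sc <- scores[ok]; lb <- label[ok]
      n_cases <- sum(lb); n_controls <- sum(!lb)
      unreliable <- n_cases < 2L || n_controls < 2L
      res <- data.frame(
        biomarker = bm, outcome = out,
        n_cases = n_cases, n_controls = n_controls,
        auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        cutoff = NA_real_, sensitivity = NA_real_, specificity = NA_real_,
        fpr = NA_real_, tpr = NA_real_, ppv = NA_real_, npv = NA_real_,
        unreliable = unreliable)
      if (n_cases >= 1L && n_controls >= 1L) {
        res$auc <- roc_auc(sc, lb, direction)
        yc <- youden_cutoff(sc, lb, direction)
        cm <- confusion_at_cutoff(sc, lb, yc$cutoff, direction)
        res$cutoff <- yc$cutoff
        res$sensitivity <- cm$sensitivity; res$specificity <- cm$specificity
        res$fpr <- cm$fpr; res$tpr <- cm$tpr
        res$ppv <- cm$ppv; res$npv <- cm$npv
        if (n_cases >= 2L && n_controls >= 2L) {
          ci <- delong_ci(sc, lb, direction)
          res$ci_low <- ci$ci[1L]; res$ci_high <- ci$ci[2L]
        }
      }
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}
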