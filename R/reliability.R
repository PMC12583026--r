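#' Night-to-night reliability via a random-intercept model
#'
#' Fits `mean_cvt ~ recording_number (fixed) + (1 | subject)` by restricted
#' maximum likelihood and returns the between-subject and residual variance
#' components together with the intraclass correlation coefficient, the
#' proportion of total variance attributable to differences between
#' individuals. Subjects with only one recording are excluded before
#' fitting. Unbalanced designs (2 vs 3 nights) are handled natively by
#' REML; variance estimates are bounded at 0 by construction.
#'
#' @param observations data frame with columns `subject_id`,
#'   `recording_number`, `mean_cvt`.
#' @param fixed_recording include recording number as a categorical fixed
#'   effect (default TRUE; FALSE fits the intercept-only one-way layout).
#' @return list of class `icc_result`: `var_between`, `var_within`, `icc`,
#'   `n_subjects`, `n_observations`, `fixed_effect_levels`.
#' @export
fit_random_intercept <- function(observations, fixed_recording = TRUE) {
  req <- c("subject_id", "recording_number", "mean_cvt")
  if (!all(req %in% names(observations)))
    stop("observations must have columns subject_id, recording_number, mean_cvt")
  obs <- observations[stats::complete.cases(observations[req]), req]
  counts <- table(obs$subject_id)
  keep <- names(counts)[counts >= 2L]
  obs <- obs[obs$subject_id %in% keep, ]
  if (length(unique(obs$subject_id)) < 2L)
    stop("need >= 2 subjects with >= 2 recordings each after exclusion")
  obs$subject_id <- factor(obs$subject_id)
  obs$recording_number <- factor(obs$recording_number)
  n_levels <- nlevels(obs$recording_number)
  form <- if (fixed_recording && n_levels > 1L)
    mean_cvt ~ recording_number + (1 | subject_id)
  else
    mean_cvt ~ 1 + (1 | subject_id)
  fit <- lme4::lmer(form, data = obs, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_between <- max(0, vc$vcov[vc$grp == "subject_id"])
  var_within <- max(0, vc$vcov[vc$grp == "Residual"])
  structure(list(
    var_between = var_between,
    var_within = var_within,
    icc = icc(var_between, var_within),
    n_subjects = nlevels(obs$subject_id),
    n_observations = nrow(obs),
    fixed_effect_levels = if (fixed_recording) n_levels else 1L),
    class = "icc_result")
}

#' Intraclass correlation coefficient from variance components
#'
#' @param var_between between-subject variance (>= 0).
#' @param var_within within-subject (residual) variance (>= 0).
#' @return `var_between / (var_between + var_within)`, in \[0, 1\].
#' @export
icc <- function(var_between, var_within) {
  if (var_between < 0 || var_within < 0)
    stop("variance components must be >= 0")
  if (var_between + var_within == 0)
    stop("degenerate: both variance components are 0")
  var_between / (var_between + var_within)
}
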