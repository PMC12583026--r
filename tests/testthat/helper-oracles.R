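# Independent reference implementations used as oracles. Deliberately
# written as plain loops, sharing no code with the package internals.

# small random recording with arbitrary quality/rr structure
make_small_recording <- function(n, subject_id = "X", recording_index = 1L,
                                 artifact_frac = 0.03, low_q_frac = 0.1) {
  rr <- runif(n, 700, 1100)
  k <- max(0L, round(artifact_frac * n))
  if (k > 0) {
    idx <- sample(2:n, k)
    rr[idx] <- rr[idx - 1L] / (1 + runif(k, 0.30, 0.60))  # big HR jump
  }
  t <- cumsum(rr) / 1000
  quality <- sample(10:15, n, replace = TRUE)
  nl <- round(low_q_frac * n)
  if (nl > 0) quality[sample.int(n, nl)] <- sample(0:9, nl, replace = TRUE)
  structure(list(subject_id = subject_id, recording_index = recording_index,
                 kind = "night", session_start = 0, session_end = max(t) + 1,
                 device_id = "test",
                 beats = data.frame(t = t, rr = rr,
                                    raw_lvs = pmax(0, rnorm(n, 6, 2)),
                                    quality = quality),
                 ground_truth = NULL), class = "night_recording")
}

# single-pass naive reference for the full preprocessing pipeline
naive_process <- function(rec, roll = 10L, trim = 10L, jump = 15,
                          flank = 7L, qmin = 10L, rmin = 0.70) {
  b <- rec$beats
  n <- nrow(b)
  if (n < roll + 2L * trim + 1L) return(NULL)
  rolled <- sapply((roll):n, function(i) mean(b$raw_lvs[(i - roll + 1L):i]))
  nr <- length(rolled)
  trimmed <- rolled[(trim + 1L):(nr - trim)]
  raw_of_pos <- (trim + roll):(nr - trim + roll - 1L)  # raw beat per position
  stopifnot(length(raw_of_pos) == length(trimmed))
  hr <- 60000 / b$rr
  art_raw <- c()
  for (i in 2:n) if (hr[i] - hr[i - 1L] > jump) art_raw <- c(art_raw, i)
  np <- length(trimmed)
  drop <- rep(FALSE, np)
  for (a in art_raw) {
    p <- a - (roll - 1L) - trim
    for (q in (p - flank):(p + flank))
      if (q >= 1L && q <= np) drop[q] <- TRUE
  }
  keep_pos <- which(!drop)
  keep_pos <- keep_pos[b$quality[raw_of_pos[keep_pos]] >= qmin]
  list(cvt = trimmed[keep_pos],
       t = b$t[raw_of_pos[keep_pos]],
       n_original = np,
       n_retained = length(keep_pos),
       retention = length(keep_pos) / np,
       accepted = length(keep_pos) / np >= rmin,
       n_art = sum(drop))
}

# tie-corrected pair-counting AUC
pair_auc <- function(scores, labels, direction = "lower") {
  x <- scores[as.logical(labels)]
  y <- scores[!as.logical(labels)]
  s <- 0
  for (a in x) for (b in y) {
    more_extreme <- if (direction == "lower") a < b else a > b
    s <- s + more_extreme + 0.5 * (a == b)
  }
  s / (length(x) * length(y))
}

# brute-force DeLong structural components
delong_brute <- function(scores, labels, direction = "lower") {
  z <- if (direction == "lower") -scores else scores
  x <- z[as.logical(labels)]; y <- z[!as.logical(labels)]
  m <- length(x); n <- length(y)
  v10 <- numeric(m); v01 <- numeric(n)
  for (i in 1:m) {
    s <- 0
    for (j in 1:n) s <- s + (x[i] > y[j]) + 0.5 * (x[i] == y[j])
    v10[i] <- s / n
  }
  for (j in 1:n) {
    s <- 0
    for (i in 1:m) s <- s + (x[i] > y[j]) + 0.5 * (x[i] == y[j])
    v01[j] <- s / m
  }
  auc <- mean(v10)
  list(auc = auc,
       var = sum((v10 - auc)^2) / (m - 1) / m + sum((v01 - auc)^2) / (n - 1) / n)
}

# closed-form one-way balanced ANOVA method-of-moments variance components
anova_mom <- function(subject, y) {
  subject <- factor(subject)
  k <- as.integer(table(subject)[1L])
  stopifnot(all(table(subject) == k))
  a <- nlevels(subject)
  grand <- mean(y)
  means <- tapply(y, subject, mean)
  ssb <- k * sum((means - grand)^2)
  ssw <- sum((y - means[subject])^2)
  msb <- ssb / (a - 1)
  msw <- ssw / (a * (k - 1))
  c(var_between = max(0, (msb - msw) / k), var_within = msw)
}

# exhaustive Youden scan over observed thresholds
youden_brute <- function(scores, labels, direction = "lower") {
  x <- scores[as.logical(labels)]; y <- scores[!as.logical(labels)]
  best_j <- -Inf
  for (c in sort(unique(scores))) {
    if (direction == "lower") {
      sens <- mean(x <= c); spec <- mean(y > c)
    } else {
      sens <- mean(x >= c); spec <- mean(y < c)
    }
    j <- sens + spec - 1
    if (j > best_j + 1e-12) best_j <- j
  }
  best_j
}

# tiny fast simulation config for tests
tiny_config <- function(...) {
  args <- list(n_control = 3, n_t2d = 4, session_length = 95,
               sleep_cycle_minutes = 90, nights_per_subject = 2,
               night_missing_rate = 0, seed = 7L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
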