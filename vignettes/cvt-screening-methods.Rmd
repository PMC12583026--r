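---
title: "Methods: overnight cardiac vagal tone as a CAN screening biomarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overnight cardiac vagal tone as a CAN screening biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cvtscreen)
```

# The measurement model

Cardiac vagal tone (CVT) is a beat-to-beat index of parasympathetic control
of the heart, reported on the linear vagal scale (LVS). The LVS is
atropine-calibrated with an absolute zero at full vagal blockade; normal
resting values are roughly 5–15, and vagal withdrawal — the first lesion of
cardiovascular autonomic neuropathy (CAN) — lowers it. Overnight recordings
are attractive for screening because parasympathetic tone peaks during
sleep, but they bring sleep-stage structure (REM lowers vagal tone, brief
awakenings raise it), body-movement artifacts, and long contiguous signal
losses when the sleeper moves off a non-contact sensor.

`cvtscreen` models a recording as an ordered series of beats, each carrying
a timestamp, an RR interval (ms), a raw vagal-tone value (LVS) and a device
signal-quality score (integer 0–15). Everything downstream — cleaning,
summary statistics, reliability, diagnostic performance — operates on this
representation.

# Preprocessing chain and its constants

`process_recording()` applies, in order:

1. **Rolling average** (window 10): each CVT value is the mean of the
   current beat and its 9 predecessors, emitted only where a full window
   exists. The window is read as *including* the current beat; this keeps
   the subsequent edge exclusion (10 points) symmetric with the window
   length. The device this emulates streams CVT already rolled, so either
   reading is defensible; the choice is fixed here once.
2. **Edge exclusion**: exactly the first and last 10 points of the rolled
   series are dropped (rolling-average edge artifacts).
3. **Artifact excision**: an artifact is a beat-to-beat *increase* in
   instantaneous heart rate strictly greater than 15 bpm, detected on the
   raw RR stream (artifacts are raw-beat phenomena; detecting on the rolled
   stream would smear them). Each artifact is removed together with the 7
   preceding and 7 following points; overlapping windows are unioned so no
   point is removed twice. Decreases are never flagged — a compensatory
   pause after an ectopic beat falls inside the ±7 window of the spike that
   precedes it.
4. **Quality filtering**: points whose underlying beat scores below 10 on
   the 0–15 scale are removed. The score is attached to the beat, so the
   rolled series is filtered at the positions of low-quality beats.
5. **Retention gate**: the retained fraction is computed against the
   rolled-and-trimmed length — the first point in the chain where "original
   data points" is a well-defined countable series — and recordings below
   70% are rejected. The per-stage removal counts are logged and satisfy
   `n_raw − Σ removals = n_retained` exactly.

The stage order follows the order in which the protocol states the rules;
it is not otherwise identifiable, and all constants (15 bpm, ±7, 10, 10,
0.70) are configuration with these defaults, never hard-coded in logic.

**Missing data** is estimated before cleaning from the mean heart rate: a
recording at ≥ 60 bpm should contain at least one R-peak per second of its
declared session, so `expected = duration` seconds; below 60 bpm the
expectation is scaled by `meanHR/60`. The fraction is clipped at zero when
a fast heart over-delivers beats.

**Best-recording selection** replaces a manual, sleep-morphology-guided
choice with a deterministic proxy: highest retention, then longest retained
series, then lowest recording index. The morphology criterion ("prominent
broad wake peaks") is not operationalizable from the protocol text; the
proxy is auditable and reproducible, at the cost of ignoring sleep quality.

# CVT summaries

Per recording: arithmetic mean, sample SD (n − 1), and **CVT capacity** —
the mean absolute difference between the whole-night mean and the 20 most
extreme values (10 highest, 10 lowest) of the *processed* series. Capacity
summarizes dynamic vagal modulation across sleep stages. It requires ≥ 20
points, is translation-invariant, scales linearly with positive rescaling,
and is 0 iff all 20 extremes equal the mean. Ties at the 10th rank are
broken by earliest index via a stable sort, and the two extreme sets are
disjoint index sets taken from the ends of the sorted order. Whether the
extremes should be raw beats or rolled points is not stated in the protocol;
rolled points are used since capacity is defined on the processed series.

# Reliability

Night-to-night reliability of mean CVT uses the random-intercept model
y_ij = μ + β_(recording j) + u_i + e_ij with recording number as a
categorical fixed effect and subject as the random intercept, fitted by
REML (`lme4::lmer`). Subjects with a single recording are excluded first.
The ICC σ²_u / (σ²_u + σ²_e) is the share of variance attributable to
differences between individuals. REML over ML is standard practice for
variance components (the protocol names no estimator); estimates are
non-negative by construction, and on balanced designs without the fixed
effect they coincide with the one-way ANOVA moment estimator — a closed
form the test suite checks to 1e-6. Convergence is delegated to lme4's
defaults; the coding of the fixed effect (treatment contrasts) does not
affect the variance components.

# Diagnostic performance

CVT biomarkers are oriented **lower-is-positive** (disease lowers vagal
tone; published cut-offs are upper bounds for positivity). For each
biomarker (short-term awake mean, long-term overnight mean, overnight
capacity) and outcome contrast — any CAN (early ∪ manifest vs none), early
CAN (early vs none, manifest excluded), manifest CAN (manifest vs none,
early excluded) — the package computes:

* **AUC** as the trapezoidal area over the empirical ROC curve, which
  equals the tie-corrected pair-counting statistic
  P(case more extreme) + ½P(tie); the identity is enforced by tests at
  1e-12.
* **DeLong 95% CI** from the U-statistic structural components: per-case
  and per-control placement values whose sample variances, scaled by the
  class sizes, sum to the AUC variance. The interval is
  AUC ± z·SE, clipped to [0, 1]; with perfect separation the variance is
  exactly 0.
* **Youden cut-off**: the observed score value maximizing
  J = sensitivity + specificity − 1 under the rule score ≤ cutoff.
  Candidate cut-offs are restricted to observed values (published cut-offs
  are data values). Ties in J are broken toward higher specificity — in a
  screening context, fewer false positives at equal J — then toward the
  more conservative cut-off; all tied cut-offs are reported, since real
  data can produce two equal-J thresholds.
* **Predictive values** at sample prevalence; an empty predicted margin
  makes the corresponding predictive value undefined (`NA`), never 0.

Missing biomarker values are dropped pairwise per model. Group labels
(control vs diabetes) play no role in staging: controls can have CAN, and
the staging comes from the reflex tests alone. A contrast with fewer than
2 cases or controls is flagged `unreliable` but still reported.

# The synthetic world

Because no patient-level data are deposited, the generator *is* the test
bed, and its defaults state the emulated world once:

* **Design**: 20 controls + 40 with type 2 diabetes, up to 3 nights each
  (scheduled nights missing with probability 0.089, matching 164-of-180
  attrition), sessions of 434 min, plus one 5-min awake recording each.
* **CAN stages** follow the reported prevalences (controls 80/15/5%,
  diabetes 47.5/25/27.5% for none/early/manifest), and CART abnormality
  counts are drawn consistently with the stage.
* **Levels**: overnight mean CVT by group × stage is calibrated to the
  reported medians (no CAN ≈ 7.1–8, early 5.5, manifest 4 LVS) — these are
  configuration, not fact, since stage-wise effect sizes beyond medians are
  not reported. The awake short-term level sits 3 LVS below the overnight
  intercept, reflecting higher parasympathetic activity during sleep.
* **Variance**: between-subject SD 2 LVS; night-offset SD 0.8 LVS. At the
  cohort level the between-subject variance also includes the stage/group
  mixture spread (~2.2 LVS²), so these values put the night-to-night ICC of
  mean CVT near the reported 0.91 (observed 0.90–0.93 across seeds).
* **Sleep architecture** is a deterministic 90-min cycle template (25% REM
  at the end of each cycle, −2 LVS floored at 0; a 2-min wake bout at +3
  LVS opening each later cycle) with per-beat Gaussian noise (SD 1.5 LVS)
  — stage-dependent *levels* are what the analysis consumes, so no Markov
  hypnogram is modelled.
* **Coupling**: heart rate falls linearly with CVT (0.5 bpm per LVS around
  60 bpm at 8 LVS). The protocol records both but states no coupling; a
  small negative slope is physiologically signed and keeps the artifact
  rule exercised on a non-constant HR stream.
* **Degradation**: artifacts are single shortened RR intervals producing
  > 15 bpm jumps (rate 0.002/beat); dropouts are 3 contiguous gaps
  totalling 20.8% of the session (rolling off the sheet is episodic);
  93.7% of beats score 13–15, the rest 0–12 in bursts of ~20 beats.
* **Reproducibility**: one master seed; each subject's stream is seeded by
  a fixed affine function of it, so cohorts are identical beat-for-beat
  across runs and insertion order.

What a green test run establishes: the pipeline implements its stated rules
exactly (oracle equivalence, boundary tests), recovers configured variance
components and binormal AUCs, and its inference machinery has correct
frequentist behaviour (DeLong coverage 0.93–0.97 at n = 60). What it does
**not** establish: clinical performance. The synthetic effect sizes derive
from group medians under Gaussian noise, so the demo AUCs (0.85–0.95) are
cleaner than the published clinical ones (0.64–0.79); real recordings also
carry morphology (arousals, apnea, medication effects) the template does
not emulate.

# Numerical and edge-case choices

* All LVS truncations are hard floors at 0 (the scale has an absolute
  zero).
* `rolling_cvt` on fewer than 10 beats and `trim_edges` on ≤ 20 points
  return empty, flagged output; `process_recording` turns this into a
  rejection with reason rather than an error.
* Artifact indices whose excision window falls entirely outside the
  surviving series have no effect; partial overlaps are truncated at the
  bounds.
* The orthostatic-hypotension windows are stated as "within the first
  minute", "between the first and third", "from the fourth to the tenth",
  leaving minutes (3, 4) unassigned; readings there are classified
  *classic* (the delayed label is reserved for the explicitly late
  window). Reverse dipping uses the ratio test night/day ≥ 1.10, exact at
  the boundary.
* Scaled-down simulations in the test suite (shorter sessions, 30-min
  sleep cycles, fewer seeds than the nominal 200-cohort property) keep the
  suite under a small CPU budget; the statistical margins are computed in
  the tests' comments where they matter.

# Known limitations

* The raw vagal-tone signal is an *input*: the phase-shift algorithm that
  derives CVT from ECG voltage is proprietary and out of scope, as are
  R-peak detection, frequency-domain HRV, polysomnography and CART
  acquisition.
* Best-recording selection ignores sleep morphology (see above).
* No confidence interval is attached to the ICC (none is needed by the
  screening contract), and correlated-AUC comparison (DeLong's paired
  test) is not implemented.
* The generator's stage means are identifiable only up to the reported
  medians; conclusions about *early* CAN detectability transfer from this
  synthetic world only qualitatively.
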