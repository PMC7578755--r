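---
title: "Measuring gesture laterality from bilateral wrist accelerometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gesture laterality methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gesticulate)
```

## The measurement problem

Co-speech gestures are spontaneous, bimanual, and unscripted. For a
prosthesis user, the *balance* of gesture movement across the intact arm and
the prosthesis is an implicit behavioural measure of how far the device has
been absorbed into everyday action — one that does not rely on asking the
user anything. The raw material is two time-aligned wrist accelerometer
traces recorded while the participant performs speech tasks (describing
object pairs, retelling a story). This vignette documents the processing
model, every tunable parameter, the simulators used for validation, and the
choices made where the design was genuinely open.

## From acceleration to per-second magnitudes

Each wrist contributes a tri-axial series in units of g. Gravity is removed
per axis with a zero-phase (forward–backward) 4th-order Butterworth
high-pass, and the residual is collapsed to the Euclidean vector magnitude.

* **Cutoff** (`cutoff_hz`, default 0.25 Hz). Standard wrist-actigraphy
  practice: slow orientation drift and the static 1 g offset lie well below
  0.25 Hz, whereas gesture energy (bursts of a few tenths of a second to a
  few seconds, with oscillation around 2–8 Hz) lies well above. The filter
  must satisfy `cutoff < fs/2`; violations are errors, not warnings.
* **Zero-phase filtering with reflection padding.** Forward–backward
  filtering doubles the effective order and cancels phase delay, which
  matters because the two arms are compared second by second. We pad by
  reflection over roughly three filter time constants (capped at the signal
  length) before `filtfilt`; without padding, edge transients at a 0.25 Hz
  cutoff extend several seconds into the recording. With padding, a constant
  1 g input leaves a residual below 5e-4 g.
* **Alternative estimator** (`magnitude_minus_1g`): |‖a‖ − 1| needs no
  filter and is offered for quick checks; it conflates orientation change
  with movement and is not the default.

Magnitudes are averaged within consecutive half-open epochs
`[start, start + epoch_len_s)` inside each task window. `epoch_len_s`
defaults to 1 s — the laterality measure is defined second by second — and a
trailing partial epoch is dropped rather than padded, so every epoch mean
averages the same number of samples. An arm is *active* in an epoch when its
mean magnitude reaches `activity_threshold_g` (default 0.01 g, i.e. about
twice the epoch-mean noise floor of a typical wrist device; the value is
echoed into every output).

## The laterality measures

For each active epoch (at least one arm active), the log magnitude ratio is

\[ r(t) = \log m_{np}(t) - \log m_{p}(t), \]

where *p* is the preferred arm (intact or dominant) and *np* the
nonpreferred arm (prosthesis or nondominant); this pairing treats the
prosthesis side of a one-hander as corresponding to the nondominant side of
a control. The **MMR** is the sample median of the r(t). Zero means
symmetric contribution; negative means the intact/dominant arm produced the
larger movements. Design notes:

* **Difference of logs, not log of a quotient.** `log(a) - log(b)` negates
  *bit-exactly* when the arms are swapped, so the antisymmetry of the
  measure holds to the last ulp, not merely to rounding.
* **Unilateral epochs** (exactly one arm active) are assigned ±`cap`
  (default 7, following the bilateral arm-use convention of capping
  single-arm seconds at a large finite log-ratio); bilateral ratios are
  clamped to the same bounds so the MMR always lies in [−cap, cap].
* **Minimum evidence.** An MMR is only reported when at least
  `min_active_epochs` (default 10) active epochs exist; otherwise the
  metric is a flagged missing value with a reason string, and the
  participant is excluded from laterality analyses *visibly*, never
  silently.
* **Pooling.** Ratios are pooled over all task windows before the median is
  taken (rather than per task and averaged); the per-window epoch series is
  retained so per-task values can be derived if wanted.

Movement *counts* are maximal runs of suprathreshold magnitude
(`threshold_g`, default 0.05 g) lasting at least `min_dur_s` (0.25 s), after
absorbing sub-threshold gaps shorter than `merge_gap_s` (0.25 s), expressed
per minute of task time. Counts are threshold-dependent by construction —
which is exactly why the MMR, not the count, is the primary measure — so all
three parameters are recorded in every metrics row. Two simpler summaries
are also emitted as robustness companions: the **use ratio** (active
nonpreferred epochs over active preferred epochs) and a **laterality index**
(M_np − M_p)/(M_np + M_p) over summed active-epoch magnitudes, bounded in
[−1, 1]. Both are this package's own stand-ins for the general class of
bilateral-use indices, and are labelled as such.

## Questionnaire scoring

* **PAL score**: mean of the functional-use items normalized to [0, 1]
  (0 = no function, 1 = maximum function). The item scale is configurable
  because instruments vary; up to 20% missing items are tolerated (excluded
  from the mean), more flags the score as missing.
* **Embodiment**: the mean of exactly five −3..+3 statements; the
  positive/neutral-negative split puts the boundary score of 0 in the
  neutral/negative group (`> 0` is positive). A control statement ("it
  seems like I have three hands") should be strongly rejected; responses
  above −1 flag possible non-engagement.
* **Daily-use composite**: wear hours/week and the PAL score have
  incommensurate units, so the composite is the mean of their within-cohort
  z-scores (cohort mean 0 by construction). A rank-based variant is
  available; rank-based analyses downstream are invariant to the choice
  whenever both components enter monotonically. Raw components are always
  reported alongside, and a zero-variance component is dropped with a
  warning rather than producing NaNs.

## The statistical battery

All tests report their options (exactness, tie handling, prior scale) inside
the result object.

* **Mann-Whitney U** counts pairs `a < b` plus half the ties. The p value
  uses the exact null distribution whenever there are no ties and
  n1·n2 ≤ 400 (which covers groups of 25 vs 15), otherwise a
  tie-corrected, continuity-corrected normal approximation. The min-U value
  is reported alongside for cross-convention comparison.
* **Spearman** is the Pearson correlation of mid-ranks with the
  t-approximation on n − 2 df; an exact permutation p is available for
  small untied samples.
* **JZS Bayes factor** for one-sample/paired t tests integrates the
  Zellner–Siow Cauchy prior (scale `r_scale`, default √2/2 ≈ 0.707)
  numerically to a relative tolerance of 1e-6. The prior scale is
  configurable and recorded, since default-prior conventions differ across
  software.
* **2×2 mixed ANOVA** (between: group; within: arm) via the classical
  Error-stratum decomposition, F on (1, N − 2) df. With fully constant
  input the 0/0 F is reported as 0 with p = 1 rather than NaN.
* **ANCOVA** fits the additive linear model with sum-to-zero contrasts and
  Type III sums of squares, so factor tests are order-invariant.
* **Outliers** are *flagged*, never deleted: |value − median| > 3 scaled
  MADs marks a row for exclusion from parametric analyses only, and named
  exclusions can be supplied by participant code in the run configuration.
  Every exclusion is listed in the battery output with its rule and value.
* p values are reported unadjusted, matching standard practice for this
  battery; a Benjamini-Hochberg column can be added downstream and is
  deliberately not baked in.

## What the simulators emulate — and what they do not

**Signal level** (`simulate_session`): gesture events arrive as a Poisson
stream (default 20/min), each a raised-cosine amplitude envelope (smooth
onset/offset, avoiding filter ringing; square envelopes are available for
threshold tests) modulating a ~4 Hz sinusoid in a random horizontal
direction, riding on gravity plus white per-axis noise. Coupled events
(probability `bilateral_coupling`, default 1) recruit both arms with a
shared envelope and amplitude jitter, the nonpreferred arm scaled by the
laterality factor k, so the per-event amplitude ratio is exactly k. A
minimum quiet gap (0.35 s) is enforced between kept bursts so that
ground-truth event counts are well defined with respect to the detector's
gap-merging rule. Defaults — 0.5 g peak amplitude, 3 mg noise — sit in the
realistic regime where gesture energy dominates device noise; because the
epoch mean includes the quiet fraction of each second, an additive noise
floor compresses extreme log-ratios slightly toward zero (about 0.06 log
units at k = 0.25 under the defaults, shrinking as amplitude grows). The
recovery checks in the test suite quantify exactly this residual. The
simulator does *not* model arm kinematics, posture change, speech-correlated
timing structure, or device-specific noise spectra — so passing recovery
tests demonstrates correctness of the measurement chain, not realism of any
particular device.

**Cohort level** (`simulate_cohort`): MMR, wear time, PAL and embodiment
are drawn from a 4-dimensional Gaussian copula. Rank-correlation targets
are specified on the Spearman scale and mapped to the latent Pearson scale
by r = 2 sin(πρ/6); the wear/PAL latents are correlated 0.5 with each other
and scaled so that the *composite* daily-use score attains the requested
correlation with MMR. Marginals are truncated normals matched to a
realistic cohort (25 one-handers: 15 congenital/10 acquired, 9 cosmetic/3
mechanical/13 myoelectric; wear 72.8 ± 29.8 h/week; PAL 0.49 ± 0.21;
embodiment 0.75 ± 1.68; 15 controls). Truncation is rare in the use-score
components (≲1% of draws), so ranks are essentially undisturbed. The
embodiment-group contrast in MMR arises from the continuous MMR–embodiment
correlation (default Spearman 0.37); an explicit additive group shift
(`emb_shift`) exists for constructing designed contrasts but defaults to 0
so that correlation targets remain exact. Movement rates use a
per-participant base rate (10 ± 3 /min) with per-arm noise (1.5 /min) and a
1.3 /min intact-arm excess for one-handers, chosen to give a paired-t
signal of the size typical for a 25-person group without saturating it.

## Numerical and degenerate-input choices

* Epoch windows are half-open, so a sample on an epoch boundary belongs to
  exactly one epoch; sample-to-epoch assignment uses a 1e-9 s guard against
  float boundary error.
* Recording CSVs are validated for monotone time and ≤1% relative step
  jitter; m/s² input is divided by 9.80665. NaN samples are rejected by
  default; optional linear interpolation covers gaps up to 0.2 s.
* `simulate_session`/`simulate_cohort` require an explicit seed; identical
  seeds give bit-identical output, and the pipeline writes byte-identical
  bundles on rerun.
* The test suite validates the statistics against independent oracles:
  full labeling enumeration for the exact U, hand-built mid-ranks for
  Spearman, fine-grid trapezoid quadrature for the JZS integral,
  sum/difference-score t² decomposition for the mixed ANOVA, and
  nested-model residual comparisons for the Type III ANCOVA. Simulation
  checks use 20–50 sessions of 300 s per condition and 1000 cohort draws —
  sizes at which medians and rejection rates are stable to the tolerances
  asserted.

## Known limitations

* The MMR compares *magnitudes*, not movement quality or gesture meaning;
  video-based gesture coding is out of scope here.
* Epoch means include quiet sub-epoch samples, so very low signal-to-noise
  recordings bias ratios toward symmetry (quantified above); with real
  devices this matters only for barely-moving arms near the activity
  threshold.
* The composite daily-use score's exact combination rule (z-mean) is a
  convention; rank-based analyses are unaffected, but the composite's
  absolute values should not be compared across cohorts standardized
  separately.
* The deposit-reproduction path (`reproduce_osf`) depends on a manual
  download and a documented per-participant CSV layout; it never fetches
  anything itself.
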