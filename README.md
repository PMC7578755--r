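# gesticulate

Gesture laterality from bilateral wrist accelerometry.

When people talk they gesture, and they gesture with both arms. For people
with unilateral upper-limb loss who wear a prosthesis, *how symmetrically*
they gesture is an implicit, behavioural window on how far the prosthesis has
been incorporated into the body's everyday repertoire. `gesticulate` turns
raw bilateral wrist accelerometer recordings made during speech tasks into
gesture laterality metrics, scores the accompanying prosthesis-use and
embodiment questionnaires, and runs the cohort statistics that relate the
three — for movement scientists, rehabilitation researchers and prosthetics
engineers who want an objective, 10-minute, device-agnostic measure of
prosthesis engagement.

## The measures

For each arm, tri-axial acceleration (units of g) is gravity-filtered
(zero-phase 4th-order Butterworth high-pass, 0.25 Hz default) and collapsed
to the vector magnitude. Magnitudes are averaged into per-second epochs.
Writing m_p(t) and m_np(t) for the preferred (intact/dominant) and
nonpreferred (prosthesis/nondominant) arm's epoch magnitude, each epoch in
which at least one arm is active (magnitude ≥ 0.01 g default) contributes a
log magnitude ratio

    r(t) = ln m_np(t) − ln m_p(t)

with unilateral epochs assigned ±cap (default ±7; positive when only the
nonpreferred arm moved). The **median magnitude ratio**

    MMR = median{ r(t) : epoch t active }

is 0 for perfectly symmetric gesturing and negative when the intact/dominant
arm produces the larger movements. Movement *counts* per arm are maximal
suprathreshold runs (default threshold 0.05 g, minimum duration 0.25 s,
sub-threshold gaps < 0.25 s merged), expressed per minute of task time.

Questionnaires are scored as: PAL functional-use mean normalized to [0, 1];
embodiment as the mean of five −3..+3 Likert statements (split into
positive > 0 vs neutral/negative ≤ 0 groups); and a composite daily-use
score as the mean of within-cohort z-scores of weekly wear hours and the
PAL score.

The statistical battery provides Spearman correlations (mid-rank, t
approximation), Mann-Whitney U (exact null distribution whenever there are
no ties and n1·n2 ≤ 400), one-sample/paired t tests with default JZS Bayes
factors (Cauchy prior, scale 0.707), a 2×2 mixed ANOVA (group × arm), and a
Type III ANCOVA, plus a flag-based (never silent) MAD outlier rule.

Simulators for both signal-level sessions (Poisson gesture bursts with a
known amplitude ratio between the arms) and cohort tables (Gaussian copula
with controlled Spearman targets) make every stage testable end to end with
known ground truth.

## Worked example

Simulate a 300 s bimanual session whose prosthesis-side amplitude is half
the intact side's (true log-ratio ln 0.5 ≈ −0.693), and recover the metrics:

```r
library(gesticulate)

sim <- simulate_session(signal_sim_params(laterality_k = 0.5, seed = 1))
compute_gesture_metrics(sim$session)
#> gesture_metrics: sim01
#>   movements/min: preferred 14.80, nonpreferred 14.80 (over 300 s)
#>   MMR: -0.671 over 107 active epochs (8 unilateral)
#>   use ratio 0.925, laterality index -0.326
```

Both arms move equally *often* (coupled gestures), but the prosthesis side
moves at half the magnitude: the MMR of −0.671 recovers the injected
ln 0.5 = −0.693 to within a few percent.

At the cohort level, simulate 25 one-handers and 15 controls with a target
MMR–daily-use Spearman correlation of 0.55 and run the battery:

```r
co  <- simulate_cohort(cohort_sim_params(seed = 1))
bat <- run_stat_battery(co)
bat$u_mmr_group
#> mann_whitney: U = 343, p = 2.007e-06
#>   options: p_method=exact; ties=FALSE; u_min=32
bat$spearman_mmr_use
#> spearman: rho(23) = 0.5262, p = 0.0069
#>   options: p_method=t approximation; ties=FALSE
bat$moves_paired_twohanders
#> t_paired: t(14) = -0.1288, p = 0.8994, BF10 = 0.2643
#>   options: r_scale=0.7071068
```

One-handers' MMR separates strongly from controls' (exact U test); the
recovered rank correlation between gesture laterality and daily prosthesis
use sits near its 0.55 target; and the controls' arm symmetry yields a
Bayes factor well below 1 (evidence *for* the null of no arm difference).

File-based studies are driven by `run_pipeline()` from a single YAML
configuration (session manifest, task windows, questionnaire CSV, every
threshold), writing epoch files, a metrics CSV, the cohort table, a
readable stats report with its machine-readable twin, and a provenance
record. `reproduce_osf()` is the strictly opt-in path for recomputing the
statistics of the publicly deposited study data from a manual download.

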