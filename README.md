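# hapticube

Analysis of haptic exploration recordings from a sensorized cube (the
"iCube": 6 faces × 16 capacitive cells plus an inertial orientation
estimate, reported wirelessly at an irregular ~5 Hz). The package is aimed
at researchers studying haptic exploration strategies — for example how
congenitally blind (CB), late blind (LB) and sighted (SI) people explore a
hand-held object — and at anyone who needs tested, scriptable versions of
the metrics this paradigm uses.

## What it computes

From raw samples (timestamp, 6 × 16 binary tactile maps, unit quaternion):

1. **Constant-rate grid.** Touch maps are resampled at 0.2 s by zero-order
   hold; orientation by quaternion SLERP along the shortest arc. Trials are
   trimmed to the actively touched interval (leading/trailing samples with
   < 2 active cells).
2. **Explorative-touch filter.** For each face and grid step the simple
   matching coefficient against the previous sample,
   `SMC = (M00 + M11) / 16`; the face(s) with the lowest SMC are the
   explored faces (holding touches are stable, SMC ≈ 1). The filter yields
   per-trial mean SMC, mean active cells per explored sample, touch counts
   and frequencies, exploration duration, and per-face duration statistics.
3. **Rotation.** Per-axis traversal angles
   `Δθ = atan2(‖v_t × v_(t−1)‖, v_t · v_(t−1)) · 180/π` for the three
   face-normal body axes; the amount of rotation is the maximum per-axis
   cumulative sum, rotation speed the cross-axis mean over instants in
   motion (> 1°/s). Faces are labeled by relative (up/down/front/rear/
   left/right) and absolute (cardinal) orientation at every instant.
4. **Transition matrices.** Exploration episodes (maximal runs of one
   explored face) yield 6 × 6 percentage matrices over relative labels, the
   maximum diagonal score, the number of different transitions and the
   number of returns to already-explored faces.
5. **Group statistics.** MANOVA with Roy's largest root (top eigenvalue of
   `W⁻¹B`), Fisher LDA with normalized coefficients and percent separation,
   univariate ANOVAs with Welch post hocs under Benjamini–Hochberg FDR, a
   BIC-approximate Bayes factor for recognition accuracy after Box-Cox
   transformation, and one-tailed Pearson correlations.

A scripted simulator (`simulate_session()`, `simulate_cohort()`) generates
raw sessions with known ground truth — episodic face exploration, controlled
SMC and active-cell targets, scripted single-axis rotations, irregular
203 ± 113 ms sampling — so the whole pipeline is testable without any
recordings. Its presets carry the published group profiles (active cells
5.24/4.32/4.14; SMC 0.77/0.81/0.80; rotation 560/517/710°; accuracy
72/77/69% for CB/LB/SI).

## Worked example

```r
library(hapticube)

cohort  <- simulate_cohort(seed = 42)            # 6 CB + 10 LB + 16 SI
metrics <- cohort_metrics(cohort)                # 192 trial rows, 13 variables
fit     <- analyze_cohort(metrics)
fit
```

```
Haptic exploration analysis (trial-level, 192 rows)
Accuracy BF01 (null/group): 14.52 (Box-Cox lambda 1.03)
MANOVA Roy's root = 0.500, F(12, 179) = 7.45, p = 4.625e-11
LDA separation: 71.1% / 28.9%
ANOVA mean_smc: F(2, 189) = 5.95, p = 0.003114
  CB vs LB: t(76.6) = -3.59, p_fdr = 0.001738
  CB vs SI: t(77.0) = -3.29, p_fdr = 0.002293
  LB vs SI: t(140.1) = 0.46, p_fdr = 0.6482
...
  pair                                   direction       r         p     p_fdr
1 mean_smc~exploration_duration          positive  -0.0941 0.903     0.903
2 mean_active_cells~exploration_duration negative  -0.279  0.0000439 0.0000877
```

Read: the Bayes factor favors the null (no group effect on recognition
accuracy, as in the study), the MANOVA separates the groups on the haptic
variables with two discriminants carrying roughly 71% and 29% of the
separation, the SMC post hocs isolate the congenitally blind profile (lower
SMC — faster pattern change — than both other groups, which do not differ),
and the number of active cells correlates negatively with exploration
duration while SMC does not correlate significantly.
`univariate_followup(metrics, "mean_active_cells", "group")` gives the
active-cells post hocs, and `fit$lda$scores` the per-trial discriminant
scores for a discriminant-plane scatter.

Single-session use: `read_session("s.jsonl")` (JSON-lines dialect documented
in `?write_session`), `session_metrics()`, or the step-by-step functions
(`make_trial_grid()`, `trim_trial()`, `classify_explorative()`,
`amount_of_rotation()`, `transition_matrix()`, ...).

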