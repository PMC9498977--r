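---
title: "Haptic exploration metrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haptic exploration metrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapticube)
```

## The measurement problem

A sensorized cube reports, at an irregular ~5 Hz cadence (one sample every
203 ± 113 ms), a binary tactile map per face (6 faces × 16 capacitive cells)
and a unit quaternion for its orientation. From these streams we want
per-trial descriptions of *how* a participant explored the cube: which
touches probed a face rather than merely held the device, how much and how
fast the cube was rotated, and in what sequence faces and orientations were
visited. Thirteen per-trial variables feed a group-discrimination stage
comparing congenitally blind (CB), late blind (LB) and sighted (SI)
participants.

## Resampling

All computation happens on a constant 0.2 s grid, close to the device's mean
cadence. Binary maps cannot be averaged without creating non-binary states
the similarity filter could not consume, so touch maps use a zero-order hold:
each grid sample takes the map of the latest raw sample at or before it. The
hold never invents a map that was not observed. Orientation uses spherical
linear interpolation (SLERP) between the bracketing raw quaternions, with the
shortest-arc convention (one endpoint is negated when the quaternion dot
product is negative), so an antipodal representation never produces a
spurious 360° sweep.

Trials are trimmed by the criterion used for manual cutting in this
paradigm: leading and trailing grid samples with fewer than two active cells
(summed over the whole cube) are removed, interior samples never. Whether the
original trimming considered per-face or whole-cube counts is not recorded;
whole-cube is assumed. Raw gaps are held, with a warning above 2 s
(`gap_warning_s`).

## Explorative versus holding touches

Holding touches are stable in time; explorative touches change the activation
pattern. The filter computes, for each face at each grid sample, the simple
matching coefficient (SMC) against the previous sample,

$$\mathrm{SMC} = \frac{M_{00} + M_{11}}{M_{00} + M_{01} + M_{10} + M_{11}},$$

with the counts taken over the 16 cells. The face(s) attaining the minimum
SMC are the explored faces of that sample; ties keep all tied faces; if every
face has SMC 1 the cube is taken as untouched at that instant and the sample
carries no explored face. Sample 1 of a trial has no predecessor and is
excluded from all SMC-based metrics.

"Number of touches" has no unique definition on binary maps; this package
counts cell onsets (0 → 1 between consecutive grid samples) on explored
faces, the only event definition robust to the sampling rate. Per-face
exploration-duration statistics include never-explored faces as zeros, which
keeps the variability metric sensitive to focused exploration.

## Rotation

For each of the three body axes orthogonal to the faces, the per-step
traversal angle between world-frame positions $v_t$ and $v_{t-1}$ is

$$\Delta\theta = \operatorname{atan2}(\lVert v_t \times v_{t-1}\rVert,\;
v_t \cdot v_{t-1}) \cdot 180/\pi .$$

The arctangent of the absolute cross/dot quotient is identical to this on
(0°, 90°) but undefined at 90° and ambiguous beyond; at 5 Hz the per-step
angles are far below 90°, so `atan2` reproduces the intended quantity while
removing the singularity. The amount of rotation is the maximum over the
three axes of the summed per-step angles. Rotation speed divides each
per-step angle by 0.2 s; an instant is "in motion" when the cross-axis mean
speed exceeds 1°/s (`motion_threshold_dps`), and the reported speed is the
mean of per-axis speeds over the three axes and all in-motion instants. The
cross-axis reading of the threshold gives each instant a single motion state.

Faces receive two label sets per instant: *relative* labels (up, down, front,
rear, left, right) in a declared participant frame (default: world +Z is the
participant's up, +X the front, left = up × front), and *absolute* cardinal
labels (North = +Y, East = +X, Up = +Z). A face gets the label of the
canonical direction most aligned with its world normal; assignment is greedy
over the 36 face-label alignments so both maps are bijections at every
orientation, including degenerate 45° poses where a per-face argmax could
collide. The participant frame is a declared convention, not inferred from
the data.

## Episodes and transition matrices

Maximal runs of a constant explored face form episodes; unexplored samples
break runs; tied explored faces resolve to the lowest face id. Each episode
carries the modal relative label of its samples (ties: the label at episode
start). Consecutive episodes define transitions between labels, accumulated
into a 6 × 6 percentage matrix. A transition across an unexplored gap is not
counted when the same physical face resumes — the cube was set down and
picked up again — but the revisit still counts as a return. Diagonal entries
arise when consecutive episodes (necessarily different faces) share a label,
i.e., the cube was rotated to bring the next face to the same relative
position; with 12 episodes per trial the diagonal percentages are quantized
in steps of about 9%, which makes the per-trial maximum diagonal score a
coarse, high-variance measure.

Under the irregular cadence, about a fifth of grid steps repeat the previous
raw sample (no raw sample falls in the window), producing all-SMC-1 frames
that fragment episodes. Measured episode and return counts therefore sit well
above the scripted ones; the scripted sequence is recovered exactly under
dense regular sampling, which the simulator offers as a noise-free mode.

## The statistics stage

The thirteen dependent variables are analyzed at trial level by default: the
published post-hoc degrees of freedom (44.8–68.6) exceed the participant
count, implying trial-level observations, while the observation unit of the
published MANOVA cannot be reverse-engineered; participant-mean aggregation
is available as `unit = "participant"`.

* **Accuracy.** Per-participant recognition accuracy is Box-Cox transformed
  (profile likelihood on a λ grid [−2, 2], step 0.01; non-positive values
  shifted up with a message) and the one-way group model is compared with the
  intercept-only model by the BIC approximation
  $\mathrm{BF}_{01} = \exp((\mathrm{BIC}_{\mathrm{group}} -
  \mathrm{BIC}_{\mathrm{null}})/2)$ — a closed-form, dependency-free
  approximation to a default Bayes factor that preserves the decision
  direction.
* **MANOVA.** Roy's largest root is the top eigenvalue of $W^{-1}B$; the F
  approximation uses $df_1 = \max(p, k-1)$, $df_2 = N - k - df_1 + (k-1)$.
* **LDA.** Fisher discriminants from the same eigenproblem, scaled to unit
  pooled within-group score variance (the conventional normalized
  coefficients); percent separation is the eigenvalue share.
* **Follow-ups.** One-way ANOVA on the variables with the largest |LD1|
  coefficients, Welch pairwise t-tests with Welch–Satterthwaite df, BH-FDR
  within each variable's three pairwise tests. FDR families are one per
  analysis block (each variable's post hocs; the two correlations), a choice
  the analysis logs rather than hides. For error-rate control the chain gates
  post hocs on ANOVA p < 0.05; its empirical family error stays below 0.05
  by construction of the gate.
* **Correlations.** One-tailed Pearson tests of exploration duration against
  mean SMC (positive direction) and mean active cells (negative direction).

## The simulator

The simulator generates raw sessions whose pipeline output has known ground
truth. Its defaults are the study conditions: cohorts of 6 CB, 10 LB and 16
SI participants, three memorization + recall trials each, 60 s nominal
explorations, 12 episodes, published group targets (active cells 5.24 / 4.32
/ 4.14; SMC 0.77 / 0.81 / 0.80; rotation 560 / 517 / 710°; accuracy 72 / 77 /
69%), sampling intervals truncated-Gaussian (mean 0.203 s, SD 0.113 s, floor
0.05 s), and 5% between-participant jitter on the targets.

Design choices worth knowing:

* **Keyframe alignment.** The explored face's map changes only at the raw
  samples the 0.2 s zero-order hold will select, so the changed-cell count of
  every reconstructed grid step is under direct control and recovery
  tolerances can be derived in closed form. Intermediate raw samples repeat
  the current map, i.e., the hand moves at roughly the grid rate, slower than
  the radio.
* **Count dynamics.** A change of $k$ cells bounds the active-count change by
  $k$ with equal parity, so high SMC targets force small count increments;
  independent count draws are infeasible. Active-cell counts therefore follow
  a bounded birth-death chain on five states around the target, with a tilted
  stationary distribution whose mean is solved to equal the target exactly.
  Changed-cell counts are chosen by error diffusion around
  $k^\ast = 16(1 - \mathrm{SMC}^\ast)$, so the mean SMC over explored frames
  converges to the target to within a fraction of a cell. Because every
  explorative step changes at least one cell and parity forces part of the
  mass onto two-cell changes, targets above SMC 0.9 are infeasible; and
  since a map with on average $n$ active cells can change at most $2n$ cells
  per step (complete replacement), targets below $1 - n/8$ are infeasible
  too. Both are rejected with the constraint named.
* **Rotation script.** Between episodes the cube rotates in single-axis
  segments at 25°/s: an alignment move that brings the next face to the
  preferred relative label (probability `focus`), plus mean-zero
  back-and-forth segments that consume the per-trial rotation budget.
  Stationary pauses flank every segment and raw samples are forced at
  segment boundaries, so the SLERP reconstruction lies exactly on the
  scripted path and the measured amount of rotation equals the planted
  per-axis maximum to within a degree. Touch is released for the whole gap
  (the hands turn the cube), which is what permits label self-transitions:
  the pre-switch explored label is the episode's own, not a mid-rotation
  transient, and gap time never enters the explored-frame statistics.
* **Calibrations from published statistics.** Quantities the study reports
  only implicitly fix several variance parameters: the trial-level SD of
  mean active cells (≈ 25% of target) reproduces the published Welch t
  statistics (≈ ±4.96 / 3.91) and the non-significant LB–SI comparison; SMC
  variability (participant 3%, trial SD 0.025) matches the within-group SD
  implied by the published t values; the rotation budget is lognormal with
  σ = 0.45 because the published 560°-vs-710° contrast is far from
  significance, implying within-group variability of hundreds of degrees;
  the duration model (slope −0.057, noise 0.14 on the log scale) plants the
  published r ≈ −0.38 coupling between active-cell count and exploration
  duration; focus probabilities (0.20 / 0.19 / 0.15) land the expected
  maximum diagonal score near the published 3.4 / 3.3 / 2.2 band. The
  published discriminant geometry — CB and LB scoring above SI on LD1 with
  CB apart — cannot arise from the published mean profiles of active cells
  and SMC alone at trial level (their implied Fisher combination puts LB
  marginally below SI), so the presets also encode a *focused exploration*
  gradient consistent with the published account of systematic exploration
  and spatial ability: episode dwell times drawn with gamma shape 0.5 (CB),
  1.0 (LB) and 12 (SI), so the blind groups concentrate exploration time on
  few faces while the sighted spread it evenly. This gradient expresses
  itself mainly in the per-face duration variability, whose published
  discriminant coefficient is positive.
* **Problem sizes.** Parameter-recovery checks use ≥ 2000 explored frames
  per preset (four 150 s explorations); group-separation checks use the full
  default cohort and 20 master seeds; the correlation-recovery check uses 96
  trials of 20 s explorations over 100 seeds. These sizes give the test
  statistics comfortable margins over their Monte Carlo noise.

What the simulator does **not** emulate: multi-face holding patterns (one
constant two-cell holding face is the minimal structure satisfying the
stable-holding premise), pressure or pin geometry, sensor noise or dropped
radio packets, smooth multi-axis rotation paths, and any decision process
behind the same/different response (responses are scripted labels with the
preset accuracy). Passing recovery tests therefore demonstrates that the
pipeline measures what the generative script planted under the study's
sampling conditions — not that real explorations satisfy the script's
structure.

## Numerical choices

Quaternions are scalar-first, active body-to-world; norms within 1e-3 of 1
are renormalized on read, larger deviations rejected. SLERP falls back to a
normalized linear blend below 1e-8 rad. Transition matrices store percentages
of the per-trial transition total; an all-zero matrix with a transition count
of zero represents trials with fewer than two episodes. The singular-W case
in the MANOVA names the collinear columns instead of silently regularizing.
Box-Cox λ is profiled on a fixed grid for reproducibility. All simulation
randomness flows from a single integer seed per session; cohort seeds are
drawn once from the master seed, so any participant's session can be
regenerated in isolation.

## Known limitations

Trial-level rows within a participant share that participant's jitter, so
trial-level tests treat correlated rows as independent — the same ambiguity
the published degrees of freedom exhibit; participant-level aggregation is
one switch away. The episode-level reading of the transition sequence makes
per-trial diagonal scores coarse (quantized near 9%), so transition metrics
discriminate groups only weakly at trial level. The importer for the study's
deposited recordings is an extension point: `read_session()` documents the
JSON-lines dialect, and mapping the deposit's native layout onto it is left
to the user.
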