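---
title: "Simulating and scoring gamified motor-imagery BCI training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring gamified motor-imagery BCI training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mibci)
```

## The problem

Motor-imagery (MI) brain-computer interfaces for post-stroke upper-limb
rehabilitation ask the patient to imagine a wrist dorsiflexion while a
decoder watches the EEG for the hallmark of imagery: event-related
desynchronization (ERD), a lateralized drop of band power in the mu
(8–12 Hz) and beta (18–26 Hz) rhythms over the sensorimotor cortex
contralateral to the imagined hand. Training protocols of this kind run
in fixed blocks — here, runs of 80 cued trials at a 9 s cadence — and
report per-run decoding accuracy as their efficacy measure. A
serious-game layer (protecting pieces of cheese from a rat) can be
placed on top of the visual feedback without altering the protocol's
pace; the scientific question is whether the game changes decodability
or only the experience.

`mibci` implements that entire evaluation as testable code: a synthetic
EEG generator with a known ground truth, the standard CSP + LDA
decoding chain, the game's scoring state machine, the two-session study
protocol, the repeated-measures statistics, and the satisfaction
questionnaire arithmetic. Everything downstream of the generator is the
same code one would point at real recordings.

## The synthetic EEG generator

`simulate_run()` builds a 16-channel recording (extended 10/20 montage
over FC/C/CP rows) as a sum of

* **1/f background**: independent per-channel Gaussian noise spectrally
  shaped to `f^-alpha` (`noise_exponent`, default 1), SD `noise_sd`
  (default 5 µV);
* **two lateralized rhythm sources**, one over C3 and one over C4, each
  a band-limited Gaussian process in the mu band (SD `mu_sd`, 10 µV)
  plus one in the beta band (SD `beta_sd`, 5 µV), projected with weight
  1 to the primary electrode, 0.5 to its immediate neighbours and 0
  elsewhere — a deliberately coarse spatial spread that keeps the CSP
  problem solvable with a known answer;
* **ERD**: during the imagery window (2–8 s of each 9 s trial) the
  source contralateral to the cued hand is multiplied by
  `sqrt(1 - erd_depth)` with a 0.2 s cosine ramp, so its *variance*
  drops by `erd_depth` (default 0.6);
* optionally, common-mode 50 Hz line interference (`line_amp`) and
  high-amplitude artifact trials (`artifact_rate`; a 0.5 s step of 10
  channel SDs on two random channels).

The amplitude scales were chosen once, on physiological grounds: over
sensorimotor cortex the idle mu rhythm dominates its own band, so the
generator puts roughly 25× more mu-band power into the rhythm than into
the background at C3/C4 (10 µV source vs ≈ 2 µV of background inside
8–12 Hz). A consequence one can measure directly (and the tests do): at
`erd_depth = 0.6` the mu-band variance at C3 during right-hand imagery
is ≈ 0.4 of its resting value — the configured attenuation plus a
little background leakage.

The class sequence is a seeded permutation of a balanced 40/40
assignment, and identical seeds give bit-identical runs. The sampling
rate is configurable (`fs`, default 256 Hz — typical for this hardware
class, not a protocol constant).

What the generator does **not** emulate: realistic head-volume
conduction, eye-blink/EMG artifacts, non-stationary rhythm amplitude
drift, inter-subject montage variability. Passing tests therefore show
that the chain is *correct and calibrated*, not that its accuracies
transfer to any particular patient population.

## The decoding chain

The chain follows the standard recipe for this protocol family:

1. `broadband_filter()` — per-channel demeaning, then zero-phase
   (forward–backward) Butterworth band-pass 0.5–30 Hz. The two edges
   are realized as separate 4th-order high-pass and low-pass stages: a
   single band-pass prototype with a 0.5 Hz edge at 256 Hz is
   numerically fragile, the cascade is not.
2. `notch_filter()` — a unity-gain biquad notch at 50 Hz (1 Hz
   bandwidth), applied forward–backward; skipped automatically when the
   sampling rate cannot represent 50 Hz.
3. `epoch_run()` — one 8 s epoch per trial, starting at the cue.
4. `reject_artifacts()` — a trial is dropped when, on any channel, its
   log peak amplitude exceeds the across-trial median by more than 5
   robust SDs (MAD scale). The log matters: raw per-trial maxima are
   right-skewed and ordinary clean trials reach raw-scale z ≈ 5–7,
   while on the log scale clean trials stay near z ≈ 4 and the injected
   artifacts sit above z ≈ 7. Rejection runs on the broadband epochs
   because amplitude artifacts are broadband; the 8–30 Hz filter
   attenuates step transients enough to hide some of them. A MAD of
   zero (identical trials) is floored so nothing is rejected, and at
   least two trials per class are always retained.
5. `narrowband_filter()` — zero-phase Butterworth band-pass 8–30 Hz per
   epoch (single band-pass prototype; both edges are comfortable here,
   and the high-pass/low-pass cascade would sag to 0.90 at 10 Hz).
6. `fit_csp()` / `apply_csp()` — Common Spatial Patterns on
   trial-averaged, trace-normalized class covariances (normalizing each
   trial's covariance by its trace makes the estimate robust to
   inter-trial amplitude drift). The generalized eigenproblem
   `C_L w = λ (C_L + C_R) w` is solved by whitening the composite
   covariance; near-singular composites get diagonal loading
   (`1e-8 · trace/16`). The 4 retained filters are the two most
   left-discriminative and two most right-discriminative (the extremes
   of the spectrum), each scaled so its largest coefficient is positive
   so results are reproducible across eigensolvers.
7. `extract_features()` — at 14 timepoints (1.5 s to 8 s in 0.5 s
   steps) the variance of each virtual channel over the *trailing*
   1.5 s window, floored at 1e-12, normalized to sum to one across the
   4 channels, then logged. Trailing windows make 1.5 s the earliest
   timepoint with a full window; the alignment is a package choice, the
   grid is the protocol's.
8. `train_lda()` / `crossval_accuracy()` — equal-prior two-class LDA
   with pooled within-class covariance (diagonal loading
   `1e-9 ·` mean diagonal when singular), trained on every
   (trial, timepoint) sample pooled; accuracies are evaluated per
   timepoint and per class on held-out *trials* in a stratified,
   seeded 10-fold split, and summarized per class as the maximum or
   the mean over the 14 timepoints.

### Design choices that were genuinely open

**Pooled vs per-timepoint LDA.** The protocol description ("all the
features from all the timepoints … a classifier") is ambiguous between
one pooled LDA and fourteen per-timepoint LDAs. The pooled reading is
the default — it matches the wording and yields per-timepoint curves
through per-timepoint evaluation — and `per_timepoint = TRUE` provides
the alternative for sensitivity checks.

**Where CSP sits relative to cross-validation.** Fitting CSP once on
the whole run and then cross-validating only the LDA — the procedure
the original acquisition software describes — leaks class information
into the held-out folds: on null data (no ERD) it reports ≈ 66%
"accuracy". `crossval_accuracy()` therefore refits the spatial filters
inside every fold by default (pass `epochs`), so that no stage sees
held-out trials and null data scores at chance; the fit-once variant is
retained (pass a ready feature block, or `csp_per_fold = FALSE` in
`mi_accuracy_pipeline()`) for comparison with the original procedure.
This is the package's most consequential deviation from a literal
reading, and it is what makes the chance-level calibration property
hold.

**Evaluation unit.** Held-out performance is scored per trial at each
timepoint (not per pooled sample), which is what a per-timepoint
accuracy curve over trials means.

## The game

`resolve_trial()` reads the classifier's boolean correctness events of
one trial; the cheese is saved iff the stream contains a run of ≥ 5
consecutive correct events. The phrase "five consecutive events" is
read as *at least one such run anywhere in the feedback stream* (the
temporal reading); a stricter suffix variant (the run must persist to
the end of the stream) is available as `rule = "suffix"`. One event is
emitted per feature timepoint inside the imagery window — the true
event cadence of the original system is unknown, and scoring only
depends on run structure, not rate. `init_game()`/`update_state()`
keep the ledger: 80 pieces staked, one lost per failed trial,
`user_score + rat_score` always equals trials resolved. The outcome is
monotone (turning a miss into a hit can never lose a saved cheese), and
the final pile depends only on the multiset of outcomes.

## The protocol

`run_subject()` simulates two sessions of Calibration / Training 1 /
Training 2 with independent noise, scores the five reported runs
(C-S1, T1-S1, T2-S1, T1-S2, T2-S2) by leak-free 10-fold CV, and drives
the game with the *online* decoder chain: T1 uses the
calibration-trained CSP+LDA, T2 an "enhanced" decoder refitted on the
pooled calibration + T1 trials (the original system's exact update
rule is proprietary; pooling the two stages is the plain reading of
"data from the previous two stages"). Sessions start from scratch —
session 2 never sees session-1 models. Calibration feedback is always
positive. The game consumes all 80 recorded trials; artifact rejection
affects only the offline analysis. Optional per-run `erd_offsets` let
a study inject true condition effects; with all offsets zero the five
runs are exchangeable, which is the protocol's own null.

## The statistics stage

`rm_anova()` implements the one-way within-subject decomposition
(`SS_total = SS_subjects + SS_condition + SS_error`,
`F = MS_cond/MS_err`) with Greenhouse–Geisser, Huynh–Feldt (classical
1976 form, `(n(k-1)ε_GG − 2)/((k−1)(n−1−(k−1)ε_GG))`, capped at 1) and
lower-bound (`1/(k−1)`) corrections applied to both degrees of freedom,
and listwise deletion of subjects with missing runs (logged). Note the
corrected-p ordering `p_LB ≥ p_GG ≥ p` is a property of `F ≥ 1` only;
for `F < 1` shrinking the degrees of freedom can *lower* the tail
probability, which published tables of this design also show.
`mauchly()` uses the Box chi-square series with the second-order term,
matching the standard multivariate-model implementation to 1e-6.
Normality gating, group comparison and correlation (`shapiro_wilk()`,
`mann_whitney_u()` — exact below 400 pairwise comparisons without ties,
tie-corrected normal approximation otherwise — `t_test_ind()`,
`pearson_cor()`) wrap the standard library tests; the package adds only
their domain checks and a uniform return shape. Which runs feed the
ANOVA cells is exposed as configuration (`study_cells()`), because the
published design leaves the cell selection ambiguous.

## The questionnaire

Eight Likert items (1–5) per subject with group and gaming-frequency
labels. `question_means()` averages per item; `overall_score()`
averages the eight means and reports two decimals with *half-up*
rounding (the convention of the summary table it reproduces — banker's
rounding would change printed values); `group_summary()` reports, per
stratum, n, the mean and SD of subjects' individual mean scores
(sample SD, absent for singleton strata) and per-question means. On
balanced tables the subject-level and question-level aggregation routes
agree exactly, and the overall score equals the group-size-weighted
mean of group scores — the identity behind the worked 4.20/5 example.
The published summary itself reports SDs that disagree between its
table and its text (0.37 vs 0.35, 0.68 vs 0.63); the package does not
resolve that discrepancy, it documents it.

## Numerical conventions and degenerate inputs

* Filters: zero-phase via forward–backward application; DC is removed
  by demeaning before the high-pass.
* Variance floor 1e-12 before feature normalization; covariance
  diagonal loading as above; MAD floor in rejection.
* Ties in LDA decisions (`w'x + b = 0`) go to the class listed first
  (left).
* `rm_anova` with zero condition variance returns `F = 0, p = 1`;
  `mauchly` with no within-subject variance returns perfect sphericity;
  `k = 2` is spherical by construction.
* All randomness (class sequences, noise, folds, simulations) is
  seeded; identical seeds give bit-identical results, and the CSV+JSON
  writers round-trip exactly at 9 significant digits.

## Problem sizes used by the test-suite and acceptance studies

Unit tests run the generator at 64 Hz with 24-trial runs (fast, same
band structure); calibration-sensitive checks — the chance-level null,
the ERD-recovery power property, and the PSD-ratio oracle — run at the
full study conditions (256 Hz, 80 trials) over 20 seeds each, and the
ANOVA calibration studies use 1000 replicates at n = 16 subjects,
k = 3 conditions. These sizes are the package's definition of "at
scale" for a desk reproduction: large enough that binomial bands and
KS tests have teeth, small enough to re-run routinely.

## Known limitations

* The generator's two-source, fixed-projection head model cannot probe
  spatial-filter behaviour under realistic volume conduction.
* The "enhanced" Training-2 decoder is a plain refit on pooled trials;
  the commercial system's update rule may weight stages differently.
* The artifact model exercises the rejection rule, nothing more;
  physiological artifact realism is out of scope.
* Real-time operation (pacing, online event generation against a live
  amplifier) is simulated instantaneously, not emulated.
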