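# mibci

Simulation and evaluation of a gamified motor-imagery (MI)
brain-computer interface rehabilitation protocol, in R.

In MI-BCI rehabilitation after stroke, the patient imagines a wrist
dorsiflexion while a decoder watches 16-channel EEG for event-related
desynchronization (ERD): a lateralized power drop of the mu (8–12 Hz)
and beta (18–26 Hz) rhythms over the sensorimotor cortex contralateral
to the imagined hand. Protocols of this family run 12-minute blocks of
80 cued trials, score each run by cross-validated decoding accuracy,
and can wrap the feedback in a serious game (save pieces of cheese from
a rat) without changing the protocol's pace. This package implements
that whole evaluation as tested, reusable code for methodologists who
want to study the pipeline itself — no recordings required:

* **`mi_eeg_sim`** — a seeded generator of synthetic MI runs: two
  lateralized mu+beta rhythm sources over C3/C4 on 1/f background
  noise, class-dependent ERD with configurable depth, optional 50 Hz
  line interference and artifact trials (`sim_config()`,
  `simulate_run()`, `erd_envelope()`).
* **decoding chain** — 0.5–30 Hz zero-phase band-pass, 50 Hz notch,
  8 s epochs, robust amplitude-based artifact rejection, 8–30 Hz
  narrow-band filter, Common Spatial Patterns (16 → 4 virtual
  channels, generalized eigenproblem `C_L w = λ (C_L + C_R) w`),
  log-variance features on a 14-point grid (trailing 1.5 s windows),
  equal-prior LDA, stratified 10-fold cross-validated per-timepoint
  accuracy curves with max/mean summaries
  (`mi_accuracy_pipeline()` and the individual stages).
* **game logic** — the cheese/rat state machine: a trial's cheese is
  saved iff the classifier-event stream contains ≥ 5 consecutive
  correct events (`init_game()`, `resolve_trial()`, `update_state()`).
* **protocol** — two sessions × (Calibration, Training 1, Training 2),
  T1 decoded online with the calibration model, T2 with a refit on
  pooled C+T1 trials, sessions independent (`run_subject()`,
  `run_study()`).
* **stats** — one-way repeated-measures ANOVA with Mauchly's test and
  Greenhouse–Geisser / Huynh–Feldt / lower-bound corrections, plus the
  normality-gated group comparisons (`rm_anova()`, `mauchly()`,
  `shapiro_wilk()`, `mann_whitney_u()`, `t_test_ind()`,
  `pearson_cor()`).
* **questionnaire** — 8-item Likert satisfaction scoring with
  group/gaming-experience summaries (`question_means()`,
  `overall_score()`, `group_summary()`).

## Worked example

```r
library(mibci)

cfg <- sim_config(seed = 42)      # 16 ch, 256 Hz, 80 trials, ERD depth 0.6
run <- simulate_run(cfg)
res <- mi_accuracy_pipeline(run, cv_seed = 1)
print(res$accuracy)
```

```
<accuracy_result> 10-fold CV over 14 timepoints
  max accuracy:  left 100.0%  right 100.0%
  mean accuracy: left 86.6%  right 87.0%
```

At the study's ERD depth (0.6) the decoder finds the lateralized
power drop easily: the maximum of the per-timepoint accuracy curve
("Max. Accuracy") saturates near 100%, while its mean over the 14
timepoints ("Mean Accuracy") sits in the 80s because early timepoints
carry little imagery signal. With `erd_depth = 0` the same chain
scores at chance (the cross-validation refits the spatial filters per
fold, so nothing leaks).

The game layer on the same subject:

```r
sub <- run_subject(sim_config(erd_depth = 0.6), seed = 5)
sub$game[["T1-S1"]]
```

```
<game_state> trial 80/80: cheese 80, user 80, rat 0 (panel: intermittent)
```

The scripts under `analysis/` run these pieces at study scale:
`01_simulate_example_run.R` (one archived run plus the ground-truth
ERD ratio), `02_decode_cohort.R` (a 6 healthy + 10 stroke cohort
through both sessions), `03_game_session.R` (cheese ledgers per run),
`04_condition_stats.R` (the repeated-measures comparison of feedback
conditions and the group baseline test), `05_questionnaire.R` (the
satisfaction arithmetic). Each writes its tables under `results/`.

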