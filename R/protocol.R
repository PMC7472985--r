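#' Session plan for the two-session training protocol
#'
#' Each session consists of three runs: Calibration (C), Training 1
#' (T1) and Training 2 (T2). T1 is decoded with the classifier fitted
#' on the calibration run; T2 with an enhanced classifier refitted on
#' the pooled calibration + T1 trials. Sessions start from scratch:
#' session 2 never reuses session-1 classifiers. During calibration the
#' online feedback is always positive regardless of the decoder.
#'
#' @param feedback Named character vector giving the feedback condition
#'   of each run, conditions among `"standard-avatar"`,
#'   `"game-no-feedback"`, `"game-intermittent"`, `"game-constant"`.
#' @return An object of class `session_plan`.
#' @export
session_plan <- function(feedback = c(C = "standard-avatar",
                                      T1 = "game-intermittent",
                                      T2 = "game-constant")) {
  stopifnot(identical(names(feedback), c("C", "T1", "T2")))
  ok <- c("standard-avatar", "game-no-feedback", "game-intermittent",
          "game-constant")
  if (!all(feedback %in% ok))
    stop("unknown feedback condition(s): ",
         paste(setdiff(feedback, ok), collapse = ", "), call. = FALSE)
  structure(list(runs = c("C", "T1", "T2"), feedback = feedback,
                 classifier_source = c(C = "C", T1 = "C", T2 = "C+T1")),
            class = "session_plan")
}

# Classifier-correctness events of one run under a given CSP + LDA:
# one boolean per feature timepoint inside the MI window per trial.
# During calibration the feedback is always positive.
run_events <- function(fb, csp_lda, mi_window, always_positive = FALSE) {
  d <- dim(fb$values)
  in_win <- fb$timepoints >= mi_window[1] & fb$timepoints <= mi_window[2]
  lapply(seq_len(d[1]), function(i) {
    if (always_positive) return(rep(TRUE, sum(in_win)))
    X <- fb$values[i, in_win, , drop = TRUE]
    dim(X) <- c(sum(in_win), d[3])
    as.vector(predict(csp_lda$lda, X) == fb$labels[i])
  })
}

# Fit CSP + pooled LDA on one or more runs' preprocessed epochs.
fit_decoder <- function(es_list) {
  es <- es_list[[1]]
  if (length(es_list) > 1) {
    es$epochs <- do.call(abind_trials, lapply(es_list, `[[`, "epochs"))
    es$labels <- factor(unlist(lapply(es_list, function(e) as.character(e$labels))),
                        levels = c("left", "right"))
    es$kept_mask <- rep(TRUE, dim(es$epochs)[1])
  }
  csp <- fit_csp(es)
  fb <- extract_features(apply_csp(csp, es))
  list(csp = csp, lda = train_lda(fb))
}

abind_trials <- function(...) {
  mats <- list(...)
  d <- dim(mats[[1]])
  total <- sum(vapply(mats, function(m) dim(m)[1], numeric(1)))
  out <- array(0, dim = c(total, d[2], d[3]))
  at <- 0
  for (m in mats) {
    out[at + seq_len(dim(m)[1]), , ] <- m
    at <- at + dim(m)[1]
  }
  out
}

#' Simulate and score one subject through the full protocol
#'
#' Simulates two sessions of three runs each (C, T1, T2) with
#' independent noise realizations, preprocesses every run (broadband +
#' notch, epoching, narrow-band, artifact rejection), and scores the
#' five reported runs (C-S1, T1-S1, T2-S1, T1-S2, T2-S2) by 10-fold
#' cross-validation with CSP + LDA refitted within the scored run.
#' Separately, the plan's online decoder chain (C-trained for T1,
#' C+T1-trained for T2, always-positive for C) generates the boolean
#' event streams that drive the serious game.
#'
#' Optional per-run ERD-depth offsets emulate condition effects; with
#' all offsets zero the five runs are exchangeable draws, matching a
#' protocol in which feedback modality does not alter decodability.
#'
#' @param config A [sim_config()] for this subject.
#' @param plan A [session_plan()].
#' @param seed Subject-level seed; run seeds are derived from it.
#' @param erd_offsets Named numeric offsets added to `config$erd_depth`
#'   per run label (e.g. `c("T1-S1" = 0.05)`).
#' @param cv_seed Seed for CV fold assignment.
#' @return List with `accuracy` (data frame: run, class, max, mean),
#'   `game` (per training run, final `game_state`), `plan`, `seed`.
#' @export
run_subject <- function(config, plan = session_plan(), seed = 1,
                        erd_offsets = NULL, cv_seed = seed) {
  run_ids <- c("C-S1", "T1-S1", "T2-S1", "C-S2", "T1-S2", "T2-S2")
  reported <- c("C-S1", "T1-S1", "T2-S1", "T1-S2", "T2-S2")
  seeds <- seed * 1000L + seq_along(run_ids)

  prep <- full <- list()
  for (i in seq_along(run_ids)) {
    cfg <- config
    cfg$seed <- seeds[i]
    off <- if (!is.null(erd_offsets) && run_ids[i] %in% names(erd_offsets))
      erd_offsets[[run_ids[i]]] else 0
    cfg$erd_depth <- min(max(cfg$erd_depth + off, 0), 1)
    run <- simulate_run(cfg)
    run <- broadband_filter(run)
    if (50 < run$fs / 2) run <- notch_filter(run)
    es <- narrowband_filter(epoch_run(run, epoch_len = cfg$epoch_len))
    # offline analysis drops artifact trials; the online game saw them all
    full[[run_ids[i]]] <- es
    prep[[run_ids[i]]] <- kept_epochs(reject_artifacts(es))
  }

  # offline accuracy: CV within each reported run
  acc_rows <- list()
  for (id in reported) {
    res <- crossval_accuracy(NULL, k = 10, seed = cv_seed,
                             epochs = prep[[id]])
    acc_rows[[id]] <- data.frame(
      run = id, class = c("left", "right"),
      max = as.vector(res$summary_max), mean = as.vector(res$summary_mean))
  }
  accuracy <- do.call(rbind, c(acc_rows, make.row.names = FALSE))

  # online decoder chain per session -> game event streams
  game <- list()
  for (s in c("S1", "S2")) {
    dec_C <- fit_decoder(prep[paste0("C-", s)])
    dec_T2 <- fit_decoder(prep[paste0(c("C-", "T1-"), s)])
    for (r in c("C", "T1", "T2")) {
      id <- paste0(r, "-", s)
      dec <- switch(r, C = dec_C, T1 = dec_C, T2 = dec_T2)
      fb <- extract_features(apply_csp(dec$csp, full[[id]]))
      ev <- run_events(fb, dec, config$mi_window,
                       always_positive = (r == "C"))
      panel <- switch(plan$feedback[[r]],
                      "game-intermittent" = "intermittent",
                      "game-constant" = "constant", "none")
      game[[id]] <- play_game(ev, panel_mode = panel)
    }
  }
  list(accuracy = accuracy, game = game, plan = plan, seed = seed)
}

#' Run a cohort of simulated subjects
#'
#' @param n_subjects Number of subjects.
#' @param config Base [sim_config()] shared by all subjects.
#' @param plan A [session_plan()].
#' @param seed Cohort seed; subject seeds are `seed * 100 + 1..n`.
#' @param erd_offsets Per-run ERD offsets, as in [run_subject()].
#' @return List with `table` (subject x run accuracy data frame in the
#'   reported five-column layout, one row per subject x class x
#'   summary mode) and `subjects` (per-subject results).
#' @export
run_study <- function(n_subjects, config = sim_config(),
                      plan = session_plan(), seed = 1,
                      erd_offsets = NULL) {
  subjects <- lapply(seq_len(n_subjects), function(i)
    run_subject(config, plan, seed = seed * 100L + i,
                erd_offsets = erd_offsets))
  rows <- list()
  for (i in seq_len(n_subjects)) {
    acc <- subjects[[i]]$accuracy
    for (mode in c("max", "mean")) {
      w <- stats::reshape(acc[, c("run", "class", mode)],
                          direction = "wide", idvar = "class",
                          timevar = "run")
      names(w) <- c("class", unique(acc$run))
      w <- data.frame(subject = i, mode = mode, w, check.names = FALSE)
      rows[[length(rows) + 1]] <- w
    }
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       subjects = subjects)
}

#' Accuracy cells for the repeated-measures comparison
#'
#' Extracts a subjects x conditions matrix of per-subject accuracies
#' (averaged over the two classes) for a chosen set of runs and summary
#' mode, ready for [rm_anova()]. Which runs feed the comparison is
#' configuration, not convention.
#'
#' @param study Result of [run_study()].
#' @param cells Run labels to compare.
#' @param mode `"max"` or `"mean"` summary.
#' @return Numeric matrix, `n_subjects` x `length(cells)`.
#' @export
study_cells <- function(study, cells = c("T2-S1", "T1-S2", "T2-S2"),
                        mode = c("max", "mean")) {
  mode <- match.arg(mode)
  tab <- study$table[study$table$mode == mode, ]
  out <- sapply(cells, function(cl)
    tapply(tab[[cl]], tab$subject, mean))
  out <- matrix(out, ncol = length(cells),
                dimnames = list(NULL, cells))
  out
}
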