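#' Initialize the cheese-versus-rat game
#'
#' One piece of cheese is staked per exercise (trial). The score panel
#' can be hidden, shown intermittently, or shown constantly; the mode
#' only affects what is displayed, never the scoring.
#'
#' @param n_trials Number of trials (cheese pieces), `>= 1`.
#' @param panel_mode One of `"none"`, `"intermittent"`, `"constant"`.
#' @return An object of class `game_state`: `cheese`, `initial_cheese`,
#'   `trial_index`, `outcomes` (character per resolved trial),
#'   `panel_mode`, `user_score`, `rat_score`.
#' @export
init_game <- function(n_trials = 80,
                      panel_mode = c("none", "intermittent", "constant")) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  panel_mode <- match.arg(panel_mode)
  structure(list(cheese = as.integer(n_trials),
                 initial_cheese = as.integer(n_trials),
                 trial_index = 0L, outcomes = character(0),
                 panel_mode = panel_mode,
                 user_score = 0L, rat_score = 0L),
            class = "game_state")
}

#' Resolve one trial from its classifier-event stream
#'
#' The classifier emits one boolean per feedback event saying whether
#' the mental image was decoded as correct at that moment. The cheese
#' is saved when the stream contains a run of at least `run_len`
#' consecutive correct events; otherwise the rat takes it. With
#' `rule = "suffix"` only a correct run ending at the last event saves
#' the cheese (stricter reading in which the run must persist into the
#' relax sub-stage).
#'
#' @param events Non-empty logical vector of correctness events.
#' @param run_len Required consecutive-correct run length.
#' @param rule `"anywhere"` (default) or `"suffix"`.
#' @return `"saved"` or `"taken"`.
#' @export
resolve_trial <- function(events, run_len = 5,
                          rule = c("anywhere", "suffix")) {
  rule <- match.arg(rule)
  if (length(events) == 0) stop("empty event sequence", call. = FALSE)
  events <- as.logical(events)
  saved <- switch(rule,
    anywhere = {
      r <- rle(events)
      any(r$values & r$lengths >= run_len)
    },
    suffix = {
      n <- length(events)
      n >= run_len && all(events[(n - run_len + 1):n])
    })
  if (saved) "saved" else "taken"
}

#' Advance the game state by one resolved trial
#'
#' A taken cheese decrements the pile and scores for the rat; a saved
#' one scores for the user. `user_score + rat_score` always equals the
#' number of resolved trials, and `cheese = initial - taken`.
#'
#' @param state A `game_state`.
#' @param outcome `"saved"` or `"taken"`.
#' @return The updated `game_state`.
#' @export
update_state <- function(state, outcome = c("saved", "taken")) {
  outcome <- match.arg(outcome)
  if (state$trial_index >= state$initial_cheese)
    stop("all ", state$initial_cheese, " trials already resolved",
         call. = FALSE)
  state$trial_index <- state$trial_index + 1L
  state$outcomes <- c(state$outcomes, outcome)
  if (outcome == "taken") {
    state$cheese <- state$cheese - 1L
    state$rat_score <- state$rat_score + 1L
  } else {
    state$user_score <- state$user_score + 1L
  }
  state
}

#' Play a full session from per-trial event streams
#'
#' @param event_streams List of logical vectors, one per trial.
#' @param panel_mode Score panel mode, recorded in the state.
#' @param run_len,rule Passed to [resolve_trial()].
#' @return Final `game_state` after all trials.
#' @export
play_game <- function(event_streams, panel_mode = "none",
                      run_len = 5, rule = "anywhere") {
  state <- init_game(length(event_streams), panel_mode)
  for (ev in event_streams)
    state <- update_state(state, resolve_trial(ev, run_len, rule))
  state
}

#' @export
print.game_state <- function(x, ...) {
  cat(sprintf("<game_state> trial %d/%d: cheese %d, user %d, rat %d (panel: %s)\n",
              x$trial_index, x$initial_cheese, x$cheese,
              x$user_score, x$rat_score, x$panel_mode))
  invisible(x)
}

#' Write a game log as JSON lines
#'
#' One JSON object per resolved trial (`trial`, `outcome`,
#' `cheese_after`).
#'
#' @param state A `game_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_game_log <- function(state, path) {
  cheese <- state$initial_cheese - cumsum(state$outcomes == "taken")
  lines <- vapply(seq_along(state$outcomes), function(i)
    jsonlite::toJSON(list(trial = i, outcome = state$outcomes[i],
                          cheese_after = cheese[i]),
                     auto_unbox = TRUE), character(1))
  writeLines(lines, path)
  invisible(path)
}
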