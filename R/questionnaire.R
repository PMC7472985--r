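#' Read a questionnaire response table
#'
#' One row per subject with columns `group` (`healthy`/`stroke`),
#' `gaming_freq` (`never`, `almost never`, `sometimes`, `often`,
#' `usually`, `always`) and the eight Likert items `q1..q8` (integers
#' 1-5).
#'
#' @param path CSV path.
#' @return Validated data frame of class `response_table`.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_responses(df)
}

validate_responses <- function(df) {
  items <- paste0("q", 1:8)
  if (!all(c("group", "gaming_freq", items) %in% names(df)))
    stop("response table needs columns group, gaming_freq, q1..q8",
         call. = FALSE)
  for (it in items) {
    v <- df[[it]]
    if (any(v != round(v)) || any(v < 1) || any(v > 5))
      stop("item ", it, " has scores outside the 1-5 Likert range",
           call. = FALSE)
  }
  ok_freq <- c("never", "almost never", "sometimes", "often", "usually",
               "always")
  if (!all(df$gaming_freq %in% ok_freq))
    stop("unknown gaming_freq level(s): ",
         paste(setdiff(df$gaming_freq, ok_freq), collapse = ", "),
         call. = FALSE)
  class(df) <- c("response_table", "data.frame")
  df
}

#' Per-question mean scores
#'
#' @param table A `response_table`.
#' @param filter Optional logical vector selecting subjects.
#' @return Named numeric vector of the 8 per-question means.
#' @export
question_means <- function(table, filter = NULL) {
  items <- paste0("q", 1:8)
  if (!is.null(filter)) table <- table[filter, , drop = FALSE]
  if (nrow(table) == 0) stop("no subjects selected", call. = FALSE)
  colMeans(table[, items])
}

# Round half away from zero at `digits` decimals (commercial rounding,
# unlike R's banker's rounding).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Overall satisfaction score
#'
#' Unweighted mean of the eight per-question means, reported to two
#' decimals with half-up rounding (the convention of the summary table
#' it reproduces).
#'
#' @param per_question_means Numeric vector of the 8 question means.
#' @param digits Decimals to report (`NULL` for unrounded).
#' @return Scalar overall score.
#' @export
overall_score <- function(per_question_means, digits = 2) {
  if (length(per_question_means) != 8)
    stop("expected 8 per-question means, got ",
         length(per_question_means), call. = FALSE)
  m <- mean(per_question_means)
  if (is.null(digits)) m else round_half_up(m, digits)
}

#' Group-and-gaming-experience summary of questionnaire results
#'
#' One row for all subjects, one per group, and one per gaming
#' frequency stratum within group: group size `n`, mean and SD of the
#' subjects' individual mean scores (sample SD; absent for a single
#' subject), and the eight per-question means.
#'
#' @param table A `response_table`.
#' @return Data frame in the summary-table layout.
#' @export
group_summary <- function(table) {
  items <- paste0("q", 1:8)
  subj_mean <- rowMeans(table[, items])
  row_for <- function(label, idx) {
    if (length(idx) == 0) return(NULL)
    data.frame(row = label, n = length(idx),
               mean = round_half_up(mean(subj_mean[idx]), 2),
               sd = if (length(idx) > 1)
                 round_half_up(stats::sd(subj_mean[idx]), 2) else NA_real_,
               t(round_half_up(colMeans(table[idx, items, drop = FALSE]), 2)),
               check.names = FALSE)
  }
  out <- list(row_for("All", seq_len(nrow(table))))
  for (g in unique(table$group)) {
    in_g <- which(table$group == g)
    out <- c(out, list(row_for(g, in_g)))
    for (fr in unique(table$gaming_freq[in_g]))
      out <- c(out, list(row_for(paste0(g, "/", fr),
                                 in_g[table$gaming_freq[in_g] == fr])))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Simulate a questionnaire response table
#'
#' Synthetic stand-in for the study's satisfaction questionnaire:
#' item scores drawn from a discretized normal around a per-question
#' target mean (high satisfaction, around 4 of 5), with a cohort of
#' healthy volunteers and stroke patients and random gaming-experience
#' strata.
#'
#' @param n_healthy,n_stroke Group sizes.
#' @param target_means Length-8 vector of target item means.
#' @param seed Seed.
#' @return A `response_table`.
#' @export
simulate_responses <- function(n_healthy = 6, n_stroke = 10,
                               target_means = c(3.3, 3.8, 4.4, 4.7,
                                                4.4, 4.3, 4.3, 4.5),
                               seed = 1) {
  stopifnot(length(target_means) == 8)
  n <- n_healthy + n_stroke
  with_local_seed(seed, {
    df <- data.frame(
      group = rep(c("healthy", "stroke"), c(n_healthy, n_stroke)),
      gaming_freq = sample(c("never", "almost never", "sometimes",
                             "often"), n, replace = TRUE))
    for (j in 1:8)
      df[[paste0("q", j)]] <-
        pmin(pmax(round(stats::rnorm(n, target_means[j], 0.8)), 1), 5)
    validate_responses(df)
  })
}

#' Write a questionnaire summary as TSV
#'
#' @param summary Result of [group_summary()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
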