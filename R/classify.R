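#' Timepoint grid for accuracy curves
#'
#' Inclusive arithmetic grid of feature timepoints within the epoch.
#' Defaults give the 14 points 1.5, 2.0, ..., 8.0 s.
#'
#' @param epoch_len Epoch length (grid end) in seconds.
#' @param start First timepoint in seconds.
#' @param step Grid step in seconds (> 0).
#' @return Numeric vector of timepoints.
#' @export
timepoint_grid <- function(epoch_len = 8, start = 1.5, step = 0.5) {
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  if (start > epoch_len)
    stop("start (", start, " s) exceeds epoch length (", epoch_len, " s)",
         call. = FALSE)
  seq(start, epoch_len, by = step)
}

#' Windowed log-variance features
#'
#' For each timepoint `t`, computes the variance of each virtual
#' channel over the trailing window `[t - window_len, t]` (clipped to
#' the epoch start), floors each variance at `1e-12`, normalizes the
#' variances to sum to one across channels, and takes the natural log.
#' By construction `exp(features)` sums to 1 over the channels at every
#' (trial, timepoint).
#'
#' @param es An `epoch_set` of CSP virtual channels (typically 4).
#' @param grid Timepoints in seconds (see [timepoint_grid()]).
#' @param window_len Trailing window length in seconds.
#' @return An object of class `feature_block`: `values` (array trials x
#'   timepoints x channels), `timepoints`, `labels`, `window_len`.
#' @export
extract_features <- function(es, grid = timepoint_grid(), window_len = 1.5) {
  d <- dim(es$epochs)
  n_samp <- d[3]
  fs <- es$fs
  if (any(grid * fs < 1))
    stop("window entirely outside the epoch for timepoint(s) ",
         paste(grid[grid * fs < 1], collapse = ", "), call. = FALSE)
  values <- array(0, dim = c(d[1], length(grid), d[2]))
  for (j in seq_along(grid)) {
    t1 <- max(1L, round((grid[j] - window_len) * fs) + 1L)
    t2 <- min(n_samp, round(grid[j] * fs))
    seg <- es$epochs[, , t1:t2, drop = FALSE]
    len <- t2 - t1 + 1L
    s1 <- rowSums(seg, dims = 2)
    s2 <- rowSums(seg^2, dims = 2)
    v <- pmax((s2 - s1^2 / len) / (len - 1), 1e-12)   # trials x channels
    values[, j, ] <- log(v / rowSums(v))
  }
  structure(list(values = values, timepoints = grid, labels = es$labels,
                 window_len = window_len),
            class = "feature_block")
}

#' Two-class linear discriminant analysis (equal priors)
#'
#' Pools every (trial, timepoint) pair of the feature block into one
#' training sample and fits the closed-form two-class LDA with pooled
#' within-class covariance and equal priors: `w = Sigma^{-1} (mu_R -
#' mu_L)`, bias from the class-mean midpoint. A singular pooled
#' covariance is handled by diagonal loading (`1e-9` of the mean
#' diagonal). The decision value is `w'x + b`; positive means `right`,
#' ties break toward `left` (the class listed first).
#'
#' @param fb A `feature_block` (or a plain samples x features matrix
#'   via `lda_fit`).
#' @param timepoint Optional single timepoint index: train on that
#'   timepoint only (per-timepoint variant) instead of pooling.
#' @return An object of class `lda_model`: `weights`, `bias`,
#'   `class_order = c("left", "right")`, `training_scope`.
#' @export
train_lda <- function(fb, timepoint = NULL) {
  d <- dim(fb$values)
  if (is.null(timepoint)) {
    X <- matrix(aperm(fb$values, c(2, 1, 3)), ncol = d[3])
    y <- rep(fb$labels, each = d[2])
    scope <- "pooled-timepoints"
  } else {
    X <- fb$values[, timepoint, , drop = TRUE]
    dim(X) <- c(d[1], d[3])
    y <- fb$labels
    scope <- paste0("timepoint-", timepoint)
  }
  m <- lda_fit(X, y)
  m$training_scope <- scope
  m
}

lda_fit <- function(X, y) {
  y <- factor(as.character(y), levels = c("left", "right"))
  if (any(table(y) == 0))
    stop("both classes must be present to train LDA", call. = FALSE)
  mu_L <- colMeans(X[y == "left", , drop = FALSE])
  mu_R <- colMeans(X[y == "right", , drop = FALSE])
  center <- function(cl) {
    Z <- X[y == cl, , drop = FALSE]
    sweep(Z, 2, colMeans(Z))
  }
  Zl <- center("left"); Zr <- center("right")
  S <- (crossprod(Zl) + crossprod(Zr)) / (nrow(X) - 2)
  S <- S + diag(1e-9 * mean(diag(S)), ncol(S))
  w <- solve(S, mu_R - mu_L)
  b <- -sum(w * (mu_L + mu_R) / 2)
  structure(list(weights = w, bias = b,
                 class_order = c("left", "right"),
                 training_scope = "pooled-timepoints"),
            class = "lda_model")
}

#' Predict classes from an LDA model
#'
#' @param object An `lda_model`.
#' @param X Samples x features matrix.
#' @param ... Unused.
#' @return Factor of predicted classes (`left`/`right`); the decision
#'   value `w'x + b > 0` maps to `right`, ties to `left`.
#' @export
predict.lda_model <- function(object, X, ...) {
  score <- drop(X %*% object$weights) + object$bias
  factor(ifelse(score > 0, "right", "left"), levels = c("left", "right"))
}

# Seeded stratified k-fold assignment at the trial level.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Subset an epoch_set to a set of trials.
subset_epochs <- function(es, idx) {
  es$epochs <- es$epochs[idx, , , drop = FALSE]
  es$labels <- factor(as.character(es$labels[idx]),
                      levels = c("left", "right"))
  es$kept_mask <- rep(TRUE, length(idx))
  es
}

#' Cross-validated per-timepoint accuracy curves
#'
#' Stratified k-fold cross-validation at the trial level (all
#' timepoints of a trial stay in one fold). Per fold, an LDA is trained
#' on the training trials — pooling all timepoints by default, or one
#' LDA per timepoint when `per_timepoint = TRUE` — and held-out trials
#' are scored per timepoint and per class; fold accuracies are
#' averaged.
#'
#' When `epochs` is supplied, the CSP spatial filters are also refitted
#' inside every fold on the training trials only and features are
#' re-extracted, so no stage of the chain sees held-out data. Fitting
#' CSP once outside the loop (passing a ready `fb` only) reproduces the
#' evaluation described for the original acquisition software but is
#' optimistically biased, visibly so on null data.
#'
#' @param fb A `feature_block` with at least `k` trials per class, or
#'   `NULL` when `epochs` is given.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param per_timepoint Train one LDA per timepoint instead of pooling.
#' @param epochs Optional narrow-band `epoch_set` (pre-CSP); triggers
#'   per-fold CSP refitting.
#' @param n_filters,grid,window_len CSP/feature settings used when
#'   refitting per fold.
#' @return An object of class `accuracy_result`: `acc` (class x
#'   timepoint matrix, percent), `per_fold` (fold x class x timepoint
#'   array), `folds`, `summary_max`, `summary_mean` (named per-class
#'   vectors), `timepoints`.
#' @export
crossval_accuracy <- function(fb, k = 10, seed = 1, per_timepoint = FALSE,
                              epochs = NULL, n_filters = 4,
                              grid = timepoint_grid(), window_len = 1.5) {
  labels <- if (is.null(epochs)) fb$labels else epochs$labels
  if (!is.null(fb)) grid <- fb$timepoints
  n_class <- table(labels)
  if (k > min(n_class))
    stop("k = ", k, " folds exceeds the smallest class size (",
         min(n_class), ")", call. = FALSE)
  n_tp <- length(grid)
  fold <- stratified_folds(labels, k, seed)
  per_fold <- array(NA_real_, dim = c(k, 2, n_tp),
                    dimnames = list(NULL, c("left", "right"), NULL))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (is.null(epochs)) {
      fb_f <- fb
    } else {
      csp_f <- fit_csp(subset_epochs(epochs, which(tr)), n_filters)
      fb_f <- extract_features(apply_csp(csp_f, epochs), grid, window_len)
    }
    d <- dim(fb_f$values)
    fb_tr <- list(values = fb_f$values[tr, , , drop = FALSE],
                  labels = labels[tr], timepoints = grid,
                  window_len = fb_f$window_len)
    class(fb_tr) <- "feature_block"
    te <- which(!tr)
    pooled <- if (!per_timepoint) train_lda(fb_tr)
    for (j in seq_len(n_tp)) {
      model <- if (per_timepoint) train_lda(fb_tr, timepoint = j) else pooled
      Xte <- fb_f$values[te, j, , drop = TRUE]
      dim(Xte) <- c(length(te), d[3])
      pred <- predict(model, Xte)
      for (cl in c("left", "right")) {
        in_cl <- labels[te] == cl
        per_fold[f, cl, j] <- 100 * mean(pred[in_cl] == cl)
      }
    }
  }
  acc <- apply(per_fold, c(2, 3), mean, na.rm = TRUE)
  structure(list(acc = acc, per_fold = per_fold, folds = k,
                 summary_max = apply(acc, 1, max),
                 summary_mean = apply(acc, 1, mean),
                 timepoints = grid),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<accuracy_result> %d-fold CV over %d timepoints\n",
              x$folds, length(x$timepoints)))
  cat(sprintf("  max accuracy:  left %.1f%%  right %.1f%%\n",
              x$summary_max["left"], x$summary_max["right"]))
  cat(sprintf("  mean accuracy: left %.1f%%  right %.1f%%\n",
              x$summary_mean["left"], x$summary_mean["right"]))
  invisible(x)
}

#' Summarize an accuracy curve
#'
#' Per-class maximum ("Max. Accuracy") or arithmetic mean ("Mean
#' Accuracy") of the cross-validated accuracy curve across timepoints.
#'
#' @param result An `accuracy_result`.
#' @param mode `"max"` or `"mean"`.
#' @return Named per-class vector in percent.
#' @export
summarize_accuracy <- function(result, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  if (length(result$acc) == 0) stop("empty accuracy matrix", call. = FALSE)
  switch(mode,
         max = apply(result$acc, 1, max),
         mean = apply(result$acc, 1, mean))
}

#' Write an accuracy result as TSV + JSON summary
#'
#' @param result An `accuracy_result`.
#' @param path Base path; `<path>.tsv` (class x timepoint curve) and
#'   `<path>.json` (summaries) are written.
#' @return `path`, invisibly.
#' @export
write_accuracy <- function(result, path) {
  df <- data.frame(class = rownames(result$acc), result$acc,
                   check.names = FALSE)
  names(df)[-1] <- sprintf("t%.1f", result$timepoints)
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(folds = result$folds,
                            summary_max = as.list(result$summary_max),
                            summary_mean = as.list(result$summary_mean)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Full single-run decoding chain
#'
#' Convenience wrapper running the complete offline chain on one run:
#' broadband filter (0.5-30 Hz), 50 Hz notch, 8 s epoching, artifact
#' rejection on the broadband epochs (amplitude artifacts live there),
#' narrow-band filter (8-30 Hz), CSP (16 -> 4 virtual
#' channels), log-variance features on the 14-point grid, and 10-fold
#' cross-validated accuracy curves.
#'
#' By default the CSP filters are refitted inside every CV fold
#' (leak-free evaluation); pass a pre-fitted `csp` model or
#' `csp_per_fold = FALSE` for the fit-once variant.
#'
#' @param run An `mi_run`.
#' @param cv_seed Seed for the CV fold assignment.
#' @param z_threshold Artifact-rejection robust-z cut-off.
#' @param csp A pre-fitted `csp_model` to reuse, or `NULL` to fit on
#'   this run.
#' @param csp_per_fold Refit CSP within each CV fold (ignored when
#'   `csp` is supplied).
#' @return List with `accuracy` (an `accuracy_result`), `csp` (the
#'   full-data model, for reuse/inspection), `features` and `epochs`
#'   (post-rejection).
#' @export
mi_accuracy_pipeline <- function(run, cv_seed = 1, z_threshold = 5,
                                 csp = NULL, csp_per_fold = is.null(csp)) {
  run <- broadband_filter(run)
  if (50 < run$fs / 2) run <- notch_filter(run)   # line freq must be below Nyquist

  es <- kept_epochs(reject_artifacts(epoch_run(run), z_threshold))
  es <- narrowband_filter(es)
  csp_full <- if (is.null(csp)) fit_csp(es) else csp
  fb <- extract_features(apply_csp(csp_full, es))
  acc <- if (csp_per_fold)
    crossval_accuracy(NULL, k = 10, seed = cv_seed, epochs = es)
  else
    crossval_accuracy(fb, k = 10, seed = cv_seed)
  list(accuracy = acc, csp = csp_full, features = fb, epochs = es)
}
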