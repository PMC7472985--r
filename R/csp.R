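#' Fit a Common Spatial Patterns filter bank
#'
#' Estimates per-class spatial covariances as trial-averaged,
#' trace-normalized covariance matrices and solves the generalized
#' eigenproblem `C_L w = lambda (C_L + C_R) w` by whitening the
#' composite covariance. Eigenvalues are the left-class variance ratios
#' `w' C_L w / w' (C_L + C_R) w`, sorted descending in `[0, 1]`; the
#' filters kept are the extremes of the spectrum (`n_filters / 2` most
#' left-discriminative and as many most right-discriminative).
#'
#' Each filter is scaled so its largest-magnitude coefficient is
#' positive, making results reproducible across eigensolvers.
#'
#' @param es A narrow-band filtered `epoch_set` with at least 2 kept
#'   trials per class.
#' @param n_filters Number of spatial filters (even; default 4).
#' @param reg Diagonal-loading factor applied to the composite
#'   covariance when it is near-singular, as a fraction of
#'   `trace / n_channels`.
#' @return An object of class `csp_model`: `filters` (n_filters x
#'   channels), `patterns`, `eigenvalues` (all channels, descending),
#'   `selected_idx`, `band`, `n_train_trials`, `channel_names`.
#' @export
fit_csp <- function(es, n_filters = 4, reg = 1e-8) {
  stopifnot(n_filters %% 2 == 0)
  es <- kept_epochs(es)
  for (cl in c("left", "right"))
    if (sum(es$labels == cl) < 2)
      stop("need >= 2 kept trials per class to fit CSP (class ", cl,
           " has ", sum(es$labels == cl), ")", call. = FALSE)

  cov_class <- function(cl) {
    idx <- which(es$labels == cl)
    acc <- 0
    for (i in idx) {
      x <- es$epochs[i, , ]
      x <- x - rowMeans(x)
      C <- tcrossprod(x) / ncol(x)
      acc <- acc + C / sum(diag(C))
    }
    acc / length(idx)
  }
  C_L <- cov_class("left")
  C_R <- cov_class("right")
  Cc <- C_L + C_R
  p <- nrow(Cc)

  ec <- eigen(Cc, symmetric = TRUE)
  tol <- reg * sum(diag(Cc)) / p
  if (min(ec$values) < tol) {
    Cc <- Cc + diag(tol, p)
    ec <- eigen(Cc, symmetric = TRUE)
    if (min(ec$values) <= 0)
      stop("composite covariance is rank deficient; increase `reg` ",
           "(diagonal loading)", call. = FALSE)
  }
  # whiten, rotate
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  S <- P %*% C_L %*% t(P)
  er <- eigen((S + t(S)) / 2, symmetric = TRUE)
  W <- t(er$vectors) %*% P                      # rows = filters, sorted by lambda desc
  lambda <- pmin(pmax(er$values, 0), 1)

  half <- n_filters / 2
  selected_idx <- c(seq_len(half), p - rev(seq_len(half)) + 1L)
  filters <- W[selected_idx, , drop = FALSE]
  # sign convention
  for (i in seq_len(nrow(filters))) {
    j <- which.max(abs(filters[i, ]))
    if (filters[i, j] < 0) filters[i, ] <- -filters[i, ]
  }
  patterns <- tryCatch(t(solve(W))[, selected_idx, drop = FALSE],
                       error = function(e) NULL)
  structure(list(filters = filters, patterns = patterns,
                 eigenvalues = lambda, selected_idx = selected_idx,
                 band = es$band,
                 n_train_trials = table(es$labels),
                 channel_names = es$channel_names),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d filters over %d channels; extreme eigenvalues %s\n",
              nrow(x$filters), ncol(x$filters),
              paste(sprintf("%.3f", x$eigenvalues[x$selected_idx]),
                    collapse = ", ")))
  invisible(x)
}

#' Apply a CSP model to epochs
#'
#' Projects every epoch through the spatial filters, yielding virtual
#' channels (default 4) with unchanged sample count.
#'
#' @param model A `csp_model`.
#' @param es An `epoch_set` whose channels match the model.
#' @return An `epoch_set` with `n_filters` virtual channels named
#'   `CSP1..CSPn`.
#' @export
apply_csp <- function(model, es) {
  if (dim(es$epochs)[2] != ncol(model$filters) ||
      !identical(es$channel_names, model$channel_names))
    stop("channel mismatch: model expects {",
         paste(model$channel_names, collapse = ", "), "}, epochs have {",
         paste(es$channel_names, collapse = ", "), "}", call. = FALSE)
  d <- dim(es$epochs)
  k <- nrow(model$filters)
  out <- array(0, dim = c(d[1], k, d[3]))
  for (i in seq_len(d[1]))
    out[i, , ] <- model$filters %*% es$epochs[i, , ]
  es$epochs <- out
  es$channel_names <- paste0("CSP", seq_len(k))
  es
}

#' Serialize a CSP model to JSON
#'
#' @param model A `csp_model`.
#' @param path Output JSON path.
#' @return `write_csp`: `path` invisibly; `read_csp`: a `csp_model`.
#' @export
write_csp <- function(model, path) {
  obj <- list(filters = model$filters, eigenvalues = model$eigenvalues,
              selected_idx = model$selected_idx, band = model$band,
              n_train_trials = as.list(model$n_train_trials),
              channel_names = model$channel_names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_csp
#' @export
read_csp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(filters = obj$filters, patterns = NULL,
                 eigenvalues = obj$eigenvalues,
                 selected_idx = as.integer(obj$selected_idx),
                 band = obj$band, n_train_trials = obj$n_train_trials,
                 channel_names = obj$channel_names),
            class = "csp_model")
}
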