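#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] with explicit domain
#' checks (3 <= n <= 5000, non-degenerate sample), returning the
#' statistic and p-value as a named list.
#'
#' @param x Numeric sample.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("sample has zero variance; normality test undefined", call. = FALSE)
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples via
#' [stats::wilcox.test()]. The exact null distribution is used for
#' small problems (`n_x * n_y <= exact_limit`, no ties); otherwise the
#' normal approximation with tie correction. `U` is the number of
#' (x, y) pairs with `x > y`, so `U` is in `[0, n_x * n_y]`.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative As in [stats::wilcox.test()].
#' @param exact_limit Switch point between exact and asymptotic p.
#' @return List with `U`, `p` and `method`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided",
                           exact_limit = 400) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  exact <- length(x) * length(y) <= exact_limit &&
    !any(duplicated(c(x, y)))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = !exact))
  list(U = unname(ht$statistic), p = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Pooled-variance two-sample t test
#'
#' @param x,y Numeric samples with at least 2 observations in total per
#'   the positive-df requirement.
#' @return List with `t`, `df` and `p`.
#' @export
t_test_ind <- function(x, y) {
  if (length(x) + length(y) < 3 || length(x) < 1 || length(y) < 1 ||
      (length(x) == 1 && length(y) == 1))
    stop("pooled t test needs n_x + n_y - 2 >= 1 degrees of freedom",
         call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Pearson correlation test
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho` and `p`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired vectors of equal length >= 3", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson")
  list(rho = unname(ht$estimate), p = ht$p.value)
}

# Orthonormal contrast basis over k conditions (k-1 columns
# orthogonal to the unit vector), via QR.
contrast_basis <- function(k) {
  qr.Q(qr(cbind(rep(1, k), diag(k))))[, 2:k, drop = FALSE]
}

#' Mauchly's test of sphericity
#'
#' Tests whether the covariance of the within-subject differences is
#' proportional to identity. With `k = 2` conditions sphericity holds
#' trivially (`p = 1`). The chi-square approximation uses the standard
#' Box correction factor; `df = k(k-1)/2 - 1`.
#'
#' @param data Numeric matrix, subjects x k conditions (complete
#'   cases).
#' @return List with `chi2`, `df`, `p` and `W`.
#' @export
mauchly <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (k < 2) stop("need at least 2 conditions", call. = FALSE)
  if (n <= k - 1)
    stop("need more subjects (", n, ") than k - 1 = ", k - 1, call. = FALSE)
  if (k == 2)
    return(list(chi2 = 0, df = 0L, p = 1, W = 1))
  C <- contrast_basis(k)
  S <- stats::cov(data %*% C)              # (k-1) x (k-1)
  p_ <- k - 1
  if (sum(diag(S)) < 1e-12 * max(1, mean(abs(data))))  # no within-subject variance
    return(list(chi2 = 0, df = as.integer(k * (k - 1) / 2 - 1), p = 1, W = 1))
  W <- det(S) / (sum(diag(S)) / p_)^p_
  # Box chi-square series (first- plus second-order term, as in the
  # standard multivariate-model machinery)
  n1 <- n - 1
  rho <- 1 - (2 * p_^2 + p_ + 2) / (6 * p_ * n1)
  chi2 <- -n1 * rho * log(W)
  df <- as.integer(p_ * (p_ + 1) / 2 - 1)
  w2 <- (p_ + 2) * (p_ - 1) * (p_ - 2) * (2 * p_^3 + 6 * p_^2 + 3 * k + 2) /
    (288 * (n1 * p_ * rho)^2)
  pr1 <- stats::pchisq(chi2, df, lower.tail = FALSE)
  pr2 <- stats::pchisq(chi2, df + 4, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = pr1 + w2 * (pr2 - pr1), W = W)
}

# Greenhouse-Geisser epsilon from the double-centered condition
# covariance.
gg_epsilon <- function(S) {
  k <- nrow(S)
  D <- diag(k) - matrix(1 / k, k, k)
  Sd <- D %*% S %*% D
  sum(diag(Sd))^2 / ((k - 1) * sum(Sd^2))
}

#' One-way repeated-measures ANOVA with sphericity corrections
#'
#' Within-subject decomposition `SS_total = SS_subjects + SS_condition
#' + SS_error`, `F = MS_condition / MS_error` on `(k-1, (n-1)(k-1))`
#' degrees of freedom, with corrected p-values from the
#' Greenhouse-Geisser and Huynh-Feldt epsilons and the lower bound
#' `1/(k-1)` applied to both df. The Huynh-Feldt epsilon follows the
#' classical 1976 definition `(n(k-1)e_GG - 2) / ((k-1)(n-1-(k-1)e_GG))`,
#' capped at 1. Subjects with any missing condition are dropped
#' (listwise deletion) with a message.
#'
#' @param data Numeric matrix or data frame, subjects x k conditions.
#' @return An object of class `rm_anova`: sums of squares, df, mean
#'   squares, `F`, `p`, `p_GG`, `p_HF`, `p_LB`, `epsilon_GG`,
#'   `epsilon_HF`, `epsilon_LB`, `n`, `k`, and the Mauchly test
#'   (`mauchly_chi2`, `mauchly_df`, `mauchly_p`).
#' @export
rm_anova <- function(data) {
  data <- as.matrix(data)
  complete <- stats::complete.cases(data)
  if (!all(complete)) {
    message("rm_anova: dropping ", sum(!complete),
            " subject(s) with missing runs: ",
            paste(which(!complete), collapse = ", "))
    data <- data[complete, , drop = FALSE]
  }
  n <- nrow(data); k <- ncol(data)
  if (k < 2 || n < 2)
    stop("need >= 2 subjects and >= 2 conditions (got ", n, " x ", k, ")",
         call. = FALSE)

  grand <- mean(data)
  subj_means <- rowMeans(data)
  cond_means <- colMeans(data)
  SS_subjects <- k * sum((subj_means - grand)^2)
  SS_condition <- n * sum((cond_means - grand)^2)
  SS_total <- sum((data - grand)^2)
  SS_error <- SS_total - SS_subjects - SS_condition

  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  MS_condition <- SS_condition / df1
  MS_error <- SS_error / df2
  Fv <- if (MS_condition == 0) 0 else MS_condition / MS_error

  e_GG <- if (k == 2) 1 else gg_epsilon(stats::cov(data))
  e_LB <- 1 / (k - 1)
  if (!is.finite(e_GG)) e_GG <- 1       # degenerate (zero) condition covariance
  e_GG <- min(max(e_GG, e_LB), 1)
  e_HF <- min((n * df1 * e_GG - 2) / (df1 * (n - 1 - df1 * e_GG)), 1)
  e_HF <- max(e_HF, e_GG)

  p_at <- function(eps) stats::pf(Fv, eps * df1, eps * df2,
                                  lower.tail = FALSE)
  mau <- mauchly(data)
  structure(list(SS_condition = SS_condition, SS_error = SS_error,
                 SS_subjects = SS_subjects,
                 df_condition = df1, df_error = df2,
                 MS_condition = MS_condition, MS_error = MS_error,
                 F = Fv, p = p_at(1),
                 p_GG = p_at(e_GG), p_HF = p_at(e_HF), p_LB = p_at(e_LB),
                 epsilon_GG = e_GG, epsilon_HF = e_HF, epsilon_LB = e_LB,
                 n = n, k = k,
                 mauchly_chi2 = mau$chi2, mauchly_df = mau$df,
                 mauchly_p = mau$p),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (n = %d subjects, k = %d conditions)\n",
              x$n, x$k))
  cat(sprintf("  condition: SS = %.3f, df = %d, MS = %.3f\n",
              x$SS_condition, x$df_condition, x$MS_condition))
  cat(sprintf("  error:     SS = %.3f, df = %d, MS = %.3f\n",
              x$SS_error, x$df_error, x$MS_error))
  cat(sprintf("  F = %.4f, p = %.4g (GG %.4g, HF %.4g, LB %.4g)\n",
              x$F, x$p, x$p_GG, x$p_HF, x$p_LB))
  cat(sprintf("  epsilon: GG %.3f, HF %.3f, LB %.3f; Mauchly chi2(%d) = %.3f, p = %.4g\n",
              x$epsilon_GG, x$epsilon_HF, x$epsilon_LB,
              x$mauchly_df, x$mauchly_chi2, x$mauchly_p))
  invisible(x)
}

#' Long-format helper for the repeated-measures comparison
#'
#' Pivots a long (subject, condition, value) data frame into the
#' subjects x conditions matrix [rm_anova()] expects.
#'
#' @param df Data frame with columns `subject`, `condition`, `value`.
#' @return Numeric matrix with one row per subject, one column per
#'   condition (in first-appearance order); missing cells are `NA`.
#' @export
long_to_cells <- function(df) {
  stopifnot(all(c("subject", "condition", "value") %in% names(df)))
  subs <- unique(df$subject)
  conds <- unique(df$condition)
  out <- matrix(NA_real_, length(subs), length(conds),
                dimnames = list(NULL, conds))
  for (i in seq_len(nrow(df)))
    out[match(df$subject[i], subs), match(df$condition[i], conds)] <-
      df$value[i]
  out
}
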