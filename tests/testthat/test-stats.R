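test_that("Shapiro-Wilk gate behaves on normal, bimodal and degenerate input", {
  x <- qnorm(ppoints(20))
  expect_gt(shapiro_wilk(x)$W, 0.99)
  bimodal <- c(rnorm(15, -4, 0.3), rnorm(15, 4, 0.3))
  expect_lt(shapiro_wilk(bimodal)$p, 0.05)
  expect_error(shapiro_wilk(rep(2, 10)), "variance")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("Mann-Whitney U matches exhaustive enumeration on small samples", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)   # 2 of 6 arrangements as extreme
  expect_equal(r$method, "exact")

  # enumeration oracle for a 3 vs 3 fixture: U over all C(6,3) splits
  x <- c(1.2, 3.4, 5.1); y <- c(2.0, 6.3, 7.7)
  pool <- c(x, y)
  u_stat <- function(a, b) sum(outer(a, b, `>`))
  u_obs <- u_stat(x, y)
  us <- apply(combn(6, 3), 2, function(ix) u_stat(pool[ix], pool[-ix]))
  mu <- length(x) * length(y) / 2
  p_exact <- mean(abs(us - mu) >= abs(u_obs - mu))
  r2 <- mann_whitney_u(x, y)
  expect_equal(r2$U, u_obs)
  expect_equal(r2$p, p_exact, tolerance = 1e-10)
})

test_that("Mann-Whitney handles identity and degenerate input", {
  x <- c(1, 2, 3, 4)
  r <- mann_whitney_u(x, x)
  expect_equal(r$U, length(x)^2 / 2)
  expect_equal(r$p, 1)
  expect_error(mann_whitney_u(numeric(0), x), "non-empty")
})

test_that("pooled t test matches its closed form", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  r <- t_test_ind(x, y)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  x <- c(84, 86, 88, 90, 92); y <- c(81, 84, 85, 86)  # hand-computed fixture
  sp2 <- (4 * var(x) + 3 * var(y)) / 7
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 4))
  r2 <- t_test_ind(x, y)
  expect_equal(r2$t, t_hand, tolerance = 1e-12)
  expect_equal(r2$df, 7)
  expect_equal(r2$p, 2 * pt(-abs(t_hand), 7), tolerance = 1e-12)
  expect_error(t_test_ind(1, 2), "degrees of freedom")
})

test_that("Pearson correlation hits the exact linear limits and a uniform null", {
  x <- 1:14
  expect_equal(pearson_cor(x, 2 * x + 1)$rho, 1, tolerance = 1e-12)
  expect_equal(pearson_cor(x, -x)$rho, -1, tolerance = 1e-12)
  set.seed(41)
  ps <- replicate(1000, pearson_cor(rnorm(14), rnorm(14))$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Mauchly matches the multivariate-model oracle and the k = 2 triviality", {
  set.seed(42)
  Y <- matrix(rnorm(14 * 4, 70, 8), 14, 4) %*% diag(c(1, 1.3, 0.8, 1.7))
  m <- mauchly(Y)
  fit <- lm(Y ~ 1)
  ref <- stats::mauchly.test(fit, X = ~1)
  expect_equal(m$W, unname(ref$statistic), tolerance = 1e-6)
  expect_equal(m$p, ref$p.value, tolerance = 1e-6)
  expect_equal(m$df, 4 * 3 / 2 - 1)

  expect_equal(mauchly(Y[, 1:2])$p, 1)
  expect_error(mauchly(Y[1:2, ]), "subjects")
})

test_that("Mauchly rejection is near nominal under compound symmetry", {
  set.seed(43)
  rej <- mean(replicate(500, {
    Y <- matrix(rnorm(36), 12, 3) + rnorm(12)
    mauchly(Y)$p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("repeated-measures ANOVA matches a hand-computed SS oracle", {
  D <- matrix(c(30, 28, 16, 34,
                14, 18, 10, 22,
                24, 20, 18, 30,
                38, 34, 20, 44), 4, 4, byrow = TRUE)
  r <- rm_anova(D)
  # brute-force sums of squares
  grand <- mean(D)
  ss_cond <- 4 * sum((colMeans(D) - grand)^2)
  ss_subj <- 4 * sum((rowMeans(D) - grand)^2)
  ss_err <- sum((D - outer(rowMeans(D), colMeans(D), `+`) + grand)^2)
  expect_equal(r$SS_condition, ss_cond, tolerance = 1e-8)
  expect_equal(r$SS_subjects, ss_subj, tolerance = 1e-8)
  expect_equal(r$SS_error, ss_err, tolerance = 1e-8)
  expect_equal(r$F, (ss_cond / 3) / (ss_err / 9), tolerance = 1e-8)
  expect_equal(r$df_condition, 3)
  expect_equal(r$df_error, 9)
})

test_that("rm_anova on two conditions reproduces the paired t test", {
  set.seed(44)
  Y <- matrix(rnorm(24, 75, 9), 12, 2)
  r <- rm_anova(Y)
  tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
  expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(r$p, tt$p.value, tolerance = 1e-8)
  expect_equal(r$p_GG, r$p)                 # k = 2: all epsilons are 1
  expect_equal(r$p_LB, r$p)
})

test_that("degenerate and invalid inputs are handled explicitly", {
  subj <- c(10, 20, 30, 40)
  D <- cbind(subj, subj, subj)              # no within-subject variation
  r <- rm_anova(D)
  expect_equal(r$SS_condition, 0)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  expect_error(rm_anova(matrix(1:3, 1, 3)), "subjects")
  expect_error(rm_anova(matrix(1:3, 3, 1)), "conditions")

  M <- matrix(rnorm(15), 5, 3)
  M[2, 3] <- NA
  expect_message(r2 <- rm_anova(M), "dropping 1")
  expect_equal(r2$n, 4)
})

test_that("epsilons are ordered and p-values location-invariant", {
  set.seed(45)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    Y <- matrix(rnorm(12 * k, 70, 5), 12, k) %*%
      diag(runif(k, 0.5, 2))
    r <- rm_anova(Y)
    expect_true(r$epsilon_LB <= r$epsilon_GG + 1e-12)
    expect_true(r$epsilon_GG <= r$epsilon_HF + 1e-12)
    expect_true(r$epsilon_HF <= 1 + 1e-12)
    expect_equal(r$epsilon_LB, 1 / (k - 1))
    # corrected p ordering holds whenever the effect is non-trivial
    if (r$F >= 1) {
      expect_true(r$p_LB >= r$p_GG - 1e-12)
      expect_true(r$p_GG >= r$p - 1e-12)
    }
    r_shift <- rm_anova(Y + 13.7)
    expect_equal(r_shift$F, r$F, tolerance = 1e-10)
    expect_equal(r_shift$p_GG, r$p_GG, tolerance = 1e-10)
  }
})

test_that("long-format input pivots into the subjects x conditions matrix", {
  df <- data.frame(subject = rep(1:3, each = 2),
                   condition = rep(c("a", "b"), 3),
                   value = c(1, 2, 3, 4, 5, 6))
  M <- long_to_cells(df)
  expect_equal(dim(M), c(3, 2))
  expect_equal(M[, "a"], c(1, 3, 5))
  expect_equal(M[, "b"], c(2, 4, 6))
})
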