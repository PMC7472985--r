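test_that("timepoint grid enumerates the feature instants", {
  g <- timepoint_grid()
  expect_length(g, 14)
  expect_equal(g, seq(1.5, 8, by = 0.5))
  expect_equal(timepoint_grid(epoch_len = 8, start = 8), 8)
  expect_equal(timepoint_grid(epoch_len = 8, start = 1.5, step = 1),
               c(1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5))
  expect_error(timepoint_grid(epoch_len = 8, start = 9), "exceeds")
  expect_error(timepoint_grid(step = 0), "step")
})

test_that("equal-variance channels yield ln(1/4) features", {
  x <- sin(2 * pi * 10 * (0:511) / 64)
  ep <- array(rep(x, each = 4), dim = c(1, 4, 512))
  fb <- extract_features(make_epochs(ep, "left"), grid = c(2, 4, 8))
  expect_equal(as.vector(fb$values), rep(log(0.25), 12), tolerance = 1e-12)
})

test_that("a single dominant channel saturates the normalized features", {
  ep <- array(0, dim = c(1, 4, 512))
  ep[1, 2, ] <- rnorm(512)
  fb <- extract_features(make_epochs(ep, "left"), grid = c(8))
  expect_gt(fb$values[1, 1, 2], log(0.999))   # dominant feature ~ 0
  expect_true(all(fb$values[1, 1, -2] < log(1e-6)))
})

test_that("features match a brute-force variance oracle and normalize", {
  set.seed(21)
  ep <- array(rnorm(6 * 4 * 512), dim = c(6, 4, 512))
  es <- make_epochs(ep, rep(c("left", "right"), 3))
  grid <- timepoint_grid()
  fb <- extract_features(es, grid)
  fs <- 64
  for (i in c(1, 4)) for (j in c(1, 7, 14)) {
    t1 <- max(1, round((grid[j] - 1.5) * fs) + 1)
    t2 <- round(grid[j] * fs)
    v <- sapply(1:4, function(ch) {
      z <- ep[i, ch, t1:t2]
      sum((z - mean(z))^2) / (length(z) - 1)   # two-pass variance
    })
    expect_equal(fb$values[i, j, ], log(v / sum(v)), tolerance = 1e-10)
  }
  sums <- apply(exp(fb$values), c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("LDA matches the closed form and MASS::lda decisions", {
  set.seed(22)
  n <- 60
  X <- rbind(matrix(rnorm(n * 4, -1, 1), n, 4),
             matrix(rnorm(n * 4, 1, 1), n, 4))
  y <- rep(c("left", "right"), each = n)
  m <- mibci:::lda_fit(X, y)
  # closed-form oracle with explicit inverse
  mu_L <- colMeans(X[1:n, ]); mu_R <- colMeans(X[-(1:n), ])
  S <- (cov(X[1:n, ]) * (n - 1) + cov(X[-(1:n), ]) * (n - 1)) / (2 * n - 2)
  w <- solve(S + diag(1e-9 * mean(diag(S)), 4)) %*% (mu_R - mu_L)
  expect_equal(unname(m$weights), as.vector(w), tolerance = 1e-8)
  expect_equal(m$bias, -sum(w * (mu_L + mu_R) / 2), tolerance = 1e-8)

  skip_if_not_installed("MASS")
  ref <- MASS::lda(X, grouping = factor(y), prior = c(0.5, 0.5))
  expect_equal(as.character(predict(m, X)),
               as.character(predict(ref, X)$class))
})

test_that("well-separated clouds are classified perfectly; label swap flips weights", {
  set.seed(23)
  X <- rbind(matrix(rnorm(40, -5), 10, 4), matrix(rnorm(40, 5), 10, 4))
  y <- rep(c("left", "right"), each = 10)
  m <- mibci:::lda_fit(X, y)
  expect_equal(as.character(predict(m, X)), y)
  m_sw <- mibci:::lda_fit(X, rev(y))
  expect_equal(m_sw$weights, -m$weights, tolerance = 1e-10)
  expect_error(mibci:::lda_fit(X, rep("left", 20)), "both classes")
})

test_that("train_lda pools every (trial, timepoint) sample", {
  set.seed(24)
  vals <- array(rnorm(8 * 3 * 4), dim = c(8, 3, 4))
  fb <- make_features(vals, rep(c("left", "right"), 4))
  m <- train_lda(fb)
  X <- do.call(rbind, lapply(1:8, function(i) vals[i, , ]))
  y <- rep(rep(c("left", "right"), 4), each = 3)
  expect_equal(m$weights, mibci:::lda_fit(X, y)$weights, tolerance = 1e-12)
  expect_equal(m$training_scope, "pooled-timepoints")
  expect_equal(train_lda(fb, timepoint = 2)$training_scope, "timepoint-2")
})

test_that("cross-validation is a trial-level partition and nails separable data", {
  set.seed(25)
  vals <- array(rnorm(40 * 5 * 4), dim = c(40, 5, 4))
  labels <- rep(c("left", "right"), 20)
  vals[labels == "right", , 1] <- vals[labels == "right", , 1] + 12
  fb <- make_features(vals, labels)
  res <- crossval_accuracy(fb, k = 10, seed = 3)
  expect_true(all(res$acc == 100))
  expect_equal(unname(res$summary_max), c(100, 100))
  expect_equal(unname(res$summary_mean), c(100, 100))

  fold <- mibci:::stratified_folds(factor(labels), 10, seed = 3)
  expect_equal(sort(unique(fold)), 1:10)
  expect_true(all(table(fold) == 4))            # partition, stratified
  expect_true(all(table(fold, labels) == 2))

  expect_error(crossval_accuracy(fb, k = 100), "class size")
})

test_that("permuted labels give chance-level accuracy", {
  set.seed(26)
  vals <- array(rnorm(80 * 5 * 4), dim = c(80, 5, 4))
  means <- sapply(1:20, function(s) {
    labels <- sample(rep(c("left", "right"), 40))
    fb <- make_features(vals, labels)
    mean(crossval_accuracy(fb, k = 10, seed = s)$summary_mean)
  })
  half <- 1.96 * sqrt(50 * 50 / (20 * 80))
  expect_gt(mean(means), 50 - half)
  expect_lt(mean(means), 50 + half)
})

test_that("accuracy curves are invariant to common affine feature rescaling", {
  set.seed(27)
  vals <- array(rnorm(30 * 4 * 4), dim = c(30, 4, 4))
  labels <- rep(c("left", "right"), 15)
  vals[labels == "right", , 2] <- vals[labels == "right", , 2] + 1
  fb1 <- make_features(vals, labels)
  fb2 <- make_features(2.5 * vals - 7, labels)
  r1 <- crossval_accuracy(fb1, k = 5, seed = 9)
  r2 <- crossval_accuracy(fb2, k = 5, seed = 9)
  expect_equal(r1$acc, r2$acc)
})

test_that("accuracy summaries follow max/mean arithmetic", {
  res <- structure(list(acc = matrix(c(73, 73), 2, 3,
                                     dimnames = list(c("left", "right"),
                                                     NULL)),
                        timepoints = 1:3), class = "accuracy_result")
  expect_equal(unname(summarize_accuracy(res, "max")), c(73, 73))
  expect_equal(unname(summarize_accuracy(res, "mean")), c(73, 73))
  res$acc <- matrix(c(50, 55, 60, 65, 100, 90), 2, 3,
                    dimnames = list(c("left", "right"), NULL))
  expect_equal(unname(summarize_accuracy(res, "max")), c(100, 90))
  expect_equal(unname(summarize_accuracy(res, "mean")), c(70, 70))
  expect_true(all(summarize_accuracy(res, "max") >=
                    summarize_accuracy(res, "mean")))
  expect_error(summarize_accuracy(res, "median"))
})
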