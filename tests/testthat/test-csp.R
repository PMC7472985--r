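# Independent generalized-eigen oracle: class covariances from the
# same trace-normalized estimator, solved through the non-symmetric
# eigenproblem of solve(C_L + C_R) %*% C_L.
oracle_csp <- function(es) {
  covs <- function(cl) {
    idx <- which(es$labels == cl)
    Reduce(`+`, lapply(idx, function(i) {
      x <- es$epochs[i, , ]
      x <- x - rowMeans(x)
      C <- x %*% t(x) / ncol(x)
      C / sum(diag(C))
    })) / length(idx)
  }
  C_L <- covs("left"); C_R <- covs("right")
  e <- eigen(solve(C_L + C_R) %*% C_L)
  ord <- order(Re(e$values), decreasing = TRUE)
  list(values = Re(e$values)[ord],
       vectors = Re(e$vectors)[, ord, drop = FALSE],
       C_L = C_L, C_R = C_R)
}

test_that("2-channel toy recovers axis-aligned filters and 0.8/0.2 ratios", {
  es <- scaled_noise_epochs(30, sd_left = c(2, 1), sd_right = c(1, 2),
                            seed = 10)
  m <- fit_csp(es, n_filters = 2)
  expect_equal(m$eigenvalues[1], 0.8, tolerance = 0.05)
  expect_equal(m$eigenvalues[2], 0.2, tolerance = 0.05)
  # filters align with the coordinate axes
  for (i in 1:2) {
    w <- m$filters[i, ] / sqrt(sum(m$filters[i, ]^2))
    expect_gt(max(abs(w)), 0.99)
  }
})

test_that("stored eigenvalues satisfy the variance-ratio identity", {
  es <- scaled_noise_epochs(20, sd_left = c(3, 1, 1, 2),
                            sd_right = c(1, 2, 3, 1), seed = 11)
  m <- fit_csp(es, n_filters = 4)
  orc <- oracle_csp(es)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_true(all(m$eigenvalues >= 0 & m$eigenvalues <= 1))
  expect_equal(m$selected_idx, c(1L, 2L, 3L, 4L))
  for (i in seq_len(4)) {
    w <- m$filters[i, ]
    lam <- (w %*% orc$C_L %*% w) / (w %*% (orc$C_L + orc$C_R) %*% w)
    expect_equal(as.numeric(lam), m$eigenvalues[m$selected_idx[i]],
                 tolerance = 1e-8)
  }
})

test_that("filters jointly diagonalize both class covariances", {
  es <- scaled_noise_epochs(20, sd_left = c(3, 1, 1, 2),
                            sd_right = c(1, 2, 3, 1), seed = 12)
  m <- fit_csp(es, n_filters = 4)
  orc <- oracle_csp(es)
  for (C in list(orc$C_L, orc$C_R)) {
    M <- m$filters %*% C %*% t(m$filters)
    off <- max(abs(M[upper.tri(M)]))
    expect_lt(off, 1e-6 * max(abs(diag(M))))
  }
})

test_that("filters match the brute-force generalized-eigen oracle on toys", {
  for (seed in c(13, 14)) {
    es <- scaled_noise_epochs(25, sd_left = c(2.5, 1, 1.5),
                              sd_right = c(1, 2, 1.2), seed = seed)
    m <- fit_csp(es, n_filters = 2)
    orc <- oracle_csp(es)
    expect_equal(m$eigenvalues, orc$values, tolerance = 1e-6)
    # selected filters match oracle eigenvectors up to sign/scale;
    # oracle vectors are right eigenvectors of the same pencil
    sel <- c(1, 3)
    for (i in 1:2) {
      w <- m$filters[i, ]
      v <- orc$vectors[, sel[i]]
      cosang <- abs(sum(w * v)) / sqrt(sum(w^2) * sum(v^2))
      expect_gt(cosang, 1 - 1e-6)
    }
  }
})

test_that("class swap mirrors the eigenvalue spectrum", {
  es <- scaled_noise_epochs(20, sd_left = c(3, 1, 1, 2),
                            sd_right = c(1, 2, 3, 1), seed = 15)
  m <- fit_csp(es, n_filters = 4)
  es_sw <- es
  es_sw$labels <- factor(ifelse(es$labels == "left", "right", "left"),
                         levels = c("left", "right"))
  m_sw <- fit_csp(es_sw, n_filters = 4)
  expect_equal(m_sw$eigenvalues, rev(1 - m$eigenvalues), tolerance = 1e-8)
  # same filter subspace, selection order reversed
  expect_equal(m_sw$filters[c(3, 4, 1, 2), ], m$filters[c(2, 1, 4, 3), ],
               tolerance = 1e-6)
})

test_that("filters are invariant to a global amplitude rescaling", {
  es <- scaled_noise_epochs(20, sd_left = c(2, 1, 1.4),
                            sd_right = c(1, 1.8, 1), seed = 16)
  m1 <- fit_csp(es, n_filters = 2)
  es$epochs <- es$epochs * 7.3
  m2 <- fit_csp(es, n_filters = 2)
  expect_equal(m1$filters, m2$filters, tolerance = 1e-8)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-10)
})

test_that("identical class processes give near-0.5 eigenvalues", {
  run <- simulate_run(quick_cfg(seed = 17, erd_depth = 0))
  es <- narrowband_filter(epoch_run(run))
  m <- fit_csp(es)
  expect_true(all(abs(m$eigenvalues - 0.5) < 0.15))
})

test_that("apply_csp projects epochs and validates channel identity", {
  es <- scaled_noise_epochs(5, sd_left = c(1, 1, 1, 1),
                            sd_right = c(1, 1, 1, 1), seed = 18)
  ident <- structure(list(filters = diag(4)[c(2, 4, 1, 3), ],
                          eigenvalues = rep(0.5, 4),
                          selected_idx = 1:4, band = c(8, 30),
                          n_train_trials = c(left = 5, right = 5),
                          channel_names = es$channel_names),
                     class = "csp_model")
  out <- apply_csp(ident, es)
  expect_equal(dim(out$epochs), c(10, 4, 512))
  expect_equal(out$epochs[3, 1, ], es$epochs[3, 2, ])
  expect_equal(out$epochs[7, 4, ], es$epochs[7, 3, ])

  zero <- es; zero$epochs[] <- 0
  expect_true(all(apply_csp(ident, zero)$epochs == 0))

  bad <- es; bad$channel_names <- paste0("X", 1:4)
  expect_error(apply_csp(ident, bad), "mismatch")
})

test_that("CSP models round-trip through JSON", {
  es <- scaled_noise_epochs(10, sd_left = c(2, 1, 1, 1.5),
                            sd_right = c(1, 1.5, 2, 1), seed = 19)
  m <- fit_csp(es, n_filters = 4)
  path <- file.path(tempdir(), "csp.json")
  write_csp(m, path)
  back <- read_csp(path)
  expect_equal(back$filters, unname(m$filters), tolerance = 1e-12)
  expect_equal(back$eigenvalues, m$eigenvalues, tolerance = 1e-12)
  expect_equal(back$selected_idx, m$selected_idx)
  unlink(path)
})
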