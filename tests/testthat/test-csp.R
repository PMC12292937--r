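random_spd <- function(n) {
  m <- matrix(rnorm(n * n), n)
  crossprod(m) / n + diag(0.1, n)
}

test_that("class covariance is the Ramoser-normalised average and is symmetric", {
  ts <- fixture_var_trialset(rbind(c(1, 1), c(1, 1)),
                             trials_per_class = 200, n_samples = 200)
  cv <- class_covariance(ts, 1)
  expect_lt(max(abs(cv - diag(0.5, 2))), 0.05)   # white noise -> I/2
  expect_lt(max(abs(cv - t(cv))), 1e-12)

  one <- subset_trials(ts, 1)
  X <- trial_matrix(one, 1)
  expect_equal(class_covariance(one, one$labels),
               tcrossprod(X) / sum(diag(tcrossprod(X))),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(class_covariance(ts, 99), "no trials")
})

test_that("fit matches a brute-force generalised eigendecomposition", {
  withr::with_seed(20, {
    for (rep in 1:25) {
      covA <- random_spd(4); covB <- random_spd(4)
      m <- mi3deeg:::csp_from_covs(covA, covB)
      oracle <- eigen(solve(covA + covB) %*% covA)
      ord <- order(Re(oracle$values), decreasing = TRUE)
      expect_lt(max(abs(m$eigenvalues - Re(oracle$values)[ord])), 1e-8)
      for (i in 1:4) {
        v <- Re(oracle$vectors[, ord[i]])
        w <- m$P[i, ]
        cosang <- abs(sum(v * w)) / sqrt(sum(v^2) * sum(w^2))
        expect_gt(cosang, 1 - 1e-8)
      }
    }
  })
})

test_that("whitened eigenvalues pair to one and P is C x C", {
  ts <- fixture_var_trialset(rbind(c(4, 1, 2, 1), c(1, 3, 1, 2)),
                             trials_per_class = 30)
  m <- csp(ts, 1, 2)
  expect_identical(dim(m$P), c(4L, 4L))
  lamA <- diag(m$P %*% m$covA %*% t(m$P))
  lamB <- diag(m$P %*% m$covB %*% t(m$P))
  expect_lt(max(abs(lamA + lamB - 1)), 1e-8)
  expect_lt(max(abs(lamA - m$eigenvalues)), 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))   # sorted descending

  ts22 <- fixture_var_trialset(matrix(1, 2, 22), trials_per_class = 10)
  expect_identical(dim(csp(ts22, 1, 2)$P), c(22L, 22L))
})

test_that("identical class generators give eigenvalues near one half", {
  ts <- fixture_var_trialset(rbind(rep(1, 3), rep(1, 3)),
                             trials_per_class = 200, n_samples = 200)
  m <- csp(ts, 1, 2)
  expect_lt(max(abs(m$eigenvalues - 0.5)), 0.05)
})

test_that("planted diag(4,1) vs diag(1,4) covariances are recovered", {
  ts <- fixture_var_trialset(rbind(c(4, 1), c(1, 4)),
                             trials_per_class = 200, n_samples = 200,
                             seed = 8)
  m <- csp(ts, 1, 2)
  expect_lt(abs(m$eigenvalues[1] - 0.8), 0.05)
  expect_lt(abs(m$eigenvalues[2] - 0.2), 0.05)
  w <- m$P[1, ] / sqrt(sum(m$P[1, ]^2))
  expect_gt(abs(w[1]), 0.99)   # first filter aligned with channel 1
})

test_that("row reduction keeps the top and bottom n rows and composes", {
  ts22 <- fixture_var_trialset(matrix(c(seq(4, 1, length.out = 22),
                                        seq(1, 4, length.out = 22)),
                                      2, byrow = TRUE),
                               trials_per_class = 15)
  m <- csp(ts22, 1, 2)
  r <- reduce_rows(m, 4)
  expect_identical(nrow(r$P), 8L)
  expect_identical(r$P, m$P[c(1:4, 19:22), ])
  expect_identical(reduce_rows(m, 11)$P, m$P)    # n = C/2 keeps all rows
  expect_identical(reduce_rows(reduce_rows(m, 4), 2)$P,
                   reduce_rows(m, 2)$P)
  expect_error(reduce_rows(m, 12), "exceeds")
})

test_that("log-variance features are normalised, gain-invariant and sized 2n", {
  ts22 <- fixture_var_trialset(matrix(1, 2, 22), trials_per_class = 5)
  m <- csp(ts22, 1, 2)
  X <- trial_matrix(ts22, 1)
  f <- csp_features(m, X, n_pairs = 4)
  expect_length(f, 8L)
  expect_equal(sum(exp(f)), 1, tolerance = 1e-10)
  expect_equal(csp_features(m, 10 * X, n_pairs = 4), f, tolerance = 1e-10)
})

test_that("weight genes select rows; degenerate genes are flagged", {
  ts <- fixture_var_trialset(rbind(c(4, 1, 1), c(1, 1, 4)),
                             trials_per_class = 10)
  m <- csp(ts, 1, 2)
  expect_identical(apply_weight(m, c(1, 1, 1))$P, m$P)
  e1 <- apply_weight(m, c(1, 0, 0))
  expect_identical(e1$P, m$P[1, , drop = FALSE])
  expect_length(csp_features(apply_weight(m, c(1, 0, 1)),
                             trial_matrix(ts, 1)), 2L)
  expect_error(apply_weight(m, c(0, 0, 0)), "all-zero")
  expect_error(apply_weight(m, c(1, 0)), "length")
})
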