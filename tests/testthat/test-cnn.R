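# small separable tensor fixture: class-specific smooth spatial means plus
# noise; T is kept short so the suite stays fast (the architecture is
# identical at full length)
separable_tensors <- function(n_per_class = 10, W = 9, T_len = 12,
                              noise = 0.5, seed = 1) {
  withr::with_seed(seed, {
    mu <- array(rnorm(4 * W * W * T_len), c(4, W, W, T_len))
    n <- 4 * n_per_class
    y <- rep(1:4, each = n_per_class)
    x <- array(0, c(n, W, W, T_len))
    for (i in seq_len(n))
      x[i, , , ] <- mu[y[i], , , ] + noise * rnorm(W * W * T_len)
  })
  list(x = x, y = y)
}

test_that("configs propagate shapes and reject impossible ones by layer name", {
  cfg <- cnn_config(9, 750)
  expect_identical(cfg$flat, 144L)          # (2, 1, 72) after layer 3
  expect_identical(cnn_config(9, 33)$flat, 144L)  # PSD-length input
  expect_error(cnn_config(0, 750), "input")
  expect_error(cnn_config(9, 750, n_classes = 1), "softmax")
})

test_that("forward pass yields unit-sum softmax rows for time and PSD lengths", {
  for (T_len in c(750L, 33L)) {
    m <- build_cnn(cnn_config(9, T_len), seed = 3)
    x <- array(stats::rnorm(2 * 9 * 9 * T_len), c(2, 9, 9, T_len))
    pr <- predict(m, x, type = "prob")
    expect_identical(dim(pr), c(2L, 4L))
    expect_lt(max(abs(rowSums(pr) - 1)), 1e-6)
    expect_true(all(pr >= 0))
  }
})

test_that("dual-branch parameter count is twice the branch plus the head", {
  md <- build_cnn(cnn_config(9, 40, dual_branch = TRUE))
  ms <- build_cnn(cnn_config(9, 40, dual_branch = FALSE))
  pd <- count_params(md, by_part = TRUE)
  expect_identical(pd$branches[1], pd$branches[2])
  expect_identical(count_params(md), 2L * pd$branches[1] + pd$head)
  # the dense layer is 256 units wide
  expect_identical(ncol(md$head[[1]]$params$W), 256L)
  expect_identical(ncol(ms$head[[1]]$params$W), 256L)
})

test_that("a tiny training set is memorised within the training budget", {
  fx <- separable_tensors(n_per_class = 2, T_len = 12, noise = 1)
  m <- cnn3deeg(fx$x, fx$y, epochs = 200, batch_size = 8, validation = 0,
                seed = 4)
  expect_identical(tail(m$traces$train_accuracy, 1), 1)
  # loss is non-increasing up to a 5-epoch tolerance window
  lo <- m$traces$train_loss
  run_min <- cummin(lo)
  lagged <- c(rep(Inf, 5), run_min[seq_len(length(lo) - 5)])
  expect_true(all(lo <= lagged + 1e-8 | lo <= run_min + 0.05))
})

test_that("training is deterministic given the seed", {
  fx <- separable_tensors(n_per_class = 2, T_len = 8)
  m1 <- cnn3deeg(fx$x, fx$y, epochs = 5, batch_size = 8, validation = 0,
                 seed = 11)
  m2 <- cnn3deeg(fx$x, fx$y, epochs = 5, batch_size = 8, validation = 0,
                 seed = 11)
  expect_identical(m1$traces, m2$traces)
  expect_identical(sum(abs(unlist(lapply(m1$head, `[[`, "params")))),
                   sum(abs(unlist(lapply(m2$head, `[[`, "params")))))
  expect_identical(unlist(lapply(m1$branches[[1]], `[[`, "params")),
                   unlist(lapply(m2$branches[[1]], `[[`, "params")))
})

test_that("a separable four-class set is decoded well above chance", {
  fx <- separable_tensors(n_per_class = 20, T_len = 12, noise = 0.7,
                          seed = 2)
  sp <- stratified_split(fx$y, 0.6, seed = 4)
  m <- cnn3deeg(fx$x[sp$train, , , , drop = FALSE], fx$y[sp$train],
                epochs = 40, batch_size = 16, validation = 0.16, seed = 5)
  met <- evaluate_cnn(m, fx$x[sp$test, , , , drop = FALSE], fx$y[sp$test])
  expect_gte(met$accuracy, 0.85)
  expect_equal(unname(rowSums(met$confusion)), rep(8, 4))
})

test_that("non-finite loss aborts with a diagnostic", {
  fx <- separable_tensors(n_per_class = 2, T_len = 8)
  fx$x[1, 1, 1, 1] <- NaN
  expect_error(cnn3deeg(fx$x, fx$y, epochs = 5, batch_size = 8,
                        validation = 0, seed = 1),
               "loss")
})

test_that("kappa matches hand-computed values and its degenerate case", {
  expect_equal(cohen_kappa(diag(5, 4)), 1)
  expect_equal(cohen_kappa(matrix(3, 4, 4)), 0)
  expect_equal(cohen_kappa(matrix(c(30, 10, 10, 30), 2)), 0.5)
  expect_warning(k <- cohen_kappa(matrix(c(7, 0, 0, 0), 2)), "degenerate")
  expect_identical(k, 0)
  expect_error(cohen_kappa(matrix(-1, 2, 2)), "non-negative")
})

test_that("metrics report perfect and chance-level predictions correctly", {
  y <- rep(1:4, each = 25)
  perfect <- classification_metrics(y, y)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)

  withr::with_seed(8, pred <- sample(1:4, 1000, replace = TRUE))
  truth <- rep(1:4, each = 250)
  met <- classification_metrics(truth, pred)
  expect_lt(abs(met$kappa), 0.05)
  expect_equal(unname(rowSums(met$confusion)), rep(250, 4))
  expect_error(classification_metrics(integer(0), integer(0)), "empty")
})
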