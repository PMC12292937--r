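rms_mid <- function(x) {
  mid <- seq(round(length(x) * 0.25), round(length(x) * 0.75))
  sqrt(mean(x[mid]^2))
}

sine_rec <- function(freq, fs = 250, dur = 20) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  recording(matrix(sin(2 * pi * freq * t), 1), fs)
}

test_that("bandpass passes in-band tones and rejects out-of-band tones", {
  r10 <- bandpass(sine_rec(10), 0.5, 40)
  r60 <- bandpass(sine_rec(60), 0.5, 40)
  expect_lt(abs(rms_mid(r10$data[1, ]) / rms_mid(sine_rec(10)$data[1, ]) - 1),
            0.05)
  atten_db <- 20 * log10(rms_mid(sine_rec(60)$data[1, ]) /
                           rms_mid(r60$data[1, ]))
  expect_gt(atten_db, 20)
  z <- bandpass(recording(matrix(0, 2, 500), 250), 0.5, 40)
  expect_true(all(z$data == 0))
  expect_error(bandpass(sine_rec(10), 40, 0.5), "invalid band")
  expect_error(bandpass(sine_rec(10), 0.5, 200), "invalid band")
})

test_that("notch rejects the mains band and leaves the rhythm band alone", {
  r50 <- notch(sine_rec(50))
  r10 <- notch(sine_rec(10))
  atten_db <- 20 * log10(rms_mid(sine_rec(50)$data[1, ]) /
                           rms_mid(r50$data[1, ]))
  expect_gt(atten_db, 20)
  expect_lt(abs(rms_mid(r10$data[1, ]) / rms_mid(sine_rec(10)$data[1, ]) - 1),
            0.05)
  z <- notch(recording(matrix(0, 1, 500), 250))
  expect_true(all(z$data == 0))
})

test_that("filtering is linear and preserves channel count and order", {
  withr::with_seed(3, {
    x <- matrix(rnorm(3 * 2000), 3)
    y <- matrix(rnorm(3 * 2000), 3)
  })
  rx <- recording(x, 250, c("A", "B", "C"))
  ry <- recording(y, 250, c("A", "B", "C"))
  rc <- recording(2 * x - 3 * y, 250, c("A", "B", "C"))
  lhs <- bandpass(rc, 0.5, 40)$data
  rhs <- 2 * bandpass(rx, 0.5, 40)$data - 3 * bandpass(ry, 0.5, 40)$data
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-8)
  expect_identical(rownames(lhs), c("A", "B", "C"))
})

test_that("epoching cuts the documented half-open window", {
  rec <- fixture_recording(4, 250 * 20, events = data.frame(
    sample = as.integer(250 * (0:4) * 3.5), code = rep(1:4, length.out = 5)))
  ts <- epoch_trials(rec, 0, 3)
  expect_identical(unname(dim_trials(ts)), c(5L, 4L, 750L))
  expect_identical(ts$labels, rec$events$code)
  # sample values are copied, not resampled
  expect_identical(ts$trials[1, , ], unname(rec$data[, 1:750]))
})

test_that("epoching rejects out-of-bounds windows and a trial at sample 0 with negative tmin", {
  rec <- fixture_recording(2, 1000, events = data.frame(
    sample = c(0L, 400L, 900L), code = c(1L, 2L, 3L)))
  expect_warning(ts <- epoch_trials(rec, -1, 2), "rejected")
  expect_identical(ts$labels, 2L)     # only the middle event survives
  expect_error(suppressWarnings(epoch_trials(rec, -10, 10)), "no event")
})

test_that("epoch then concatenate preserves sample values exactly", {
  ts <- synth_trials(synth_params(n_channels = 22, trials_per_class = 3,
                                  seed = 4))$trialset
  back <- epoch_trials(as_recording(ts), 0, 3)
  expect_identical(back$trials, ts$trials)
  expect_identical(back$labels, ts$labels)
})

test_that("normalization gives zero-mean unit-variance channels, idempotently", {
  ts <- fixture_var_trialset(rbind(c(4, 1, 2), c(1, 3, 1)),
                             trials_per_class = 5)
  tn <- normalize_trials(ts)
  d <- dim(tn$trials)
  mu <- apply(tn$trials, c(1, 2), mean)
  v <- apply(tn$trials, c(1, 2), function(x) mean((x - mean(x))^2))
  expect_lt(max(abs(mu)), 1e-9)
  expect_lt(max(abs(v - 1)), 1e-6)
  tn2 <- normalize_trials(tn)
  expect_equal(tn2$trials, tn$trials, tolerance = 1e-12)
})

test_that("constant channels are floored, not fatal", {
  x <- array(rnorm(2 * 2 * 100), c(2, 2, 100))
  x[1, 1, ] <- 5
  ts <- trialset(x, c(1L, 2L), 250)
  expect_warning(tn <- normalize_trials(ts), "floored")
  expect_true(all(is.finite(tn$trials)))
})
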