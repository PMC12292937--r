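test_that("filter banks match their published definitions", {
  fs_ <- filter_banks("fixed_start")
  expect_identical(nrow(fs_), 9L)
  expect_equal(unlist(fs_[3, ]), c(low = 0, high = 12))
  expect_true(all(fs_$low == 0))

  sl <- filter_banks("sliding")
  expect_identical(nrow(sl), 8L)
  expect_equal(unlist(sl[8, ]), c(low = 28, high = 36))
  expect_true(all(sl$high - sl$low == 8))

  fb <- filter_banks("fbcsp")
  expect_identical(nrow(fb), 11L)
  expect_true(all(abs(fb$high - fb$low - 4) < 1e-12))
  expect_equal(min(fb$low), 4)
  expect_equal(max(fb$high), 40)

  mg <- filter_banks("merged")
  expect_identical(nrow(mg), 16L)
  u <- unique(rbind(as.data.frame(fs_), as.data.frame(sl)))
  expect_setequal(paste(mg$low, mg$high), paste(u$low, u$high))
  expect_error(filter_banks("nope"), "unknown")
})

four_class_ts <- function(trials_per_class = 12, seed = 2, snr = 2)
  synth_trials(synth_params(n_channels = 22, trials_per_class =
                              trials_per_class, snr = snr,
                            seed = seed))$trialset

test_that("sfbcsp trains one classifier per band and votes by majority", {
  ts <- four_class_ts()
  m <- sfbcsp(ts, n_pairs = 4)
  expect_s3_class(m, "sfbcsp")
  expect_length(m$models, 16L)
  votes <- predict(m, subset_trials(ts, 1:4), type = "votes")
  expect_identical(unname(rowSums(votes)), rep(16, 4))
  # bands containing the planted rhythm separate above chance in training
  pred <- predict(m, ts)
  expect_gt(mean(pred == ts$labels), 0.25)
})

test_that("a single-band spec degenerates to the plain banded pipeline", {
  ts <- four_class_ts(trials_per_class = 8)
  one <- structure(data.frame(low = 8, high = 13), scheme = "fixed_start",
                   class = c("band_spec", "data.frame"))
  m1 <- sfbcsp(ts, banks = one, n_pairs = 4)
  direct <- csp_svm(bandpass(ts, 8, 13), n_pairs = 4)
  expect_identical(predict(m1, ts), predict(direct, bandpass(ts, 8, 13)))
})

test_that("bands at or above Nyquist are dropped with a warning", {
  ts <- four_class_ts(trials_per_class = 8)
  wide <- structure(data.frame(low = c(8, 100), high = c(13, 130)),
                    scheme = "fixed_start",
                    class = c("band_spec", "data.frame"))
  expect_warning(m <- sfbcsp(ts, banks = wide, n_pairs = 4), "dropped")
  expect_length(m$models, 1L)
})

test_that("vote counting and tie-breaking follow the documented rule", {
  # direct checks of the tie-break helper: majority first, then summed
  # margin, then lowest class index
  classes <- 1:4
  v <- matrix(c(5, 7, 2, 2), 1)
  expect_identical(mi3deeg:::vote_winner(v, matrix(0, 1, 4), classes), 2L)
  v16 <- matrix(c(0, 0, 16, 0), 1)
  expect_identical(mi3deeg:::vote_winner(v16, matrix(0, 1, 4), classes), 3L)
  tie <- matrix(c(8, 8, 0, 0), 1)
  mg <- matrix(c(0.2, 0.9, 0, 0), 1)
  expect_identical(mi3deeg:::vote_winner(tie, mg, classes), 2L)
  mg0 <- matrix(0, 1, 4)
  expect_identical(mi3deeg:::vote_winner(tie, mg0, classes), 1L)
})

test_that("ovo builds C(k,2) models, ovr builds k, and both separate separable data", {
  ts <- four_class_ts(trials_per_class = 10, snr = 3)
  ovo <- csp_svm(ts, strategy = "ovo", n_pairs = 4)
  ovr <- csp_svm(ts, strategy = "ovr", n_pairs = 4)
  expect_length(ovo$models, 6L)
  expect_length(ovr$models, 4L)
  expect_gte(mean(predict(ovo, ts) == ts$labels), 0.95)
  expect_gte(mean(predict(ovr, ts) == ts$labels), 0.95)
  expect_error(csp_svm(subset_trials(ts, 1:2)), "at least 2")
})
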