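# planted-source recording: three sources with known mixing into named
# channels (frontal/central/occipital), small sensor noise
planted_sources_rec <- function(seed = 5, dur = 40, fs = 250) {
  n <- dur * fs
  tvec <- (seq_len(n) - 1) / fs
  withr::with_seed(seed, {
    # line: pure 50 Hz
    s_line <- sin(2 * pi * 50 * tvec + runif(1, 0, 2 * pi))
    # blink: sparse raised-cosine transients (sub-3 Hz energy)
    s_blink <- numeric(n)
    width <- round(0.4 * fs)
    for (t0 in sort(sample.int(n - width, 25)))
      s_blink[t0:(t0 + width - 1)] <- s_blink[t0:(t0 + width - 1)] +
        0.5 * (1 - cos(2 * pi * seq_len(width) / width))
    # neural: 8-13 Hz band-limited noise
    co <- signal::butter(4, c(8, 13) / (fs / 2), type = "pass")
    s_neur <- signal::filtfilt(co, rnorm(n))
    S <- rbind(s_line / sd(s_line), s_blink / sd(s_blink),
               s_neur / sd(s_neur))
    A <- cbind(line = c(1.1, 0.9, 1.0, 1.0, 0.95, 1.05, 1.0, 0.9) +
                 0.4 * rnorm(8),
               blink = c(1, 1, 0.4, 0.4, 0.1, 0.1, 0, 0),
               neural = c(0.1, 0.1, 0.4, 0.4, 1, 1, 0.2, 0.2))
    X <- A %*% S + 0.05 * matrix(rnorm(8 * n), 8)
  })
  list(rec = recording(X, fs, c("Fp1", "Fp2", "F3", "F4", "C3", "C4",
                                "O1", "O2")),
       sources = S)
}

test_that("FastICA recovers planted independent sources", {
  px <- planted_sources_rec()
  ica <- eeg_ica(px$rec, n_components = 3, seed = 2)
  cors <- abs(stats::cor(t(ica$sources), t(px$sources)))
  # each planted source matched by some component up to permutation/sign
  expect_true(all(apply(cors, 2, max) > 0.95))
})

test_that("decomposition is deterministic given the seed and honours n_components", {
  rec <- fixture_recording(8, 3000)
  i1 <- eeg_ica(rec, n_components = 5, seed = 7)
  i2 <- eeg_ica(rec, n_components = 5, seed = 7)
  expect_identical(i1$unmixing, i2$unmixing)
  expect_identical(nrow(i1$sources), 5L)

  ts <- synth_trials(synth_params(trials_per_class = 2, seed = 3))$trialset
  i64 <- eeg_ica(as_recording(ts), n_components = 15, seed = 1)
  expect_identical(nrow(i64$sources), 15L)
})

test_that("sources are the unmixed centred data and rank deficiency reduces components", {
  rec <- fixture_recording(6, 2000)
  ica <- eeg_ica(rec, n_components = 4, seed = 1)
  ctr <- rec$data - rowMeans(rec$data)
  expect_equal(ica$sources, ica$unmixing %*% ctr, tolerance = 1e-8,
               ignore_attr = TRUE)

  low <- recording(matrix(rnorm(2 * 2000), 2)[rep(1:2, 3), ] +
                     1e-13 * matrix(rnorm(6 * 2000), 6), 250)
  expect_warning(ir <- eeg_ica(low, n_components = 5, seed = 1), "rank")
  expect_lt(nrow(ir$sources), 5L)
})

test_that("planted line, blink and neural components are labelled correctly", {
  px <- planted_sources_rec()
  ica <- eeg_ica(px$rec, n_components = 3, seed = 2)
  lab <- label_components(ica, px$rec)
  cors <- abs(stats::cor(t(ica$sources), t(px$sources)))
  comp_of <- apply(cors, 2, which.max)   # planted -> component index
  expect_identical(lab$klass[comp_of[1]], "line")
  expect_gt(lab$probability[comp_of[1]], 0.9)
  expect_identical(lab$klass[comp_of[2]], "eog")
  expect_gt(lab$probability[comp_of[2]], 0.9)
  expect_identical(lab$klass[comp_of[3]], "neural")
  # labelling is a pure function: repeated calls agree
  expect_identical(lab, label_components(ica, px$rec))
})

test_that("removal at threshold 1.0 is the identity and never increases variance", {
  px <- planted_sources_rec()
  ica <- eeg_ica(px$rec, n_components = 3, seed = 2)
  lab <- label_components(ica, px$rec)
  same <- remove_artifacts(px$rec, ica, lab, threshold = 1.0)
  expect_lt(max(abs(same$data - px$rec$data)) / max(abs(px$rec$data)), 1e-6)

  cleaned <- remove_artifacts(px$rec, ica, lab, threshold = 0.9)
  expect_lte(sum(cleaned$data^2), sum(px$rec$data^2) * (1 + 1e-8))
  expect_identical(cleaned$channel_names, px$rec$channel_names)
})

test_that("removing everything is refused; removing nothing returns the input", {
  px <- planted_sources_rec()
  ica <- eeg_ica(px$rec, n_components = 3, seed = 2)
  all_bad <- data.frame(component = 1:3, klass = "line", probability = 0.99)
  expect_error(remove_artifacts(px$rec, ica, all_bad, 0.9),
               "every component")
  none <- data.frame(component = 1:3, klass = "neural", probability = 0.99)
  expect_identical(remove_artifacts(px$rec, ica, none, 0.9), px$rec)
})

test_that("a planted line-noise mixture is suppressed >= 10x with the rhythm intact", {
  p <- synth_params(trials_per_class = 4, seed = 11, line = TRUE,
                    line_amp = 2)
  clean <- synth_trials(p)$trialset
  dirty <- inject_artifacts(clean, p)
  rec <- as_recording(dirty)
  ica <- eeg_ica(rec, n_components = 15, seed = 3)
  lab <- label_components(ica, rec)
  expect_true(any(lab$klass == "line" & lab$probability > 0.9))
  out <- remove_artifacts(rec, ica, lab, threshold = 0.9)
  expect_lt(peak_power(out, 50), peak_power(rec, 50) / 10)
  expect_lt(abs(peak_power(out, 10) - peak_power(rec, 10)) /
              peak_power(rec, 10), 0.1)
})
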