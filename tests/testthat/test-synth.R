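test_that("defaults reproduce the recording geometry and are seed-stable", {
  p <- synth_params(trials_per_class = 2, seed = 5)
  g <- synth_trials(p)
  expect_identical(unname(dim_trials(g$trialset)), c(8L, 64L, 750L))
  expect_equal(g$trialset$fs, 250)
  tab <- table(g$trialset$labels)
  expect_true(all(tab == 2L))      # class balance exact by construction

  g2 <- synth_trials(synth_params(trials_per_class = 2, seed = 5))
  expect_identical(g$trialset, g2$trialset)
  g3 <- synth_trials(synth_params(trials_per_class = 2, seed = 6))
  expect_false(identical(g$trialset$trials, g3$trialset$trials))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(synth_params(snr = -1), "snr")
  expect_error(synth_params(trials_per_class = 1), "at least 2")
  expect_error(synth_params(class_patterns = matrix(1, 2, 3)),
               "classes x n_channels")
})

test_that("at zero snr the classes are statistically indistinguishable", {
  g <- synth_trials(synth_params(n_channels = 8, trials_per_class = 200,
                                 snr = 0, seed = 7))
  m <- csp(g$trialset, 1, 2)
  expect_lt(max(abs(m$eigenvalues - 0.5)), 0.05)
})

test_that("class patterns are smooth bumps peaking over distinct scalp sites", {
  g <- synth_trials(synth_params(trials_per_class = 2, seed = 1))
  pat <- g$truth$patterns
  expect_identical(dim(pat), c(4L, 64L))
  expect_true(all(apply(pat, 1, max) == 1))
  peaks <- apply(pat, 1, which.max)
  expect_identical(length(unique(peaks)), 4L)
})

test_that("line injection raises mains-band power on every channel", {
  p <- synth_params(trials_per_class = 2, seed = 3, line = TRUE)
  clean <- synth_trials(p)$trialset
  dirty <- inject_artifacts(clean, p)
  for (ch in c(1L, 20L, 40L, 64L)) {
    before <- band_power(clean$trials[1, ch, ], 250, 49, 51)
    after <- band_power(dirty$trials[1, ch, ], 250, 49, 51)
    expect_gt(after, before)
  }
  # in fact on every channel of every trial
  inc <- vapply(seq_len(64), function(ch)
    band_power(dirty$trials[2, ch, ], 250, 49, 51) -
      band_power(clean$trials[2, ch, ], 250, 49, 51), 0)
  expect_true(all(inc > 0))
})

test_that("blinks load frontal channels more than occipital ones", {
  p <- synth_params(trials_per_class = 4, seed = 9, blink = TRUE,
                    blink_rate = 2)
  clean <- synth_trials(p)$trialset
  dirty <- inject_artifacts(clean, p)
  front <- which(grepl("^(Fp|AF)", clean$channel_names))
  occ <- which(grepl("^(O|PO)", clean$channel_names))
  dpow <- function(idx) mean(vapply(idx, function(ch)
    mean(vapply(1:16, function(i)
      band_power(dirty$trials[i, ch, ], 250, 0, 3) -
        band_power(clean$trials[i, ch, ], 250, 0, 3), 0)), 0))
  expect_gt(dpow(front), dpow(occ) * 3)
})

test_that("with all artifact flags off injection is the identity", {
  p <- synth_params(trials_per_class = 2, seed = 4)
  ts <- synth_trials(p)$trialset
  expect_identical(inject_artifacts(ts, p), ts)
})

test_that("generated classes are recoverable end to end by the banded pipeline", {
  # scaled-down recovery check; the acceptance suite runs the full study
  # conditions (snr 1, 100 trials/class, 3 seeds)
  p <- synth_params(n_channels = 22, trials_per_class = 20, snr = 1,
                    seed = 21)
  ts <- synth_trials(p)$trialset
  sp <- stratified_split(ts$labels, 0.5, seed = 2)
  m <- sfbcsp(subset_trials(ts, sp$train))
  acc <- mean(predict(m, subset_trials(ts, sp$test)) ==
                ts$labels[sp$test])
  expect_gte(acc, 0.40)
})
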