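# Synthetic motor-imagery EEG ---------------------------------------------
#
# Seeded generator of 4-class MI-EEG with known ground truth. Each trial
# is pink (1/f power) background noise per channel plus a shared
# common-mode pink term (volume conduction), with a class-specific
# band-limited rhythm (8-13 Hz by default) whose per-channel amplitude
# follows a smooth Gaussian bump over that class's scalp region on the
# topographic grid. The rhythm-to-background power ratio at the bump's
# peak channel is `snr`. Optional artifact injection adds frontal blink
# transients, 50 Hz line noise and broadband EMG bursts.

#' Parameters of the synthetic MI-EEG generator
#'
#' Defaults reproduce the recording geometry the pipeline targets:
#' 64 channels at 250 Hz, 3 s epochs, four balanced classes with an
#' 8-13 Hz class rhythm.
#'
#' @param n_channels channel count (64 and 22 use the packaged montages
#'   and their channel names; other counts use generic names).
#' @param fs sampling rate, Hz.
#' @param epoch_s epoch duration, seconds.
#' @param trials_per_class trials per class (>= 2).
#' @param classes number of classes (default 4).
#' @param rhythm_band class-rhythm band edges in Hz (default 8-13).
#' @param snr rhythm-to-background power ratio at each class pattern's
#'   peak channel; 0 makes classes statistically indistinguishable.
#' @param class_patterns optional classes x channels gain matrix
#'   overriding the packaged Gaussian bumps.
#' @param blink,line,emg artifact flags for [inject_artifacts()].
#' @param blink_rate expected blinks per trial.
#' @param line_amp 50 Hz amplitude relative to unit background.
#' @param emg_rate probability of an EMG burst per trial.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n_channels = 64, fs = 250, epoch_s = 3,
                         trials_per_class = 100, classes = 4,
                         rhythm_band = c(8, 13), snr = 1,
                         class_patterns = NULL,
                         blink = FALSE, line = FALSE, emg = FALSE,
                         blink_rate = 1, line_amp = 2, emg_rate = 0.5,
                         seed = 1) {
  if (snr < 0) stop("`snr` must be non-negative")
  if (trials_per_class < 2) stop("need at least 2 trials per class")
  if (!is.null(class_patterns) &&
      (nrow(class_patterns) != classes ||
       ncol(class_patterns) != n_channels))
    stop("`class_patterns` must be classes x n_channels")
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 epoch_s = epoch_s,
                 trials_per_class = as.integer(trials_per_class),
                 classes = as.integer(classes), rhythm_band = rhythm_band,
                 snr = snr, class_patterns = class_patterns,
                 blink = blink, line = line, emg = emg,
                 blink_rate = blink_rate, line_amp = line_amp,
                 emg_rate = emg_rate, seed = as.integer(seed)),
            class = "synth_params")
}

synth_montage <- function(n_channels) {
  if (n_channels == 64) grid_mapping("64ch-1020")
  else if (n_channels == 22) grid_mapping("22ch-bciiv2a")
  else NULL
}

# smooth Gaussian bumps over distinct scalp cells (or channel indices when
# no montage applies); gain is 1 at the bump centre
default_patterns <- function(n_channels, classes) {
  mp <- synth_montage(n_channels)
  pat <- matrix(0, classes, n_channels)
  if (!is.null(mp)) {
    centers <- c("C3", "C4", "Fz", "Pz", "Cz", "Oz")
    centers <- centers[centers %in% mp$channel][seq_len(classes)]
    for (k in seq_len(classes)) {
      ci <- match(centers[k], mp$channel)
      d2 <- (mp$row - mp$row[ci])^2 + (mp$col - mp$col[ci])^2
      pat[k, ] <- exp(-d2 / (2 * 1.5^2))
    }
    colnames(pat) <- mp$channel
  } else {
    centers <- round(n_channels * (seq_len(classes) - 0.5) / classes)
    sig <- max(1, n_channels / 10)
    for (k in seq_len(classes))
      pat[k, ] <- exp(-((seq_len(n_channels) - centers[k])^2) / (2 * sig^2))
  }
  pat
}

# unit-variance pink noise (power ~ 1/f) columns, n x m
pink_noise <- function(n, m) {
  W <- stats::mvfft(matrix(stats::rnorm(n * m), n, m))
  k <- 0:(n - 1)
  fr <- pmin(k, n - k); fr[1] <- 1
  W <- W / sqrt(fr)
  W[1, ] <- 0
  x <- Re(stats::mvfft(W, inverse = TRUE)) / n
  sweep(x, 2L, apply(x, 2L, stats::sd), "/")
}

#' Generate a synthetic 4-class MI-EEG trialset with ground truth
#'
#' @param params a [synth_params()] object.
#' @return A list with `trialset` (a [trialset()], classes exactly
#'   balanced, trial order randomised) and `truth` (class patterns,
#'   pattern centres implicit in the patterns, snr, rhythm band, seed).
#' @export
synth_trials <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  nsamp <- round(p$fs * p$epoch_s)
  ntr <- p$trials_per_class * p$classes
  pat <- if (is.null(p$class_patterns))
    default_patterns(p$n_channels, p$classes) else p$class_patterns
  mp <- synth_montage(p$n_channels)
  chn <- if (!is.null(mp)) mp$channel else paste0("Ch", seq_len(p$n_channels))

  ts <- with_seed(p$seed, {
    labels <- sample(rep(seq_len(p$classes), p$trials_per_class))
    # one band-limited rhythm realisation per trial, unit variance
    co <- butter_coefs(4, p$fs, p$rhythm_band[1], p$rhythm_band[2], "pass")
    rhythm <- filtfilt_mat(co$b, co$a,
                           matrix(stats::rnorm(nsamp * ntr), nsamp, ntr))
    rhythm <- sweep(rhythm, 2L, apply(rhythm, 2L, stats::sd), "/")
    cc <- 0.5   # common-mode coupling
    trials <- array(0, c(ntr, p$n_channels, nsamp))
    for (i in seq_len(ntr)) {
      bg <- pink_noise(nsamp, p$n_channels)
      common <- pink_noise(nsamp, 1L)
      bg <- (bg + common[, rep(1L, p$n_channels)] * cc) / sqrt(1 + cc^2)
      amp <- pat[labels[i], ] * sqrt(p$snr)
      trials[i, , ] <- t(10 * (bg + outer(rhythm[, i], amp)))
    }
    trialset(trials, labels, p$fs, chn)
  })
  list(trialset = ts,
       truth = list(patterns = pat, snr = p$snr,
                    rhythm_band = p$rhythm_band, seed = p$seed))
}

#' Inject seeded artifacts into a trialset
#'
#' Adds, per enabled flag:
#' * `blink`: frontal-weighted raised-cosine transients (~0.4 s, < 3 Hz
#'   energy), Poisson-placed at `blink_rate` per trial;
#' * `line`: a 50 Hz sinusoid on every channel with a random phase per
#'   trial and an impedance-like per-channel coupling spread;
#' * `emg`: broadband > 30 Hz bursts (~0.3 s) on a random quarter of the
#'   channels with probability `emg_rate` per trial.
#'
#' With all flags off the input is returned unchanged.
#'
#' @param ts a [trialset()].
#' @param params a [synth_params()] carrying the flags, rates and seed.
#' @return The contaminated [trialset()].
#' @export
inject_artifacts <- function(ts, params) {
  stopifnot(inherits(ts, "trialset"), inherits(params, "synth_params"))
  if (!params$blink && !params$line && !params$emg) return(ts)
  p <- params
  d <- dim(ts$trials)
  nsamp <- d[3L]; nch <- d[2L]; ntr <- d[1L]
  tvec <- (seq_len(nsamp) - 1L) / ts$fs
  rms <- sqrt(mean(ts$trials^2))   # artifact amplitudes scale with the data
  mp <- synth_montage(nch)
  frontal_w <- if (!is.null(mp)) exp(-mp$row / 1.2)
               else exp(-(seq_len(nch) - 1L) / (nch / 6))
  gain_jit <- NULL
  out <- ts
  with_seed(p$seed + 104729L, {
    # mains coupling varies with electrode impedance; the spread also keeps
    # the line topography distinct from the common-mode background (two
    # sources with collinear mixing are unidentifiable by any ICA)
    gain_jit <- 1 + 0.5 * stats::rnorm(nch)
    for (i in seq_len(ntr)) {
      add <- matrix(0, nch, nsamp)
      if (p$line) {
        phase <- stats::runif(1, 0, 2 * pi)
        add <- add + (p$line_amp * rms * gain_jit) %o%
          sin(2 * pi * 50 * tvec + phase)
      }
      if (p$blink) {
        nb <- stats::rpois(1, p$blink_rate)
        for (b in seq_len(nb)) {
          width <- round(0.4 * ts$fs)
          t0 <- sample.int(max(1L, nsamp - width), 1L)
          shape <- 0.5 * (1 - cos(2 * pi * seq_len(width) / width))
          w <- numeric(nsamp)
          w[t0:(t0 + width - 1L)] <- shape
          add <- add + (5 * rms * frontal_w) %o% w
        }
      }
      if (p$emg) {
        if (stats::runif(1) < p$emg_rate) {
          width <- round(0.3 * ts$fs)
          t0 <- sample.int(max(1L, nsamp - width), 1L)
          chans <- sample.int(nch, max(1L, nch %/% 4L))
          co <- butter_coefs(4, ts$fs, 30, ts$fs / 2 - 1, "pass")
          burst <- filtfilt_mat(co$b, co$a,
                                matrix(stats::rnorm(width * length(chans)),
                                       width, length(chans)))
          seg <- matrix(0, nch, nsamp)
          seg[chans, t0:(t0 + width - 1L)] <- 2 * rms * t(burst)
          add <- add + seg
        }
      }
      out$trials[i, , ] <- out$trials[i, , ] + add
    }
  })
  out
}
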