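# Welch power spectral density --------------------------------------------
#
# The estimator splits the signal into k possibly overlapping segments of
# L samples starting every D samples, applies a taper w(n) to each,
# computes the squared-magnitude DFT of each windowed segment normalised
# by sum(w^2), and averages the segment periodograms. Values are one-sided
# densities in power per Hz (divide by fs * sum(w^2)), the convention
# under which the integral of the PSD recovers the signal variance.

#' Welch parameters
#'
#' @param fs sampling rate in Hz.
#' @param L segment length in samples; default `fs` (1 s segments, 1 Hz
#'   resolution).
#' @param overlap fractional overlap between consecutive segments in
#'   `[0, 1)`; default 0.5. The segment start spacing is
#'   `D = L - round(overlap * L)`.
#' @param window taper name, `"hamming"`, `"hann"` or `"rect"`.
#' @param fmax retain only bins at or below this frequency (Hz); default
#'   `fs / 2`.
#' @param detrend remove each segment's mean before tapering (default
#'   TRUE).
#' @return A list of class `welch_params`.
#' @export
welch_params <- function(fs, L = round(fs), overlap = 0.5,
                         window = c("hamming", "hann", "rect"),
                         fmax = fs / 2, detrend = TRUE) {
  window <- match.arg(window)
  if (L <= 0) stop("`L` must be positive")
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")
  if (fmax > fs / 2) stop("`fmax` cannot exceed the Nyquist frequency")
  D <- L - round(overlap * L)
  if (D <= 0) stop("segment spacing D must be positive")
  structure(list(fs = fs, L = as.integer(L), D = as.integer(D),
                 overlap = overlap, window = window, fmax = fmax,
                 detrend = detrend),
            class = "welch_params")
}

welch_window <- function(name, L) {
  n <- seq_len(L) - 1L
  switch(name,
         hamming = 0.54 - 0.46 * cos(2 * pi * n / (L - 1)),
         hann = 0.5 - 0.5 * cos(2 * pi * n / (L - 1)),
         rect = rep(1, L))
}

#' Welch PSD of a single-channel signal
#'
#' @param x numeric vector, length at least `p$L`.
#' @param p a [welch_params()] object.
#' @return A list with `freqs` (bin centres, Hz, up to `p$fmax`) and `psd`
#'   (one-sided density, power per Hz).
#' @export
welch_psd <- function(x, p) {
  stopifnot(inherits(p, "welch_params"))
  N <- length(x)
  L <- p$L; D <- p$D
  if (N < L)
    stop(sprintf("signal length %d is shorter than segment length L = %d",
                 N, L))
  k <- 1L + (N - L) %/% D
  w <- welch_window(p$window, L)
  U <- sum(w^2)
  nfreq <- L %/% 2L + 1L
  acc <- numeric(nfreq)
  for (i in seq_len(k) - 1L) {
    seg <- x[(D * i + 1L):(D * i + L)]
    if (p$detrend) seg <- seg - mean(seg)
    X <- stats::fft(w * seg)
    acc <- acc + (Mod(X[seq_len(nfreq)])^2) / U
  }
  psd <- acc / (k * p$fs)
  # one-sided: fold negative frequencies (not DC; not Nyquist when L even)
  dbl <- 2:(nfreq - if (L %% 2L == 0L) 1L else 0L)
  psd[dbl] <- 2 * psd[dbl]
  freqs <- (seq_len(nfreq) - 1L) * p$fs / L
  keep <- freqs <= p$fmax + 1e-9
  list(freqs = freqs[keep], psd = psd[keep])
}

#' Per-trial, per-channel Welch PSD features
#'
#' Computes the Welch PSD of every channel of every trial, truncated at
#' `p$fmax` (default 40 Hz for decoding features), giving identical
#' feature length across trials.
#'
#' @param ts a [trialset()].
#' @param p a [welch_params()]; defaults to 1 s Hamming segments with 50%
#'   overlap and a 40 Hz cap at the trialset's sampling rate.
#' @return A list of class `psd_features` with `psd`
#'   (n_trials x n_channels x n_bins array), `freqs`, `labels` and
#'   `channel_names`.
#' @export
psd_features <- function(ts, p = welch_params(ts$fs, fmax = 40)) {
  stopifnot(inherits(ts, "trialset"))
  d <- dim(ts$trials)
  first <- welch_psd(ts$trials[1, 1, ], p)
  nbin <- length(first$freqs)
  out <- array(0, c(d[1L], d[2L], nbin))
  for (i in seq_len(d[1L]))
    for (ch in seq_len(d[2L]))
      out[i, ch, ] <- welch_psd(ts$trials[i, ch, ], p)$psd
  structure(list(psd = out, freqs = first$freqs, labels = ts$labels,
                 channel_names = ts$channel_names, fs = ts$fs),
            class = "psd_features")
}

#' @export
print.psd_features <- function(x, ...) {
  d <- dim(x$psd)
  cat(sprintf("<psd_features> %d trials x %d channels x %d bins (%.1f-%.1f Hz)\n",
              d[1], d[2], d[3], min(x$freqs), max(x$freqs)))
  invisible(x)
}
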