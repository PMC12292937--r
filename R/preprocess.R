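# Zero-phase IIR filtering -----------------------------------------------
#
# Filtering runs forward and backward (squared-magnitude response, zero
# phase) so event latencies are untouched. The core is vectorised across
# signals: the direct-form-II-transposed recursion advances one time step
# for all columns at once, which is what makes 16-band filter banks over
# hundreds of trials affordable. Edge handling follows the usual
# odd-reflection extension plus steady-state initial conditions.

# steady-state initial filter state per unit step input (one value per
# state); multiplied by the first sample of each column at run time
lfilter_zi <- function(b, a) {
  n <- length(a) - 1L
  if (n == 0L) return(numeric(0))
  comp <- matrix(0, n, n)
  comp[1, ] <- -a[-1L] / a[1L]
  if (n > 1L) comp[cbind(2:n, 1:(n - 1L))] <- 1
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n) - t(comp), B)
}

# direct-form II transposed, X is samples x signals, zi0 is the per-unit
# initial state (scaled by the first row of X)
filt_df2t <- function(b, a, X, zi0 = NULL) {
  b <- b / a[1L]; a <- a / a[1L]
  nfilt <- max(length(b), length(a))
  b <- c(b, numeric(nfilt - length(b)))
  a <- c(a, numeric(nfilt - length(a)))
  n <- nrow(X); m <- ncol(X)
  Y <- matrix(0, n, m)
  z <- if (is.null(zi0)) matrix(0, nfilt - 1L, m)
       else zi0 %o% X[1L, ]
  ns <- nfilt - 1L
  for (t in seq_len(n)) {
    xt <- X[t, ]
    yt <- b[1L] * xt + z[1L, ]
    if (ns > 1L)
      for (i in 1:(ns - 1L))
        z[i, ] <- b[i + 1L] * xt + z[i + 1L, ] - a[i + 1L] * yt
    z[ns, ] <- b[nfilt] * xt - a[nfilt] * yt
    Y[t, ] <- yt
  }
  Y
}

# forward-backward filter with odd-reflection padding; X samples x signals
filtfilt_mat <- function(b, a, X) {
  n <- nrow(X)
  npad <- min(3L * (max(length(a), length(b)) - 1L), n - 1L)
  zi0 <- lfilter_zi(b, a)
  pre <- 2 * matrix(X[1L, ], npad, ncol(X), byrow = TRUE) -
    X[(npad + 1L):2L, , drop = FALSE]
  post <- 2 * matrix(X[n, ], npad, ncol(X), byrow = TRUE) -
    X[(n - 1L):(n - npad), , drop = FALSE]
  ext <- rbind(pre, X, post)
  Y <- filt_df2t(b, a, ext, zi0)
  Y <- filt_df2t(b, a, Y[nrow(Y):1L, , drop = FALSE], zi0)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(npad + 1L):(npad + n), , drop = FALSE]
}

butter_coefs <- function(order, fs, low, high, type) {
  w <- c(low, high) / (fs / 2)
  flt <- signal::butter(order, if (type == "low") w[2L] else w, type = type)
  list(b = flt$b, a = flt$a)
}

# filter a recording or trialset with arbitrary (b, a) zero-phase
apply_zerophase <- function(x, b, a) {
  if (inherits(x, "eeg_recording")) {
    out <- x
    out$data <- t(filtfilt_mat(b, a, t(x$data)))
    rownames(out$data) <- x$channel_names
    out
  } else if (inherits(x, "trialset")) {
    d <- dim(x$trials)
    # samples x (trials*channels): every trial/channel filtered independently
    flat <- matrix(aperm(x$trials, c(3L, 1L, 2L)), nrow = d[3L])
    flat <- filtfilt_mat(b, a, flat)
    out <- x
    out$trials <- aperm(array(flat, c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
    out
  } else stop("unsupported input type")
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies a 4th-order Butterworth bandpass forward and backward (zero
#' phase). With `low = 0` the filter degenerates to a low-pass at `high`
#' (a 0 Hz high-pass edge is the identity); the mean is removed first in
#' that case so the pass band is not dominated by DC.
#'
#' @param x an [recording()] or [trialset()].
#' @param low,high band edges in Hz, `0 <= low < high < fs/2`.
#' @param order filter order of the analogue prototype (default 4).
#' @return An object of the same class, band-limited, with channel count
#'   and order unchanged.
#' @export
bandpass <- function(x, low, high, order = 4L) {
  fs <- x$fs
  if (!is.numeric(low) || !is.numeric(high) || low < 0 || low >= high ||
      high >= fs / 2)
    stop(sprintf("invalid band edges: need 0 <= low < high < fs/2 = %g", fs / 2))
  if (low == 0) {
    co <- butter_coefs(order, fs, 0, high, "low")
    x <- detrend_mean(x)
  } else {
    co <- butter_coefs(order, fs, low, high, "pass")
  }
  apply_zerophase(x, co$b, co$a)
}

#' Zero-phase Butterworth notch (band-stop) filter
#'
#' Rejects a narrow band, by default the 49.9-50.1 Hz window around the
#' 50 Hz mains frequency, using a 4th-order Butterworth band-stop applied
#' forward and backward.
#'
#' @inheritParams bandpass
#' @param low,high stop-band edges in Hz, `0 < low < high < fs/2`.
#' @return An object of the same class with the band rejected.
#' @export
notch <- function(x, low = 49.9, high = 50.1, order = 4L) {
  fs <- x$fs
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || low >= high ||
      high >= fs / 2)
    stop(sprintf("invalid band edges: need 0 < low < high < fs/2 = %g", fs / 2))
  co <- butter_coefs(order, fs, low, high, "stop")
  apply_zerophase(x, co$b, co$a)
}

# remove the per-channel (or per-trial-channel) mean
detrend_mean <- function(x) {
  if (inherits(x, "eeg_recording")) {
    x$data <- x$data - rowMeans(x$data)
    x
  } else {
    mu <- apply(x$trials, c(1L, 2L), mean)
    x$trials <- x$trials - as.vector(mu)  # recycles over the samples axis
    x
  }
}

#' Common-average re-reference
#'
#' Subtracts the instantaneous mean over channels from every channel.
#' Provided as an option; the decoding pipeline does not require it.
#'
#' @param rec an [recording()].
#' @return The re-referenced recording.
#' @export
car_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec
}

#' Epoch a recording around its event markers
#'
#' Cuts one trial per event over the half-open window
#' `[event + tmin, event + tmax)` using 0-based sample indexing, so the
#' default motor-imagery window of `[0, 3)` s at 250 Hz yields exactly 750
#' samples per trial. Events whose window exceeds the recording bounds are
#' dropped with a warning.
#'
#' @param rec an [recording()] with at least one event.
#' @param tmin,tmax window start and end in seconds relative to each event.
#' @return A [trialset()] with labels taken from the event codes, in
#'   acquisition order.
#' @export
epoch_trials <- function(rec, tmin = 0, tmax = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (tmax <= tmin) stop("`tmax` must exceed `tmin`")
  fs <- rec$fs
  nsamp <- round((tmax - tmin) * fs)
  total <- ncol(rec$data)
  start <- rec$events$sample + round(tmin * fs)  # 0-based
  ok <- start >= 0L & (start + nsamp) <= total
  if (any(!ok))
    warning(sprintf("%d event(s) rejected: epoch window outside recording",
                    sum(!ok)))
  if (!any(ok)) stop("no event leaves a complete epoch inside the recording")
  keep <- which(ok)
  trials <- array(0, c(length(keep), nrow(rec$data), nsamp))
  for (j in seq_along(keep)) {
    s0 <- start[keep[j]]
    trials[j, , ] <- rec$data[, (s0 + 1L):(s0 + nsamp)]
  }
  trialset(trials, rec$events$code[keep], fs, rec$channel_names)
}

#' Per-trial per-channel z-score normalization
#'
#' Centres every channel of every trial to zero mean and scales it to unit
#' variance. Channels with (numerically) zero variance are floored at
#' `1e-12` rather than producing non-finite output, with a warning.
#'
#' @param ts a [trialset()].
#' @return The normalized [trialset()]; idempotent up to floating point.
#' @export
normalize_trials <- function(ts) {
  stopifnot(inherits(ts, "trialset"))
  d <- dim(ts$trials)
  out <- ts
  floored <- FALSE
  for (i in seq_len(d[1L])) {
    m <- trial_matrix(ts, i)
    mu <- rowMeans(m)
    sd_ <- sqrt(rowSums((m - mu)^2) / d[3L])
    if (any(sd_ < 1e-12)) { floored <- TRUE; sd_ <- pmax(sd_, 1e-12) }
    out$trials[i, , ] <- (m - mu) / sd_
  }
  if (floored)
    warning("constant channel(s): variance floored at 1e-12")
  out
}
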