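# Automated ICA artifact rejection ----------------------------------------
#
# A FastICA decomposition (deflation, seeded) splits the recording into
# statistically independent components; a rule-based scorer assigns each
# component to one of {neural, emg, eog, ecg, line, impedance, other}
# with a probability in [0, 1]; components labelled as artifacts with
# probability above the removal threshold (0.9 by default) are subtracted
# from the recording. The scorer is a pluggable stand-in with documented
# heuristics — a drop-in external classifier returning the same label
# frame can be used instead.

#' FastICA decomposition of a recording
#'
#' Deflation-mode FastICA on the channel-centred data. Deterministic
#' given `seed`. If the data rank is below `n_components` the component
#' count is reduced with a warning.
#'
#' @param rec an [recording()], ideally high-pass filtered (>= 0.5 Hz)
#'   first so slow drifts do not dominate the decomposition.
#' @param n_components number of components to extract (default 15).
#' @param seed RNG seed for the random rotation initialisation.
#' @param tol convergence tolerance (default 1e-4).
#' @param maxit maximum iterations per component (default 500).
#' @return An object of class `eeg_ica` with `unmixing`
#'   (components x channels), `mixing` (channels x components), `sources`
#'   (components x samples, unit variance), and the per-channel `center`.
#' @export
eeg_ica <- function(rec, n_components = 15, seed = 1, tol = 1e-4,
                    maxit = 500) {
  stopifnot(inherits(rec, "eeg_recording"))
  C <- nrow(rec$data)
  if (n_components > C)
    stop("n_components cannot exceed the channel count")
  cv <- stats::cov(t(rec$data))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  rk <- sum(ev > 1e-10 * max(ev))
  if (rk < n_components) {
    warning(sprintf("data rank %d < n_components %d: reducing", rk,
                    n_components))
    n_components <- rk
  }
  ctr <- rowMeans(rec$data)
  fit <- with_seed(seed,
                   ica::icafast(t(rec$data), nc = n_components,
                                alg = "def", tol = tol, maxit = maxit))
  structure(list(unmixing = fit$W, mixing = fit$M, sources = t(fit$S),
                 center = ctr, n_components = n_components,
                 fs = rec$fs, channel_names = rec$channel_names,
                 seed = seed),
            class = "eeg_ica")
}

#' @export
print.eeg_ica <- function(x, ...) {
  cat(sprintf("<eeg_ica> %d components over %d channels (%d samples)\n",
              x$n_components, length(x$channel_names), ncol(x$sources)))
  invisible(x)
}

frontal_channels <- function(channel_names)
  grepl("^(Fp|AF)", channel_names, ignore.case = FALSE)

# fraction of one-sided PSD power inside [lo, hi] Hz
band_power_fraction <- function(psd, freqs, lo, hi) {
  tot <- sum(psd)
  if (tot <= 0) return(0)
  sum(psd[freqs >= lo & freqs <= hi]) / tot
}

#' Heuristic labelling of ICA components
#'
#' Pure function of the decomposition and recording: each component gets
#' one of seven classes and a probability in `[0, 1]`. Scores are mapped
#' through fixed logistic squashings of documented statistics:
#' * `line`: fraction of source power in 49-51 Hz (pivot 0.6);
#' * `eog`: |correlation| with a <3 Hz low-passed frontal-channel proxy
#'   (pivot 0.7) gated by frontal topography dominance;
#' * `ecg`: autocorrelation peak at 0.8-1.5 s lag gated by heavy-tailed
#'   (QRS-like) sample kurtosis;
#' * `impedance`: concentration of the topography's squared mass on one
#'   channel (pivot 0.8);
#' * `emg`: fraction of power above 30 Hz (pivot 0.5);
#' * otherwise `neural` (probability `1 -` strongest artifact score), or
#'   `other` when no class is convincing.
#'
#' @param ica an [eeg_ica()] decomposition.
#' @param rec the [recording()] it was fitted on.
#' @return data.frame with columns `component`, `klass`, `probability`.
#' @export
label_components <- function(ica, rec) {
  stopifnot(inherits(ica, "eeg_ica"), inherits(rec, "eeg_recording"))
  fs <- rec$fs
  front <- frontal_channels(ica$channel_names)
  eog_proxy <- NULL
  if (any(front)) {
    proxy <- colMeans(rec$data[front, , drop = FALSE])
    co <- butter_coefs(4, fs, 0, 3, "low")
    eog_proxy <- as.vector(filtfilt_mat(co$b, co$a,
                                        matrix(proxy - mean(proxy))))
  }
  wp <- welch_params(fs, L = min(round(fs), ncol(ica$sources)),
                     fmax = fs / 2)
  out <- data.frame(component = seq_len(ica$n_components),
                    klass = "neural", probability = 0,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ica$n_components)) {
    s <- ica$sources[k, ]
    topo <- ica$mixing[, k]
    sp <- welch_psd(s, wp)

    p_line <- stats::plogis((band_power_fraction(sp$psd, sp$freqs, 49, 51) -
                               0.6) / 0.05)
    # broadband high-frequency fraction, mains band excluded so a pure
    # line component does not read as EMG
    hf <- band_power_fraction(sp$psd, sp$freqs, 30, fs / 2) -
      band_power_fraction(sp$psd, sp$freqs, 49, 51)
    p_emg <- stats::plogis((hf - 0.5) / 0.05)
    p_eog <- 0
    if (!is.null(eog_proxy)) {
      r <- abs(stats::cor(s, eog_proxy))
      dom <- mean(abs(topo[front])) / mean(abs(topo))
      p_eog <- stats::plogis((r - 0.7) / 0.05) *
        stats::plogis((dom - 1.5) / 0.25)
    }
    lag <- seq.int(round(0.8 * fs), min(round(1.5 * fs), length(s) - 1L))
    ac <- stats::acf(s, lag.max = max(lag), plot = FALSE)$acf[lag + 1L]
    exkurt <- mean((s - mean(s))^4) / stats::var(s)^2 - 3
    p_ecg <- stats::plogis((max(ac) - 0.4) / 0.1) *
      stats::plogis((exkurt - 3) / 1.5)
    p_imp <- stats::plogis((max(topo^2) / sum(topo^2) - 0.8) / 0.05)

    # precedence: narrowband line before broadband emg, specific before
    # generic
    probs <- c(line = p_line, eog = p_eog, ecg = p_ecg,
               impedance = p_imp, emg = p_emg)
    if (max(probs) > 0.5) {
      kl <- names(probs)[which.max(probs)]
      out$klass[k] <- kl
      out$probability[k] <- max(probs)
    } else if (max(probs) < 0.35) {
      out$klass[k] <- "neural"
      out$probability[k] <- 1 - max(probs)
    } else {
      out$klass[k] <- "other"
      out$probability[k] <- 0.5
    }
  }
  out
}

#' Remove labelled artifact components from a recording
#'
#' Components whose class is non-neural (and not the low-confidence
#' `other` bucket's neural complement) with probability above `threshold`
#' are subtracted from the original data (`data - M_k s_k` summed over
#' removed components), so the out-of-subspace residual of the
#' decomposition is preserved and a threshold of 1.0 is the identity.
#'
#' @param rec the [recording()] the decomposition was fitted on.
#' @param ica an [eeg_ica()] decomposition.
#' @param labels label frame from [label_components()] (or a drop-in
#'   classifier with the same columns).
#' @param threshold removal probability threshold in `(0, 1]`
#'   (default 0.9).
#' @return The cleaned [recording()]; channel count and order unchanged.
#' @export
remove_artifacts <- function(rec, ica, labels, threshold = 0.9) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(ica, "eeg_ica"))
  if (threshold <= 0 || threshold > 1)
    stop("`threshold` must lie in (0, 1]")
  rem <- which(labels$klass != "neural" & labels$probability > threshold)
  if (length(rem) == ica$n_components && length(rem) > 0)
    stop("refusing to remove every component (would delete the recording)")
  if (!length(rem)) return(rec)
  out <- rec
  out$data <- rec$data - ica$mixing[, rem, drop = FALSE] %*%
    ica$sources[rem, , drop = FALSE]
  rownames(out$data) <- rec$channel_names
  out
}
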