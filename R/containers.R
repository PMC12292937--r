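#' Construct a continuous EEG recording
#'
#' An `eeg_recording` bundles a channels-by-samples signal matrix (microvolts)
#' with its channel labels, sampling rate and event markers. It is the input
#' type of the preprocessing and ICA stages.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (scalar, > 0).
#' @param channel_names character vector of unique channel labels
#'   (10-20 system names for the packaged montages); defaults to
#'   `"Ch1".."ChN"`.
#' @param events data.frame with integer column `sample` (0-based sample
#'   index of the marker) and column `code` (integer class code, e.g. 1..4
#'   for markers S1..S4). May have zero rows.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, channel_names = NULL, events = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (is.null(channel_names))
    channel_names <- paste0("Ch", seq_len(nrow(data)))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data))
    stop("length(channel_names) must equal nrow(data)")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (is.null(events))
    events <- data.frame(sample = integer(0), code = integer(0))
  events <- as.data.frame(events)
  if (!all(c("sample", "code") %in% names(events)))
    stop("`events` needs columns `sample` and `code`")
  events$sample <- as.integer(events$sample)
  events$code <- as.integer(events$code)
  if (nrow(events) && (any(events$sample < 0L) ||
                       any(events$sample >= ncol(data))))
    stop("event sample indices must lie within the recording")
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = as.numeric(fs),
         channel_names = channel_names,
         events = events[, c("sample", "code")]),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Construct a set of epoched trials
#'
#' A `trialset` holds epoched EEG as an `n_trials x n_channels x n_samples`
#' array with one class label per trial.
#'
#' @param trials numeric array, `n_trials x n_channels x n_samples`
#'   (microvolts).
#' @param labels integer class codes, one per trial (1..4 for the four
#'   motor-imagery classes).
#' @param fs sampling rate in Hz.
#' @param channel_names channel labels; defaults to `"Ch1".."ChN"`.
#' @param trial_index original acquisition indices of the trials (kept
#'   through subsetting so fitted models can record exactly which trials
#'   they saw); defaults to `1..n`.
#' @return An object of class `trialset`.
#' @export
trialset <- function(trials, labels, fs, channel_names = NULL,
                     trial_index = NULL) {
  if (length(dim(trials)) != 3L)
    stop("`trials` must be an n_trials x n_channels x n_samples array")
  storage.mode(trials) <- "double"
  labels <- as.integer(labels)
  if (length(labels) != dim(trials)[1L])
    stop("length(labels) must equal the number of trials")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (is.null(channel_names))
    channel_names <- paste0("Ch", seq_len(dim(trials)[2L]))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(trials)[2L])
    stop("length(channel_names) must equal the number of channels")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (is.null(trial_index)) trial_index <- seq_len(dim(trials)[1L])
  if (length(trial_index) != dim(trials)[1L])
    stop("length(trial_index) must equal the number of trials")
  structure(
    list(trials = trials, labels = labels, fs = as.numeric(fs),
         channel_names = channel_names,
         trial_index = as.integer(trial_index)),
    class = "trialset")
}

#' @export
print.trialset <- function(x, ...) {
  d <- dim(x$trials)
  tab <- table(factor(x$labels, levels = sort(unique(x$labels))))
  cat(sprintf("<trialset> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat("  classes:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' Number of trials, channels and samples of a trialset
#' @param ts a [trialset()].
#' @return Named integer vector `c(trials, channels, samples)`.
#' @export
dim_trials <- function(ts) {
  stopifnot(inherits(ts, "trialset"))
  d <- dim(ts$trials)
  c(trials = d[1L], channels = d[2L], samples = d[3L])
}

#' Extract one trial as a channels x samples matrix
#' @param ts a [trialset()].
#' @param i trial index.
#' @return numeric matrix, channels x samples.
#' @export
trial_matrix <- function(ts, i) {
  m <- ts$trials[i, , , drop = TRUE]
  dim(m) <- dim(ts$trials)[2:3]
  rownames(m) <- ts$channel_names
  m
}

#' Subset a trialset by trial index
#' @param ts a [trialset()].
#' @param idx integer vector of trial indices.
#' @return a [trialset()] with the selected trials, order preserved.
#' @export
subset_trials <- function(ts, idx) {
  trialset(ts$trials[idx, , , drop = FALSE], ts$labels[idx], ts$fs,
           ts$channel_names, trial_index = ts$trial_index[idx])
}

#' Concatenate the trials of a trialset into a continuous recording
#'
#' Trials are laid end to end (no resampling, no gaps) and an event marker
#' carrying the trial's class code is placed at each trial onset, so that
#' re-epoching with the trial duration recovers the original trials
#' sample-exactly.
#'
#' @param ts a [trialset()].
#' @return An [recording()] of length `n_trials * n_samples`.
#' @export
as_recording <- function(ts) {
  stopifnot(inherits(ts, "trialset"))
  d <- dim(ts$trials)
  dat <- matrix(0, d[2L], d[1L] * d[3L])
  for (i in seq_len(d[1L])) {
    m <- trial_matrix(ts, i)
    dat[, ((i - 1L) * d[3L] + 1L):(i * d[3L])] <- m
  }
  ev <- data.frame(sample = (seq_len(d[1L]) - 1L) * d[3L],
                   code = ts$labels)
  recording(dat, ts$fs, ts$channel_names, ev)
}

# run expr under a temporary RNG state seeded with `seed`; restores the
# caller's RNG so library code never perturbs user-level reproducibility
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
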