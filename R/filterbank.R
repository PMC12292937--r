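# Filter banks and SFB-CSP -------------------------------------------------
#
# The superimposed filter bank combines two segmentations of 0-36 Hz:
# fixed-start bands sharing a 0 Hz lower edge with the upper edge growing
# in 4 Hz steps (9 bands), and an 8 Hz window sliding forward in 4 Hz
# steps (8 bands). Their union, with the duplicated (0,8) band removed,
# gives 16 unique bands. The FBCSP baseline uses eleven uniform 4 Hz-wide
# bands spanning 4-40 Hz. Per band, trials are band-filtered, a
# multi-class CSP+SVM is trained, and prediction is by cross-band
# majority vote.

#' Build a band-pass filter bank
#'
#' @param scheme one of
#'   * `"fixed_start"`: (0,4), (0,8), ..., (0,36) — 9 bands;
#'   * `"sliding"`: (0,8), (4,12), ..., (28,36) — 8 bands;
#'   * `"fbcsp"`: eleven uniform 4 Hz-wide bands spanning 4-40 Hz;
#'   * `"merged"`: the set union of `fixed_start` and `sliding`
#'     (duplicates removed) — 16 bands.
#' @return A `band_spec`: data.frame with columns `low`, `high` (Hz) and
#'   a `scheme` attribute.
#' @export
filter_banks <- function(scheme = c("fixed_start", "sliding", "fbcsp",
                                    "merged")) {
  scheme <- tryCatch(match.arg(scheme),
                     error = function(e) stop("unknown filter-bank scheme"))
  bands <- switch(
    scheme,
    fixed_start = data.frame(low = 0, high = 4 * (1:9)),
    sliding = data.frame(low = 4 * (0:7), high = 4 * (0:7) + 8),
    fbcsp = {
      starts <- seq(4, 36, length.out = 11)
      data.frame(low = starts, high = starts + 4)
    },
    merged = {
      fs_ <- filter_banks("fixed_start"); sl <- filter_banks("sliding")
      u <- unique(rbind(as.data.frame(fs_), as.data.frame(sl)))
      rownames(u) <- NULL
      u
    })
  if (any(bands$low >= bands$high)) stop("invalid band in scheme ", scheme)
  structure(bands, scheme = scheme, class = c("band_spec", "data.frame"))
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %d bands %s\n", attr(x, "scheme"), nrow(x),
              paste(sprintf("(%g,%g)", x$low, x$high), collapse = " ")))
  invisible(x)
}

#' Fit the superimposed filter-bank CSP classifier
#'
#' For every band: band-filter the training trials (a 0 Hz lower edge is
#' realised as a low-pass with the DC offset removed first), fit
#' multi-class CSP features and one SVM classifier. Bands whose upper
#' edge reaches the Nyquist frequency are dropped with a warning.
#'
#' @param ts a training [trialset()].
#' @param banks a [filter_banks()] spec (default the 16-band merged bank).
#' @param n_pairs CSP rows retained per binary model (top and bottom
#'   `n_pairs`).
#' @param strategy per-band multi-class decomposition, `"ovo"` or
#'   `"ovr"`.
#' @param svm an [svm_params()] object.
#' @return An object of class `sfbcsp` with one `csp_svm` per band.
#' @export
sfbcsp <- function(ts, banks = filter_banks("merged"), n_pairs = 4,
                   strategy = c("ovo", "ovr"), svm = svm_params()) {
  stopifnot(inherits(ts, "trialset"), inherits(banks, "band_spec"))
  strategy <- match.arg(strategy)
  ok <- banks$high < ts$fs / 2
  if (any(!ok)) {
    warning(sprintf("%d band(s) dropped: upper edge at or above fs/2 = %g Hz",
                    sum(!ok), ts$fs / 2))
    banks <- banks[ok, , drop = FALSE]
  }
  if (!nrow(banks)) stop("no usable bands below the Nyquist frequency")
  models <- vector("list", nrow(banks))
  for (n in seq_len(nrow(banks))) {
    filtered <- bandpass(ts, banks$low[n], banks$high[n])
    models[[n]] <- csp_svm(filtered, strategy = strategy,
                           n_pairs = n_pairs, svm = svm)
  }
  structure(list(models = models, banks = banks, strategy = strategy,
                 n_pairs = n_pairs, svm = svm, fs = ts$fs,
                 classes = sort(unique(ts$labels)),
                 train_index = ts$trial_index),
            class = "sfbcsp")
}

#' @export
print.sfbcsp <- function(x, ...) {
  cat(sprintf("<sfbcsp> %d per-band CSP+SVM classifiers (%s, scheme %s), classes %s\n",
              length(x$models), x$strategy, attr(x$banks, "scheme"),
              paste(x$classes, collapse = ",")))
  invisible(x)
}

#' Predict with an SFB-CSP model by cross-band majority vote
#'
#' Each band classifier casts one vote per trial; the label with most
#' votes wins. Ties break on the summed per-band decision margins of the
#' tied classes, then on the lowest class index.
#'
#' @param object an [sfbcsp()] model.
#' @param newdata a [trialset()] (or single channels x samples matrix).
#' @param type `"class"` (default) or `"votes"` (per-class vote counts).
#' @param ... unused.
#' @return Predicted labels (or the vote matrix).
#' @export
predict.sfbcsp <- function(object, newdata, type = c("class", "votes"),
                           ...) {
  type <- match.arg(type)
  if (!inherits(newdata, "trialset")) {
    m <- as.matrix(newdata)
    newdata <- trialset(array(m, c(1L, nrow(m), ncol(m))), 0L, object$fs,
                        channel_names = rownames(m))
  }
  n <- dim(newdata$trials)[1L]
  classes <- object$classes
  votes <- matrix(0L, n, length(classes),
                  dimnames = list(NULL, as.character(classes)))
  margin <- matrix(0, n, length(classes),
                   dimnames = list(NULL, as.character(classes)))
  for (bn in seq_along(object$models)) {
    filtered <- bandpass(newdata, object$banks$low[bn],
                         object$banks$high[bn])
    bm <- object$models[[bn]]
    mm <- csp_svm_margins(bm, filtered)
    lab <- if (bm$strategy == "ovr")
      vote_winner(mm$margin, mm$margin, bm$classes)
    else vote_winner(mm$votes, mm$margin, bm$classes)
    margin <- margin + mm$margin
    for (k in seq_len(n)) {
      ci <- as.character(lab[k])
      votes[k, ci] <- votes[k, ci] + 1L
    }
  }
  if (type == "votes") return(votes)
  vote_winner(votes, margin, classes)
}
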