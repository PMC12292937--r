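# Multi-class CSP + SVM wrappers ------------------------------------------
#
# CSP is inherently two-class; four-class decoding decomposes into
# one-vs-one (6 pairwise CSP+SVM models, majority vote) or one-vs-rest
# (4 class-vs-rest models, argmax decision value). Ties break on the
# highest summed decision-function margin, then on the lowest class
# index — deterministic and documented.

#' RBF-SVM hyperparameters
#'
#' Defaults follow the MATLAB-style settings used throughout the pipeline
#' (kernel scale 0.783, box constraint 0.922), mapped to the
#' `exp(-gamma ||u-v||^2)` parameterisation as `gamma = 1 / scale^2`.
#'
#' @param kernel_scale RBF kernel scale `s` (gamma becomes `1/s^2`).
#' @param cost box constraint (regularisation) C.
#' @return A list of class `svm_params`.
#' @export
svm_params <- function(kernel_scale = 0.783, cost = 0.922) {
  structure(list(gamma = 1 / kernel_scale^2, cost = cost,
                 kernel_scale = kernel_scale),
            class = "svm_params")
}

svm_fit <- function(x, y, svmp) {
  e1071::svm(x, y, kernel = "radial", gamma = svmp$gamma, cost = svmp$cost,
             scale = FALSE)
}

# decision values of a binary e1071 svm oriented so positive favours
# `pos`; the single decision column is named "<first>/<second>"
svm_margin <- function(fit, x, pos) {
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")
  nm <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  if (nm[1] == as.character(pos)) dv[, 1] else -dv[, 1]
}

fit_pair_csp_svm <- function(ts, a, b, n_pairs, svmp, gene = NULL) {
  model <- csp(ts, a, b)
  if (!is.null(gene)) model <- apply_weight(model, gene)
  else if (!is.null(n_pairs)) model <- reduce_rows(model, n_pairs)
  idx <- which(ts$labels %in% c(a, b))
  sub <- subset_trials(ts, idx)
  feats <- csp_features(model, sub)
  y <- factor(sub$labels, levels = c(a, b))
  list(csp = model, svm = svm_fit(feats, y, svmp), a = a, b = b)
}

#' Fit a multi-class CSP + SVM classifier
#'
#' @param ts a training [trialset()] (2+ classes, every class with at
#'   least 2 trials).
#' @param strategy `"ovo"` (all pairwise binary models, majority vote) or
#'   `"ovr"` (class-vs-rest models, argmax decision value).
#' @param n_pairs CSP rows retained per binary model are the top and
#'   bottom `n_pairs` rows (default 4, the 22-to-8-row reduction on a
#'   22-channel montage).
#' @param svm an [svm_params()] object.
#' @return An object of class `csp_svm` with a [predict.csp_svm()] method.
#' @export
csp_svm <- function(ts, strategy = c("ovo", "ovr"), n_pairs = 4,
                    svm = svm_params()) {
  stopifnot(inherits(ts, "trialset"))
  strategy <- match.arg(strategy)
  classes <- sort(unique(ts$labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  cnt <- table(ts$labels)
  if (any(cnt < 2))
    stop("every class needs at least 2 trials; got ",
         paste(sprintf("%s:%d", names(cnt), cnt), collapse = " "))
  models <- list()
  if (strategy == "ovo") {
    for (i in seq_along(classes)) for (j in seq_along(classes)) {
      if (i >= j) next
      a <- classes[i]; b <- classes[j]
      models[[paste(a, b, sep = "v")]] <-
        fit_pair_csp_svm(ts, a, b, n_pairs, svm)
    }
  } else {
    for (a in classes) {
      rest <- -1L  # pseudo-label for the pooled complement
      lab2 <- ifelse(ts$labels == a, a, rest)
      ts2 <- trialset(ts$trials, lab2, ts$fs, ts$channel_names,
                      trial_index = ts$trial_index)
      models[[paste0(a, "vR")]] <-
        fit_pair_csp_svm(ts2, a, rest, n_pairs, svm)
    }
  }
  structure(list(models = models, strategy = strategy, classes = classes,
                 n_pairs = n_pairs, svm = svm,
                 train_index = ts$trial_index),
            class = "csp_svm")
}

#' @export
print.csp_svm <- function(x, ...) {
  cat(sprintf("<csp_svm> %s: %d binary CSP+SVM model(s) over classes %s\n",
              x$strategy, length(x$models),
              paste(x$classes, collapse = ",")))
  invisible(x)
}

# per-class summed decision margins for new trials; rows = trials
csp_svm_margins <- function(object, ts) {
  n <- dim(ts$trials)[1L]
  classes <- object$classes
  margin <- matrix(0, n, length(classes),
                   dimnames = list(NULL, as.character(classes)))
  votes <- matrix(0L, n, length(classes),
                  dimnames = list(NULL, as.character(classes)))
  for (m in object$models) {
    feats <- csp_features(m$csp, ts)
    dv <- svm_margin(m$svm, feats, m$a)
    ca <- as.character(m$a)
    if (m$b == -1L) {            # one-vs-rest
      margin[, ca] <- margin[, ca] + dv
      votes[, ca] <- votes[, ca] + as.integer(dv > 0)
    } else {
      cb <- as.character(m$b)
      margin[, ca] <- margin[, ca] + dv
      margin[, cb] <- margin[, cb] - dv
      win <- ifelse(dv > 0, ca, cb)
      for (k in seq_len(n)) votes[k, win[k]] <- votes[k, win[k]] + 1L
    }
  }
  list(margin = margin, votes = votes)
}

# deterministic winner: most votes, then largest summed margin, then
# lowest class index
vote_winner <- function(votes, margin, classes) {
  n <- nrow(votes)
  out <- integer(n)
  for (k in seq_len(n)) {
    v <- votes[k, ]
    top <- which(v == max(v))
    if (length(top) > 1) {
      mg <- margin[k, top]
      top <- top[mg == max(mg)]
    }
    out[k] <- classes[min(top)]
  }
  out
}

#' Predict class labels with a multi-class CSP + SVM model
#'
#' @param object a [csp_svm()] model.
#' @param newdata a [trialset()] or a single channels x samples matrix.
#' @param type `"class"` (default), `"votes"` or `"margin"`.
#' @param ... unused.
#' @return Predicted labels, or the per-class vote / margin matrix.
#' @export
predict.csp_svm <- function(object, newdata, type = c("class", "votes",
                                                      "margin"), ...) {
  type <- match.arg(type)
  if (!inherits(newdata, "trialset")) {
    m <- as.matrix(newdata)
    newdata <- trialset(array(m, c(1L, nrow(m), ncol(m))), 0L, 1,
                        channel_names = rownames(m))
  }
  mm <- csp_svm_margins(object, newdata)
  switch(type,
         votes = mm$votes,
         margin = mm$margin,
         class = if (object$strategy == "ovr")
           vote_winner(mm$margin, mm$margin, object$classes)
         else vote_winner(mm$votes, mm$margin, object$classes))
}
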