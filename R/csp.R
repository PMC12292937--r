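# Common spatial patterns -------------------------------------------------
#
# CSP finds spatial filters that maximise the variance ratio between two
# classes. With normalised class covariances Ca and Cb, the filters solve
# the generalised eigenproblem of (Ca, Ca + Cb): whiten the composite
# covariance, eigendecompose the whitened Ca, and map the eigenvectors
# back. Eigenvalues then live in [0, 1] and pair up as la + lb = 1; the
# most discriminative filters sit at both ends of the eigenvalue ordering.

#' Normalised average class covariance
#'
#' Average over the trials of one class of `X X' / trace(X X')` (the
#' Ramoser normalisation, making the result insensitive to per-trial
#' gain).
#'
#' @param ts a [trialset()].
#' @param klass class label whose trials are averaged.
#' @return A symmetric positive semi-definite channels x channels matrix.
#' @export
class_covariance <- function(ts, klass) {
  stopifnot(inherits(ts, "trialset"))
  idx <- which(ts$labels == klass)
  if (!length(idx)) stop("no trials with label ", klass)
  C <- dim(ts$trials)[2L]
  acc <- matrix(0, C, C)
  for (i in idx) {
    X <- trial_matrix(ts, i)
    S <- tcrossprod(X)
    acc <- acc + S / sum(diag(S))
  }
  acc <- acc / length(idx)
  (acc + t(acc)) / 2
}

csp_from_covs <- function(covA, covB, channel_names = NULL) {
  C <- nrow(covA)
  comp <- covA + covB
  eg <- eigen(comp, symmetric = TRUE)
  vals <- eg$values
  if (min(vals) < 1e-8 * sum(diag(comp))) {
    warning("near-singular composite covariance: ridge-regularised")
    ridge <- 1e-8 * sum(diag(comp))
    comp <- comp + diag(ridge, C)
    eg <- eigen(comp, symmetric = TRUE)
    vals <- eg$values
  }
  Wh <- diag(1 / sqrt(vals), C) %*% t(eg$vectors)      # whitening of Ca+Cb
  S <- Wh %*% covA %*% t(Wh)
  S <- (S + t(S)) / 2
  eg2 <- eigen(S, symmetric = TRUE)                    # descending values
  P <- t(eg2$vectors) %*% Wh                           # rows are filters
  rownames(P) <- NULL
  if (!is.null(channel_names)) colnames(P) <- channel_names
  structure(list(P = P, eigenvalues = eg2$values, covA = covA, covB = covB,
                 channel_names = channel_names),
            class = "csp")
}

#' Fit a two-class common spatial pattern model
#'
#' @param ts a [trialset()] containing trials of both classes.
#' @param classA,classB the two class labels.
#' @return An object of class `csp` with components `P` (C x C spatial
#'   filter matrix, rows ordered by descending eigenvalue for `classA`
#'   vs `classB`), `eigenvalues` (in `[0, 1]`, descending) and the two
#'   class covariances.
#' @export
csp <- function(ts, classA, classB) {
  covA <- class_covariance(ts, classA)
  covB <- class_covariance(ts, classB)
  out <- csp_from_covs(covA, covB, ts$channel_names)
  out$classA <- classA; out$classB <- classB
  out
}

#' @export
print.csp <- function(x, ...) {
  cat(sprintf("<csp> %d filters", nrow(x$P)))
  if (!is.null(x$classA))
    cat(sprintf(" (class %s vs %s)", x$classA, x$classB))
  cat("\n  eigenvalues:",
      paste(sprintf("%.3f", utils::head(x$eigenvalues, 4)), collapse = " "),
      "...",
      paste(sprintf("%.3f", utils::tail(x$eigenvalues, 2)), collapse = " "),
      "\n")
  invisible(x)
}

#' Retain the top and bottom n rows of a CSP model
#'
#' The eigenvalue ordering concentrates class-discriminative variance at
#' both ends of the filter matrix, so dimensionality is reduced by keeping
#' the first `n` and last `n` rows (e.g. `n = 4` reduces a 22-row filter
#' matrix to 8 rows).
#'
#' @param model a [csp()] model.
#' @param n pairs to keep; requires `2 n <= C`.
#' @return A `csp` model with `2 n` rows.
#' @export
reduce_rows <- function(model, n) {
  stopifnot(inherits(model, "csp"))
  C <- nrow(model$P)
  if (2 * n > C) stop(sprintf("2n = %d exceeds the filter count C = %d",
                              2 * n, C))
  keep <- c(seq_len(n), seq.int(C - n + 1L, C))
  model$P <- model$P[keep, , drop = FALSE]
  model$eigenvalues <- model$eigenvalues[keep]
  model
}

#' Apply a binary weight gene to a spatial filter matrix
#'
#' The gene `w` (one 0/1 entry per filter row) selects which rows of `P`
#' contribute features: `WP = diag(w) P` with the zeroed rows dropped from
#' feature extraction.
#'
#' @param model a [csp()] model (or a bare filter matrix).
#' @param w binary vector of length `nrow(P)`.
#' @return For a `csp` model, the model restricted to the selected rows;
#'   for a matrix, the selected rows. An all-zero `w` is flagged with an
#'   error (degenerate; fitness handling assigns it chance level instead
#'   of evaluating it).
#' @export
apply_weight <- function(model, w) {
  P <- if (inherits(model, "csp")) model$P else as.matrix(model)
  if (length(w) != nrow(P))
    stop("weight gene length must equal the number of filter rows")
  if (!all(w %in% c(0, 1))) stop("weight gene must be binary")
  if (!any(w == 1)) stop("degenerate all-zero weight gene")
  keep <- which(w == 1)
  if (inherits(model, "csp")) {
    model$P <- P[keep, , drop = FALSE]
    model$eigenvalues <- model$eigenvalues[keep]
    model
  } else P[keep, , drop = FALSE]
}

#' Log-variance CSP features of a trial
#'
#' Projects a trial through the (possibly reduced) filter rows and returns
#' the log of each projected row's variance normalised by the summed
#' variance over the retained rows, so features are invariant to a global
#' per-trial gain and their exponentials sum to one.
#'
#' @param model a [csp()] model.
#' @param trial channels x samples matrix, or a [trialset()] (one feature
#'   row per trial).
#' @param n_pairs if not `NULL`, apply [reduce_rows()] first with this
#'   `n`.
#' @return A feature vector (or matrix with one row per trial) of length
#'   equal to the retained row count.
#' @export
csp_features <- function(model, trial, n_pairs = NULL) {
  stopifnot(inherits(model, "csp"))
  if (!is.null(n_pairs)) model <- reduce_rows(model, n_pairs)
  P <- model$P
  one <- function(X) {
    Z <- P %*% X
    v <- rowSums(Z * Z)
    v <- pmax(v, 1e-12)            # zero-variance floor
    log(v / sum(v))
  }
  if (inherits(trial, "trialset")) {
    n <- dim(trial$trials)[1L]
    out <- matrix(0, n, nrow(P))
    for (i in seq_len(n)) out[i, ] <- one(trial_matrix(trial, i))
    out
  } else one(as.matrix(trial))
}
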