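# Evaluation harness -------------------------------------------------------
#
# Stratified splitting and cross-validation tying the stages into the
# evaluation protocol: stratified 10-fold CV for the CSP family; a
# stratified 50/50 train/test split (with a 16% validation slice of the
# training part) for CNN runs. Fitted models record the trial indices
# they were trained on, and the benchmark asserts they are disjoint from
# each test fold (no test-set leakage).

#' Stratified fold assignment
#'
#' Shuffles each class separately and deals its trials round-robin over
#' the folds, so per-fold class proportions are within one trial of exact
#' stratification. Deterministic per seed.
#'
#' @param labels class label per trial.
#' @param n_folds number of folds; every class must have at least
#'   `n_folds` trials.
#' @param seed RNG seed.
#' @return A list of class `split_plan` with `folds` (list of test-index
#'   vectors partitioning `seq_along(labels)`), `assignment` (fold id per
#'   trial), `n_folds` and `seed`.
#' @export
stratified_folds <- function(labels, n_folds = 10, seed = 1) {
  cnt <- table(labels)
  if (any(cnt < n_folds))
    stop(sprintf("class %s has %d trial(s); need at least n_folds = %d",
                 names(cnt)[which.min(cnt)], min(cnt), n_folds))
  assignment <- integer(length(labels))
  with_seed(seed, {
    for (kl in sort(unique(labels))) {
      idx <- sample(which(labels == kl))
      assignment[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds <- lapply(seq_len(n_folds), function(f) which(assignment == f))
  structure(list(folds = folds, assignment = assignment,
                 n_folds = n_folds, seed = seed),
            class = "split_plan")
}

#' Stratified train/test split
#'
#' @param labels class label per trial.
#' @param train_fraction fraction of each class assigned to training.
#' @param seed RNG seed.
#' @return A list with `train` and `test` index vectors.
#' @export
stratified_split <- function(labels, train_fraction = 0.5, seed = 1) {
  train <- integer(0)
  with_seed(seed, {
    for (kl in unique(labels)) {
      idx <- sample(which(labels == kl))
      ntr <- round(length(idx) * train_fraction)
      train <- c(train, idx[seq_len(ntr)])
    }
  })
  list(train = sort(train),
       test = sort(setdiff(seq_along(labels), train)))
}

benchmark_fit <- function(method, train_ts, n_pairs, strategy, svm, ga) {
  switch(method,
         csp = csp_svm(train_ts, strategy = strategy, n_pairs = n_pairs,
                       svm = svm),
         wccsp = wccsp_svm(train_ts, ga = ga, svm = svm),
         fbcsp = sfbcsp(train_ts, banks = filter_banks("fbcsp"),
                        n_pairs = n_pairs, strategy = strategy, svm = svm),
         sfbcsp = sfbcsp(train_ts, banks = filter_banks("merged"),
                         n_pairs = n_pairs, strategy = strategy,
                         svm = svm),
         stop("unknown method: ", method))
}

#' Cross-validated benchmark of the CSP-family methods
#'
#' Runs each method over the folds of `plan`: per fold the method is
#' fitted on the complement and evaluated on the fold, recording accuracy
#' and Cohen's kappa. Any per-cell failure is recorded (NA metrics) and
#' the run continues. Fitting-time trial-index bookkeeping asserts that
#' no fitted model saw a test trial.
#'
#' @param ts a [trialset()].
#' @param methods subset of `c("csp", "wccsp", "fbcsp", "sfbcsp")`.
#' @param plan a [stratified_folds()] plan (default 10-fold, seed 1).
#' @param n_pairs CSP rows retained (top/bottom n).
#' @param strategy `"ovo"` or `"ovr"`.
#' @param svm an [svm_params()] object.
#' @param ga a [ga_params()] object (WC-CSP only); defaults to a reduced
#'   search budget suitable for cross-validation.
#' @return data.frame of class `mi_benchmark` with one row per method and
#'   fold (`method`, `fold`, `n_test`, `accuracy`, `kappa`, `error`), the
#'   per-cell confusion matrices in attribute `confusions`, and per-method
#'   means via [summary.mi_benchmark()].
#' @export
run_benchmark <- function(ts, methods = c("csp", "sfbcsp"),
                          plan = stratified_folds(ts$labels, 10, 1),
                          n_pairs = 4, strategy = "ovo",
                          svm = svm_params(),
                          ga = ga_params(population_size = 20,
                                         generations = 30)) {
  stopifnot(inherits(ts, "trialset"), inherits(plan, "split_plan"))
  rows <- list(); confs <- list()
  for (method in methods) {
    for (f in seq_along(plan$folds)) {
      test <- plan$folds[[f]]
      train <- setdiff(seq_along(ts$labels), test)
      cell <- tryCatch({
        model <- benchmark_fit(method, subset_trials(ts, train), n_pairs,
                               strategy, svm, ga)
        seen <- model$train_index
        if (length(intersect(seen, ts$trial_index[test])))
          stop("leakage: model fitted on test trials")
        pred <- predict(model, subset_trials(ts, test))
        met <- classification_metrics(ts$labels[test], pred,
                                      classes = sort(unique(ts$labels)))
        confs[[paste(method, f, sep = ".")]] <- met$confusion
        data.frame(method = method, fold = f, n_test = length(test),
                   accuracy = met$accuracy, kappa = met$kappa,
                   error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e)
        data.frame(method = method, fold = f, n_test = length(test),
                   accuracy = NA_real_, kappa = NA_real_,
                   error = conditionMessage(e), stringsAsFactors = FALSE))
      rows[[length(rows) + 1L]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "confusions") <- confs
  class(out) <- c("mi_benchmark", "data.frame")
  out
}

#' @export
summary.mi_benchmark <- function(object, ...) {
  agg <- stats::aggregate(cbind(accuracy, kappa) ~ method,
                          data = as.data.frame(object), FUN = mean,
                          na.action = stats::na.omit)
  sdv <- stats::aggregate(cbind(accuracy, kappa) ~ method,
                          data = as.data.frame(object), FUN = stats::sd,
                          na.action = stats::na.omit)
  names(agg)[2:3] <- c("mean_accuracy", "mean_kappa")
  agg$sd_accuracy <- sdv$accuracy
  agg$sd_kappa <- sdv$kappa
  agg
}

#' Write a benchmark table to JSON and CSV
#'
#' @param bench a [run_benchmark()] result.
#' @param path_prefix output files become `<prefix>.json` and
#'   `<prefix>.csv`.
#' @return The two paths, invisibly.
#' @export
write_benchmark <- function(bench, path_prefix) {
  df <- as.data.frame(bench)
  utils::write.csv(df, paste0(path_prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(cells = df, summary = summary(bench)),
                       paste0(path_prefix, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paste0(path_prefix, ".json"), paste0(path_prefix, ".csv")))
}
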