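test_that("stratified folds partition the trials with exact balance when divisible", {
  labels <- rep(1:4, each = 10)   # 40 trials, 10 folds -> 1 per class/fold
  plan <- stratified_folds(labels, 10, seed = 3)
  expect_length(plan$folds, 10L)
  for (f in plan$folds) {
    expect_length(f, 4L)
    expect_identical(sort(labels[f]), 1:4)
  }
  all_idx <- sort(unlist(plan$folds))
  expect_identical(all_idx, 1:40)
  expect_identical(anyDuplicated(unlist(plan$folds)), 0L)

  expect_identical(stratified_folds(labels, 10, seed = 3)$assignment,
                   plan$assignment)
  expect_error(stratified_folds(rep(1:4, each = 3), 10), "at least")
})

test_that("near-divisible stratification stays within one trial per class", {
  withr::with_seed(1, labels <- sample(rep(1:4, times = c(11, 13, 10, 9))))
  plan <- stratified_folds(labels, 5, seed = 2)
  for (kl in 1:4) {
    per_fold <- vapply(plan$folds, function(f) sum(labels[f] == kl), 0L)
    expect_lte(diff(range(per_fold)), 1L)
  }
})

test_that("stratified splits respect the class proportions", {
  labels <- rep(1:4, each = 20)
  sp <- stratified_split(labels, 0.5, seed = 4)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_true(all(table(labels[sp$train]) == 10L))
})

test_that("the benchmark table reports per-fold metrics with recomputable kappa", {
  ts <- synth_trials(synth_params(n_channels = 16, trials_per_class = 10,
                                  snr = 2, seed = 12))$trialset
  plan <- stratified_folds(ts$labels, 4, seed = 1)
  bench <- run_benchmark(ts, methods = c("csp", "sfbcsp"), plan = plan)
  expect_identical(nrow(bench), 8L)
  expect_true(all(is.na(bench$error)))
  confs <- attr(bench, "confusions")
  for (i in seq_len(nrow(bench))) {
    key <- paste(bench$method[i], bench$fold[i], sep = ".")
    expect_equal(cohen_kappa(confs[[key]]), bench$kappa[i])
    cm <- confs[[key]]
    expect_equal(sum(diag(cm)) / sum(cm), bench$accuracy[i])
  }
  s <- summary(bench)
  expect_identical(sort(s$method), c("csp", "sfbcsp"))
  # the banded method holds its ground against plain CSP
  expect_gte(s$mean_accuracy[s$method == "sfbcsp"],
             s$mean_accuracy[s$method == "csp"] - 0.05)
})

test_that("single method and fold produce a one-row table; failures are recorded", {
  ts <- fixture_var_trialset(rbind(c(4, 1, 1, 1), c(1, 1, 1, 4)),
                             trials_per_class = 10)
  plan <- list(folds = list(c(1:2, 11:12)), assignment = NULL,
               n_folds = 1, seed = 1)
  class(plan) <- "split_plan"
  bench <- run_benchmark(ts, methods = "csp", plan = plan, n_pairs = 2)
  expect_identical(nrow(bench), 1L)

  bad <- run_benchmark(ts, methods = "nosuchmethod", plan = plan)
  expect_false(is.na(bad$error[1]))
  expect_true(is.na(bad$accuracy[1]))
})

test_that("fitted models record their training trials and never see the test fold", {
  ts <- fixture_var_trialset(rbind(c(4, 1, 1, 1), c(1, 1, 1, 4)),
                             trials_per_class = 8)
  sp <- stratified_split(ts$labels, 0.5, seed = 5)
  m <- csp_svm(subset_trials(ts, sp$train), n_pairs = 2)
  expect_identical(sort(m$train_index), sort(sp$train))
  expect_length(intersect(m$train_index, sp$test), 0L)
  mb <- sfbcsp(subset_trials(ts, sp$train),
               banks = filter_banks("sliding"), n_pairs = 2)
  expect_identical(sort(mb$train_index), sort(sp$train))
})

test_that("benchmark outputs serialise to JSON and CSV", {
  ts <- fixture_var_trialset(rbind(c(4, 1, 1, 1), c(1, 1, 1, 4)),
                             trials_per_class = 10)
  plan <- stratified_folds(ts$labels, 2, seed = 1)
  bench <- run_benchmark(ts, methods = "csp", plan = plan, n_pairs = 2)
  prefix <- file.path(withr::local_tempdir(), "bench")
  write_benchmark(bench, prefix)
  expect_true(file.exists(paste0(prefix, ".csv")))
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_length(js$cells, nrow(bench))
})
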