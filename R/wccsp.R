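# Weighted-criterion CSP (GA row selection) --------------------------------
#
# A binary gene w in {0,1}^C selects which rows of the CSP filter matrix P
# contribute features (WP = diag(w) P). A genetic algorithm searches the
# gene space, scoring each gene by the mean 5-fold cross-validated
# accuracy of an RBF SVM on the selected log-variance features. The full
# P is computed once from the training set; only the row selection
# evolves.

#' Genetic-algorithm parameters for WC-CSP
#'
#' Defaults are population 50, 200 generations, crossover rate 0.5 and
#' mutation rate 0.06; selection is size-2 tournament with elitism of 1
#' and single-point crossover.
#'
#' @param population_size individuals per generation.
#' @param generations number of generations.
#' @param crossover_rate probability that a selected pair recombines.
#' @param mutation_rate per-bit flip probability.
#' @param seed RNG seed controlling initialisation, selection, crossover,
#'   mutation and the cross-validation folds.
#' @return A list of class `ga_params`.
#' @export
ga_params <- function(population_size = 50, generations = 200,
                      crossover_rate = 0.5, mutation_rate = 0.06,
                      seed = 1) {
  stopifnot(population_size >= 2, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "ga_params")
}

#' Cross-validated SVM fitness of a weight gene
#'
#' Mean k-fold accuracy of an RBF SVM trained on the CSP features of the
#' rows selected by `gene`. The all-zero gene is not evaluated: it is
#' assigned chance level (`1 / n_classes`).
#'
#' @param model a fitted [csp()] model (full C x C filter matrix).
#' @param ts the binary-labelled [trialset()] the model was fitted on.
#' @param gene binary vector of length C.
#' @param folds list of test-index vectors partitioning the trials (as
#'   from [stratified_folds()]); fixed across genes so fitnesses are
#'   comparable.
#' @param svm an [svm_params()] object.
#' @return Mean cross-validated accuracy in `[0, 1]`.
#' @export
gene_fitness <- function(model, ts, gene, folds, svm = svm_params()) {
  classes <- sort(unique(ts$labels))
  if (!any(gene == 1)) return(1 / length(classes))
  feats <- csp_features(apply_weight(model, gene), ts)
  y <- factor(ts$labels, levels = classes)
  acc <- vapply(folds, function(test) {
    fit <- svm_fit(feats[-test, , drop = FALSE], y[-test], svm)
    mean(stats::predict(fit, feats[test, , drop = FALSE]) == y[test])
  }, 0)
  mean(acc)
}

#' Fit WC-CSP: GA-optimised row selection for a binary CSP model
#'
#' @param ts a [trialset()] containing the two classes.
#' @param classA,classB the binary task's class labels.
#' @param ga a [ga_params()] object.
#' @param svm an [svm_params()] object (fitness classifier).
#' @param n_folds folds for the fitness cross-validation (default 5).
#' @return An object of class `wccsp`: the full `csp` model, `best_gene`,
#'   `best_fitness`, and `trace` (per-generation mean and best fitness).
#'   Deterministic given `ga$seed`.
#' @export
wccsp <- function(ts, classA, classB, ga = ga_params(),
                  svm = svm_params(), n_folds = 5) {
  stopifnot(inherits(ts, "trialset"))
  idx <- which(ts$labels %in% c(classA, classB))
  sub <- subset_trials(ts, idx)
  model <- csp(sub, classA, classB)
  C <- nrow(model$P)

  with_seed(ga$seed, {
    plan <- stratified_folds(sub$labels, n_folds,
                             seed = sample.int(.Machine$integer.max, 1))
    folds <- plan$folds
    cache <- new.env(parent = emptyenv())
    fit_of <- function(g) {
      key <- paste(g, collapse = "")
      if (is.null(cache[[key]]))
        cache[[key]] <- gene_fitness(model, sub, g, folds, svm)
      cache[[key]]
    }

    pop <- matrix(sample(0:1, ga$population_size * C, replace = TRUE),
                  ga$population_size, C)
    trace <- data.frame(generation = integer(0), mean_fitness = numeric(0),
                        best_fitness = numeric(0))
    best_gene <- NULL; best_fit <- -Inf
    for (gen in seq_len(ga$generations)) {
      fits <- apply(pop, 1L, fit_of)
      gb <- which.max(fits)
      if (fits[gb] > best_fit) { best_fit <- fits[gb]; best_gene <- pop[gb, ] }
      trace <- rbind(trace,
                     data.frame(generation = gen, mean_fitness = mean(fits),
                                best_fitness = max(fits)))
      if (gen == ga$generations) break
      newpop <- matrix(0L, ga$population_size, C)
      newpop[1L, ] <- pop[gb, ]                     # elitism of 1
      tournament <- function() {
        cand <- sample.int(ga$population_size, 2L)
        cand[which.max(fits[cand])]
      }
      r <- 2L
      while (r <= ga$population_size) {
        p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
        if (stats::runif(1) < ga$crossover_rate && C > 1L) {
          cut <- sample.int(C - 1L, 1L)
          c1 <- c(p1[seq_len(cut)], p2[(cut + 1L):C])
          c2 <- c(p2[seq_len(cut)], p1[(cut + 1L):C])
        } else { c1 <- p1; c2 <- p2 }
        for (ch in list(c1, c2)) {
          if (r > ga$population_size) break
          flip <- stats::runif(C) < ga$mutation_rate
          ch[flip] <- 1L - ch[flip]
          newpop[r, ] <- ch
          r <- r + 1L
        }
      }
      pop <- newpop
    }
  })

  structure(list(model = model, best_gene = best_gene,
                 best_fitness = best_fit, trace = trace,
                 classA = classA, classB = classB, ga = ga, svm = svm,
                 train_index = sub$trial_index),
            class = "wccsp")
}

#' @export
print.wccsp <- function(x, ...) {
  cat(sprintf("<wccsp> class %s vs %s: best fitness %.3f, gene keeps %d/%d rows\n",
              x$classA, x$classB, x$best_fitness, sum(x$best_gene),
              length(x$best_gene)))
  invisible(x)
}

#' Fit a multi-class CSP + SVM classifier with GA-selected rows
#'
#' One-vs-one wrapper in which each pairwise CSP model's rows are chosen
#' by the WC-CSP genetic algorithm instead of the fixed top/bottom-n
#' reduction.
#'
#' @inheritParams csp_svm
#' @param ga a [ga_params()] object, used for every class pair.
#' @return A `csp_svm` object whose pairwise models carry GA genes.
#' @export
wccsp_svm <- function(ts, ga = ga_params(), svm = svm_params()) {
  classes <- sort(unique(ts$labels))
  models <- list()
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    if (i >= j) next
    a <- classes[i]; b <- classes[j]
    w <- wccsp(ts, a, b, ga = ga, svm = svm)
    models[[paste(a, b, sep = "v")]] <-
      fit_pair_csp_svm(ts, a, b, n_pairs = NULL, svm, gene = w$best_gene)
  }
  structure(list(models = models, strategy = "ovo", classes = classes,
                 n_pairs = NA, svm = svm, train_index = ts$trial_index),
            class = "csp_svm")
}
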