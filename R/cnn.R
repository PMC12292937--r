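# Dual-branch 3D EEG CNN ---------------------------------------------------
#
# Each branch processes a (W, W, T) topographic tensor (T = time samples
# or PSD bins, treated as the channel axis of 2D convolutions over the
# W x W plane):
#   layer 1: depthwise conv, kernel (W, 1), 'same' padding, stride 1 —
#            each kernel spans one column's full extent, so it is
#            influenced only by individual columns; ELU; dropout 0.25.
#   layer 2: depthwise conv (3, 6) + pointwise expansion to 36 channels;
#            batch-norm; ELU; dropout 0.25; average pool (3, 6).
#   layer 3: depthwise conv (2, 3) + pointwise expansion to 72 channels;
#            batch-norm; ELU; average pool (2, 4).
# The second branch receives the 90-degree-rotated tensor, supplying the
# orthogonal spatial sweep. Flattened branch outputs are concatenated and
# classified by a 256-unit dense layer and a softmax head. Training uses
# Adam with cross-entropy loss.

branch_spec <- function(W, Tn, dropout) {
  list(
    list(type = "dwconv", kh = W, kw = 1L, C = Tn, name = "layer1-depthwise"),
    list(type = "elu"),
    list(type = "dropout", p = dropout),
    list(type = "dwconv", kh = 3L, kw = 6L, C = Tn, name = "layer2-depthwise"),
    list(type = "pwconv", cin = Tn, cout = 36L, name = "layer2-pointwise"),
    list(type = "bn", C = 36L),
    list(type = "elu"),
    list(type = "dropout", p = dropout),
    list(type = "avgpool", ph = 3L, pw = 6L, name = "layer2-pool"),
    list(type = "dwconv", kh = 2L, kw = 3L, C = 36L, name = "layer3-depthwise"),
    list(type = "pwconv", cin = 36L, cout = 72L, name = "layer3-pointwise"),
    list(type = "bn", C = 72L),
    list(type = "elu"),
    list(type = "avgpool", ph = 2L, pw = 4L, name = "layer3-pool"),
    list(type = "flatten"))
}

# propagate (H, W, C) through a branch, erroring with the layer name on
# an impossible shape
propagate_shape <- function(spec, H, Wd, C) {
  for (ly in spec) {
    nm <- if (!is.null(ly$name)) ly$name else ly$type
    if (ly$type == "dwconv") {
      if (ly$C != C)
        stop(sprintf("%s: expects %d channels, got %d", nm, ly$C, C))
    } else if (ly$type == "pwconv") {
      if (ly$cin != C)
        stop(sprintf("%s: expects %d channels, got %d", nm, ly$cin, C))
      C <- ly$cout
    } else if (ly$type == "avgpool") {
      H <- as.integer(ceiling(H / ly$ph)); Wd <- as.integer(ceiling(Wd / ly$pw))
      if (H < 1 || Wd < 1)
        stop(sprintf("%s: empty feature map (%d x %d)", nm, H, Wd))
    } else if (ly$type == "flatten") {
      return(H * Wd * C)
    }
  }
  H * Wd * C
}

init_layer <- function(ly) {
  he <- function(fan_in) sqrt(2 / fan_in)
  if (ly$type == "dwconv") {
    ly$params <- list(K = array(stats::rnorm(ly$kh * ly$kw * ly$C,
                                             sd = he(ly$kh * ly$kw)),
                                c(ly$kh, ly$kw, ly$C)),
                      b = numeric(ly$C))
  } else if (ly$type == "pwconv") {
    ly$params <- list(W = matrix(stats::rnorm(ly$cin * ly$cout,
                                              sd = he(ly$cin)),
                                 ly$cin, ly$cout),
                      b = numeric(ly$cout))
  } else if (ly$type == "bn") {
    ly$params <- list(gamma = rep(1, ly$C), beta = numeric(ly$C))
    ly$run_mean <- numeric(ly$C)
    ly$run_var <- rep(1, ly$C)
  } else if (ly$type == "dense") {
    ly$params <- list(W = matrix(stats::rnorm(ly$nin * ly$nout,
                                              sd = he(ly$nin)),
                                 ly$nin, ly$nout),
                      b = numeric(ly$nout))
  }
  ly
}

layer_fwd <- function(ly, x, train) {
  switch(ly$type,
    dwconv = {
      r <- dwconv_fwd(ly$params$K, ly$params$b, x)
      list(y = r$y, cache = list(xp = r$xp, x_shape = dim(x)))
    },
    pwconv = {
      r <- pwconv_fwd(ly$params$W, ly$params$b, x)
      list(y = r$y, cache = list(xm = r$xm, x_shape = dim(x)))
    },
    bn = {
      r <- bn_fwd(ly$params$gamma, ly$params$beta, x, train,
                  ly$run_mean, ly$run_var)
      list(y = r$y, cache = list(xhat = r$xhat, invstd = r$invstd,
                                 x_shape = dim(x),
                                 batch_mean = r$batch_mean,
                                 batch_var = r$batch_var))
    },
    elu = { y <- elu_fwd(x); list(y = y, cache = list(y = y)) },
    dropout = {
      if (train && ly$p > 0) {
        mask <- (stats::runif(length(x)) >= ly$p) / (1 - ly$p)
        list(y = x * mask, cache = list(mask = mask))
      } else list(y = x, cache = list(mask = NULL))
    },
    avgpool = list(y = avgpool_fwd(x, ly$ph, ly$pw),
                   cache = list(x_shape = dim(x))),
    flatten = {
      d <- dim(x)
      list(y = matrix(x, d[1L]), cache = list(x_shape = d))
    },
    dense = {
      r <- dense_fwd(ly$params$W, ly$params$b, x)
      y <- if (isTRUE(ly$activation == "elu")) elu_fwd(r$y) else r$y
      list(y = y, cache = list(x = r$x, y = y))
    },
    stop("unknown layer type: ", ly$type))
}

layer_bwd <- function(ly, cache, dy) {
  switch(ly$type,
    dwconv = {
      r <- dwconv_bwd(ly$params$K, cache$x_shape, cache$xp, dy)
      list(dx = r$dx, grads = list(K = r$dK, b = r$db))
    },
    pwconv = {
      r <- pwconv_bwd(ly$params$W, cache$x_shape, cache$xm, dy)
      list(dx = r$dx, grads = list(W = r$dW, b = r$db))
    },
    bn = {
      r <- bn_bwd(ly$params$gamma, cache$x_shape, cache$xhat, cache$invstd,
                  dy)
      list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
    },
    elu = list(dx = elu_bwd(cache$y, dy), grads = NULL),
    dropout = list(dx = if (is.null(cache$mask)) dy else dy * cache$mask,
                   grads = NULL),
    avgpool = list(dx = avgpool_bwd(cache$x_shape, ly$ph, ly$pw, dy),
                   grads = NULL),
    flatten = list(dx = array(dy, cache$x_shape), grads = NULL),
    dense = {
      if (isTRUE(ly$activation == "elu")) dy <- elu_bwd(cache$y, dy)
      r <- dense_bwd(ly$params$W, cache$x, dy)
      list(dx = r$dx, grads = list(W = r$dW, b = r$db))
    })
}

net_fwd <- function(layers, x, train) {
  caches <- vector("list", length(layers))
  bn_stats <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fwd(layers[[i]], x, train)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

net_bwd <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_bwd(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grads)   # keep NULL slots (no trainable params)
  }
  list(dx = dy, grads = grads)
}

#' Configure the 3D EEG CNN
#'
#' Validates that the architecture's kernels, pools and dense head are
#' shape-consistent for a `(W, W, T)` input, erroring with the offending
#' layer's name otherwise.
#'
#' @param W spatial side length of the topographic grid.
#' @param T_len channel-axis length (time samples or PSD bins).
#' @param n_classes output classes (default 4).
#' @param dual_branch add the 90-degree-rotated second branch
#'   (default TRUE).
#' @param dropout dropout rate of layers 1-2 (default 0.25).
#' @param dense_units width of the fully connected layer (default 256).
#' @return A list of class `cnn_config` including the propagated
#'   per-branch flattened feature length `flat`.
#' @export
cnn_config <- function(W, T_len, n_classes = 4, dual_branch = TRUE,
                       dropout = 0.25, dense_units = 256) {
  if (W < 1 || T_len < 1) stop("input: W and T must be positive")
  if (n_classes < 2) stop("softmax head: need at least 2 classes")
  spec <- branch_spec(as.integer(W), as.integer(T_len), dropout)
  flat <- propagate_shape(spec, as.integer(W), as.integer(W),
                          as.integer(T_len))
  structure(list(W = as.integer(W), T_len = as.integer(T_len),
                 n_classes = as.integer(n_classes),
                 dual_branch = isTRUE(dual_branch), dropout = dropout,
                 dense_units = as.integer(dense_units), flat = flat),
            class = "cnn_config")
}

#' Build an (untrained) 3D EEG CNN
#'
#' @param cfg a [cnn_config()].
#' @param seed RNG seed for weight initialisation.
#' @return An object of class `cnn3deeg` (untrained; see [cnn3deeg()] for
#'   the one-call fit).
#' @export
build_cnn <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "cnn_config"))
  nb <- if (cfg$dual_branch) 2L else 1L
  model <- with_seed(seed, {
    branches <- lapply(seq_len(nb), function(i)
      lapply(branch_spec(cfg$W, cfg$T_len, cfg$dropout), init_layer))
    head <- list(
      init_layer(list(type = "dense", nin = nb * cfg$flat,
                      nout = cfg$dense_units, activation = "elu")),
      init_layer(list(type = "dense", nin = cfg$dense_units,
                      nout = cfg$n_classes, activation = "linear")))
    list(branches = branches, head = head)
  })
  structure(list(branches = model$branches, head = model$head, cfg = cfg,
                 classes = seq_len(cfg$n_classes), trained = FALSE,
                 traces = NULL, seed = seed),
            class = "cnn3deeg")
}

#' @export
print.cnn3deeg <- function(x, ...) {
  cat(sprintf("<cnn3deeg> %s-branch, input (%d,%d,%d), %d classes, %d parameters%s\n",
              if (x$cfg$dual_branch) "dual" else "single",
              x$cfg$W, x$cfg$W, x$cfg$T_len, x$cfg$n_classes,
              count_params(x), if (x$trained) " (trained)" else ""))
  invisible(x)
}

#' Count trainable parameters of a model, per part
#'
#' @param model a `cnn3deeg` model.
#' @param by_part return a breakdown (`branches`, `head`) instead of the
#'   total.
#' @return Total parameter count, or a named list.
#' @export
count_params <- function(model, by_part = FALSE) {
  cnt <- function(layers)
    sum(vapply(layers, function(ly)
      if (is.null(ly$params)) 0L else length(unlist(ly$params)), 0L))
  branches <- vapply(model$branches, cnt, 0L)
  head <- cnt(model$head)
  if (by_part) list(branches = branches, head = head)
  else sum(branches) + head
}

# forward through branches + head; x list of per-branch input arrays
model_fwd <- function(model, xs, train) {
  br <- lapply(seq_along(model$branches), function(i)
    net_fwd(model$branches[[i]], xs[[i]], train))
  feat <- do.call(cbind, lapply(br, `[[`, "y"))
  hd <- net_fwd(model$head, feat, train)
  list(z = hd$y, branch_caches = lapply(br, `[[`, "caches"),
       head_cache = hd$caches, feat_dims = vapply(br, function(b)
         ncol(b$y), 0L))
}

# prepare per-branch inputs from an (n, W, W, T) tensor array
branch_inputs <- function(model, x) {
  if (length(dim(x)) != 4L)
    stop("expected an n x W x W x T tensor array")
  if (!model$cfg$dual_branch) return(list(x))
  xr <- array(0, dim(x))
  for (i in seq_len(dim(x)[1L]))
    xr[i, , , ] <- rotate90(array(x[i, , , ], dim(x)[2:4]))
  list(x, xr)
}

adam_step <- function(model, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  upd_layers <- function(layers, glist, skey) {
    for (i in seq_along(layers)) {
      g <- glist[[i]]
      if (is.null(g)) next
      for (nm in names(g)) {
        key <- paste(skey, i, nm, sep = ".")
        if (is.null(state$m[[key]])) {
          state$m[[key]] <- g[[nm]] * 0
          state$v[[key]] <- g[[nm]] * 0
        }
        state$m[[key]] <- b1 * state$m[[key]] + (1 - b1) * g[[nm]]
        state$v[[key]] <- b2 * state$v[[key]] + (1 - b2) * g[[nm]]^2
        mh <- state$m[[key]] / (1 - b1^t)
        vh <- state$v[[key]] / (1 - b2^t)
        layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
          lr * mh / (sqrt(vh) + eps)
      }
    }
    layers
  }
  for (bi in seq_along(model$branches))
    model$branches[[bi]] <- upd_layers(model$branches[[bi]],
                                       grads$branches[[bi]],
                                       paste0("b", bi))
  model$head <- upd_layers(model$head, grads$head, "h")
  list(model = model, state = state)
}

# update batch-norm running statistics from the caches of one forward
# pass (momentum 0.9)
bn_update <- function(layers, caches, momentum = 0.9) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "bn") {
      layers[[i]]$run_mean <- momentum * layers[[i]]$run_mean +
        (1 - momentum) * caches[[i]]$batch_mean
      layers[[i]]$run_var <- momentum * layers[[i]]$run_var +
        (1 - momentum) * caches[[i]]$batch_var
    }
  }
  layers
}

#' Train a 3D EEG CNN
#'
#' Adam with cross-entropy loss; a stratified validation slice
#' (default 16%) of the training data monitors convergence. Seeding
#' covers weight initialisation, the validation split, shuffling and
#' dropout, so runs are deterministic given the seed (single-threaded).
#'
#' @param model a [build_cnn()] model.
#' @param x `n x W x W x T` tensor array (see [tensor_set()]) or a
#'   `tensor_set` list.
#' @param y class labels, one per trial.
#' @param epochs training epochs (default 200; convergence plots in
#'   longer regimes up to 360 are equally supported).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size minibatch size (default 16).
#' @param validation fraction of the training data held out for
#'   monitoring (default 0.16; 0 disables).
#' @param seed RNG seed.
#' @param verbose print per-epoch progress every `verbose` epochs
#'   (0 = silent).
#' @return The trained `cnn3deeg`, with `traces` (per-epoch train/val
#'   loss and accuracy).
#' @export
train_cnn <- function(model, x, y, epochs = 200, lr = 1e-3,
                      batch_size = 16, validation = 0.16, seed = 1,
                      verbose = 0) {
  stopifnot(inherits(model, "cnn3deeg"))
  if (is.list(x) && !is.null(x$tensors)) { y <- x$labels; x <- x$tensors }
  classes <- sort(unique(y))
  if (length(classes) > model$cfg$n_classes)
    stop("more classes than the model's softmax width")
  model$classes <- classes
  yi <- match(y, classes)

  with_seed(seed, {
    n <- dim(x)[1L]
    if (validation > 0) {
      sp <- stratified_split(yi, 1 - validation,
                             seed = sample.int(.Machine$integer.max, 1))
      tr_idx <- sp$train; va_idx <- sp$test
    } else { tr_idx <- seq_len(n); va_idx <- integer(0) }
    xs_all <- branch_inputs(model, x)
    onehot <- diag(length(classes))[yi, , drop = FALSE]
    if (length(classes) < model$cfg$n_classes)
      onehot <- cbind(onehot, matrix(0, n, model$cfg$n_classes -
                                       length(classes)))
    state <- list(m = list(), v = list())
    traces <- data.frame(epoch = integer(0), train_loss = numeric(0),
                         train_accuracy = numeric(0),
                         val_loss = numeric(0), val_accuracy = numeric(0))
    tstep <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_hit <- 0L
      for (start in seq(1L, length(ord), by = batch_size)) {
        bidx <- ord[start:min(start + batch_size - 1L, length(ord))]
        xs <- lapply(xs_all, function(a) a[bidx, , , , drop = FALSE])
        fw <- model_fwd(model, xs, train = TRUE)
        probs <- softmax_rows(fw$z)
        tgt <- onehot[bidx, , drop = FALSE]
        loss <- -mean(log(pmax(rowSums(probs * tgt), 1e-12)))
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at epoch %d (diverged; try a lower learning rate)",
                       ep))
        ep_loss <- ep_loss + loss * length(bidx)
        ep_hit <- ep_hit + sum(max.col(probs) == max.col(tgt))
        dz <- (probs - tgt) / nrow(probs)
        hb <- net_bwd(model$head, fw$head_cache, dz)
        grads <- list(branches = vector("list", length(model$branches)),
                      head = hb$grads)
        off <- 0L
        for (bi in seq_along(model$branches)) {
          cols <- off + seq_len(fw$feat_dims[bi]); off <- off + fw$feat_dims[bi]
          bb <- net_bwd(model$branches[[bi]], fw$branch_caches[[bi]],
                        hb$dx[, cols, drop = FALSE])
          grads$branches[[bi]] <- bb$grads
          model$branches[[bi]] <- bn_update(model$branches[[bi]],
                                            fw$branch_caches[[bi]])
        }
        tstep <- tstep + 1L
        st <- adam_step(model, grads, state, lr, tstep)
        model <- st$model; state <- st$state
      }
      tr_loss <- ep_loss / length(tr_idx)
      tr_acc <- ep_hit / length(tr_idx)
      va_loss <- NA_real_; va_acc <- NA_real_
      if (length(va_idx)) {
        xs <- lapply(xs_all, function(a) a[va_idx, , , , drop = FALSE])
        fw <- model_fwd(model, xs, train = FALSE)
        probs <- softmax_rows(fw$z)
        tgt <- onehot[va_idx, , drop = FALSE]
        va_loss <- -mean(log(pmax(rowSums(probs * tgt), 1e-12)))
        va_acc <- mean(max.col(probs) == max.col(tgt))
      }
      traces <- rbind(traces,
                      data.frame(epoch = ep, train_loss = tr_loss,
                                 train_accuracy = tr_acc,
                                 val_loss = va_loss, val_accuracy = va_acc))
      if (verbose > 0 && ep %% verbose == 0)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  val %.3f", ep,
                        tr_loss, tr_acc, va_acc))
    }
    model$traces <- traces
  })
  model$trained <- TRUE
  model
}

#' Fit the 3D EEG CNN in one call
#'
#' Convenience wrapper: configure, build and train on an
#' `n x W x W x T` tensor array (or [tensor_set()] list).
#'
#' @inheritParams train_cnn
#' @param dual_branch,dropout,dense_units passed to [cnn_config()].
#' @return A trained `cnn3deeg`.
#' @export
cnn3deeg <- function(x, y = NULL, dual_branch = TRUE, epochs = 200,
                     lr = 1e-3, batch_size = 16, validation = 0.16,
                     dropout = 0.25, dense_units = 256, seed = 1,
                     verbose = 0) {
  if (is.list(x) && !is.null(x$tensors)) { y <- x$labels; x <- x$tensors }
  d <- dim(x)
  cfg <- cnn_config(d[2L], d[4L], n_classes = length(sort(unique(y))),
                    dual_branch = dual_branch, dropout = dropout,
                    dense_units = dense_units)
  model <- build_cnn(cfg, seed = seed)
  train_cnn(model, x, y, epochs = epochs, lr = lr,
            batch_size = batch_size, validation = validation, seed = seed,
            verbose = verbose)
}

#' Predict with a 3D EEG CNN
#'
#' @param object a `cnn3deeg` model.
#' @param newdata `n x W x W x T` tensor array or [tensor_set()] list.
#' @param type `"class"` (default) or `"prob"` (softmax matrix, rows sum
#'   to 1).
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return Predicted labels or the probability matrix.
#' @export
predict.cnn3deeg <- function(object, newdata, type = c("class", "prob"),
                             batch_size = 32, ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.null(newdata$tensors))
    newdata <- newdata$tensors
  if (length(dim(newdata)) == 3L)
    newdata <- array(newdata, c(1L, dim(newdata)))
  xs_all <- branch_inputs(object, newdata)
  n <- dim(newdata)[1L]
  probs <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    bidx <- start:min(start + batch_size - 1L, n)
    xs <- lapply(xs_all, function(a) a[bidx, , , , drop = FALSE])
    fw <- model_fwd(object, xs, train = FALSE)
    probs <- rbind(probs, softmax_rows(fw$z))
  }
  if (type == "prob") return(probs)
  object$classes[max.col(probs[, seq_along(object$classes), drop = FALSE])]
}

#' Evaluate a trained CNN on a labelled test set
#'
#' @param model a trained `cnn3deeg`.
#' @param x test tensors (`n x W x W x T` array or [tensor_set()] list).
#' @param y test labels (taken from the tensor_set if omitted).
#' @return A [classification_metrics()] object (accuracy, Cohen's kappa,
#'   confusion counts).
#' @export
evaluate_cnn <- function(model, x, y = NULL) {
  if (is.list(x) && !is.null(x$tensors)) { y <- x$labels; x <- x$tensors }
  if (!length(y)) stop("empty test set")
  pred <- predict(model, x)
  classification_metrics(y, pred, classes = model$classes)
}
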