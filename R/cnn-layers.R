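# Neural-network primitives ------------------------------------------------
#
# Minimal batched layer operations for the 3D EEG CNN. Activations are
# (batch, H, W, C) arrays with the tensor's T axis as the channel axis C
# of 2D convolutions over the spatial plane. All convolutions use 'same'
# zero padding (asymmetric for even kernels: floor((k-1)/2) before,
# ceil((k-1)/2) after) and stride 1. Average pooling tiles the plane with
# non-overlapping windows and averages partial edge windows over the
# cells they actually cover (ceil-division output size), which keeps the
# published pool sizes shape-consistent on small feature maps.

rep_ch <- function(v, B, H, W) rep(v, each = B * H * W)

dwconv_fwd <- function(K, bias, x) {
  d <- dim(x); B <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  kh <- dim(K)[1]; kw <- dim(K)[2]
  pt <- (kh - 1L) %/% 2L; pl <- (kw - 1L) %/% 2L
  xp <- array(0, c(B, H + kh - 1L, Wd + kw - 1L, C))
  xp[, pt + seq_len(H), pl + seq_len(Wd), ] <- x
  y <- array(rep_ch(bias, B, H, Wd), d)
  for (u in seq_len(kh)) for (v in seq_len(kw)) {
    slab <- xp[, u:(u + H - 1L), v:(v + Wd - 1L), , drop = FALSE]
    y <- y + slab * rep_ch(K[u, v, ], B, H, Wd)
  }
  list(y = y, xp = xp)
}

dwconv_bwd <- function(K, x_shape, xp, dy) {
  B <- x_shape[1]; H <- x_shape[2]; Wd <- x_shape[3]; C <- x_shape[4]
  kh <- dim(K)[1]; kw <- dim(K)[2]
  pt <- (kh - 1L) %/% 2L; pl <- (kw - 1L) %/% 2L
  dK <- array(0, dim(K))
  dxp <- array(0, dim(xp))
  dym <- matrix(dy, ncol = C)
  db <- colSums(dym)
  for (u in seq_len(kh)) for (v in seq_len(kw)) {
    slab <- xp[, u:(u + H - 1L), v:(v + Wd - 1L), , drop = FALSE]
    dK[u, v, ] <- colSums(matrix(dy * slab, ncol = C))
    dxp[, u:(u + H - 1L), v:(v + Wd - 1L), ] <-
      dxp[, u:(u + H - 1L), v:(v + Wd - 1L), ] +
      dy * rep_ch(K[u, v, ], B, H, Wd)
  }
  dx <- dxp[, pt + seq_len(H), pl + seq_len(Wd), , drop = FALSE]
  list(dx = dx, dK = dK, db = db)
}

pwconv_fwd <- function(Wm, bias, x) {
  d <- dim(x)
  xm <- matrix(x, ncol = d[4])
  ym <- xm %*% Wm
  ym <- sweep(ym, 2L, bias, "+")
  list(y = array(ym, c(d[1:3], ncol(Wm))), xm = xm)
}

pwconv_bwd <- function(Wm, x_shape, xm, dy) {
  cout <- ncol(Wm)
  dym <- matrix(dy, ncol = cout)
  list(dx = array(dym %*% t(Wm), x_shape),
       dW = crossprod(xm, dym), db = colSums(dym))
}

elu_fwd <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_bwd <- function(y, dy) dy * ifelse(y > 0, 1, y + 1)

avgpool_fwd <- function(x, ph, pw) {
  d <- dim(x); B <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  Ho <- as.integer(ceiling(H / ph)); Wo <- as.integer(ceiling(Wd / pw))
  y <- array(0, c(B, Ho, Wo, C))
  for (oi in seq_len(Ho)) for (oj in seq_len(Wo)) {
    ri <- ((oi - 1L) * ph + 1L):min(oi * ph, H)
    rj <- ((oj - 1L) * pw + 1L):min(oj * pw, Wd)
    slab <- x[, ri, rj, , drop = FALSE]
    y[, oi, oj, ] <- apply(slab, c(1L, 4L), sum) / (length(ri) * length(rj))
  }
  y
}

avgpool_bwd <- function(x_shape, ph, pw, dy) {
  B <- x_shape[1]; H <- x_shape[2]; Wd <- x_shape[3]; C <- x_shape[4]
  Ho <- dim(dy)[2]; Wo <- dim(dy)[3]
  dx <- array(0, x_shape)
  for (oi in seq_len(Ho)) for (oj in seq_len(Wo)) {
    ri <- ((oi - 1L) * ph + 1L):min(oi * ph, H)
    rj <- ((oj - 1L) * pw + 1L):min(oj * pw, Wd)
    g <- dy[, oi, oj, ] / (length(ri) * length(rj))   # (B, C)
    for (i in ri) for (j in rj)
      dx[, i, j, ] <- dx[, i, j, ] + g
  }
  dx
}

bn_fwd <- function(gamma, beta, x, train, run_mean, run_var, eps = 1e-5) {
  d <- dim(x); C <- d[4]
  xm <- matrix(x, ncol = C)
  if (train) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2L, mu)^2)
  } else {
    mu <- run_mean; va <- run_var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2L, mu), 2L, invstd, "*")
  ym <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = array(ym, d), xhat = xhat, invstd = invstd,
       batch_mean = mu, batch_var = va)
}

bn_bwd <- function(gamma, x_shape, xhat, invstd, dy) {
  C <- x_shape[4]
  dym <- matrix(dy, ncol = C)
  N <- nrow(dym)
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, gamma, "*")
  t1 <- sweep(dxhat, 2L, colMeans(dxhat))
  t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
  dxm <- sweep(t1 - t2, 2L, invstd, "*")
  list(dx = array(dxm, x_shape), dgamma = dgamma, dbeta = dbeta)
}

dense_fwd <- function(Wm, bias, x) {
  y <- sweep(x %*% Wm, 2L, bias, "+")
  list(y = y, x = x)
}

dense_bwd <- function(Wm, x, dy) {
  list(dx = dy %*% t(Wm), dW = crossprod(x, dy), db = colSums(dy))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}
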