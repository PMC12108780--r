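# Layer primitives for the teacher/student convolutional networks.
#
# Internal tensor layout is time-major: (T, channels, batch), so the
# convolution kernels slide along the first (contiguous) dimension. Each
# primitive has a *_fwd returning list(out, cache) and a *_bwd returning the
# input gradient plus parameter gradients; the network files chain them.

as_cube <- function(x, d) { dim(x) <- d; x }

# ---- convolution along time (C++ backend) ----------------------------------

# X (T, Cin, n); W (K, Cin, Cout); b length Cout. "same" zero padding, K odd.
convt_fwd <- function(X, W, b) {
  out <- conv1d_fwd(X, W, b)
  list(out = out, cache = list(X = X, W = W))
}

convt_bwd <- function(cache, dY) {
  g <- conv1d_bwd(cache$X, cache$W, dY)
  list(dX = g$dX, dW = g$dW, db = as.numeric(g$db))
}

# ---- batch normalization ---------------------------------------------------

# Normalizes each channel (dim 2) over time x batch. eps/momentum follow
# common deep-learning framework defaults.
bn_init <- function(nchan) {
  list(gamma = rep(1, nchan), beta = rep(0, nchan),
       run_mean = rep(0, nchan), run_var = rep(1, nchan))
}

# per-channel totals over time x batch: colSums over dim 1 gives a
# (channels, slices) matrix, rowSums collapses the slices
chan_sums <- function(X) rowSums(colSums(X))

# broadcast a per-channel vector over a (T, channels, slices) array
chan_expand <- function(v, d) rep(rep(v, each = d[1L]), times = d[3L])

bn_fwd <- function(X, p, train, momentum = 0.1, eps = 1e-5) {
  r <- bn_fwd_cpp(X, p$gamma, p$beta, p$run_mean, p$run_var, momentum, eps,
                  train)
  p$run_mean <- as.numeric(r$run_mean)
  p$run_var <- as.numeric(r$run_var)
  list(out = r$out, params = p,
       cache = list(Xhat = r$Xhat, istd = as.numeric(r$istd),
                    gamma = p$gamma, train = train))
}

bn_bwd <- function(cache, dY) {
  r <- bn_bwd_cpp(dY, cache$Xhat, cache$istd, cache$gamma, cache$train)
  list(dX = r$dX, dgamma = as.numeric(r$dgamma),
       dbeta = as.numeric(r$dbeta))
}

# ---- activations, dropout, pooling ----------------------------------------

elu_fwd <- function(X) {
  neg <- X < 0
  out <- X
  out[neg] <- expm1(X[neg])
  list(out = out, cache = out)
}

elu_bwd <- function(cache, dY) {
  g <- dY
  neg <- cache < 0
  g[neg] <- g[neg] * (cache[neg] + 1)
  g
}

dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, cache = NULL))
  mask <- array(stats::runif(length(X)) >= p, dim = dim(X)) / (1 - p)
  list(out = X * mask, cache = mask)
}

dropout_bwd <- function(cache, dY) if (is.null(cache)) dY else dY * cache

# Non-overlapping average pooling along time with floor division: T -> T %/% w.
avgpool_fwd <- function(X, w) {
  d <- dim(X)
  Tp <- d[1L] %/% w
  Xt <- X[seq_len(Tp * w), , , drop = FALSE]
  dim(Xt) <- c(w, Tp, d[2L], d[3L])
  out <- colMeans(Xt)                      # (Tp, C, n)
  list(out = out, cache = list(d = d, w = w, Tp = Tp))
}

avgpool_bwd <- function(cache, dY) {
  d <- cache$d; w <- cache$w; Tp <- cache$Tp
  dX <- array(0, dim = d)
  expand <- array(rep(dY / w, each = w), dim = c(w * Tp, d[2L], d[3L]))
  dX[seq_len(w * Tp), , ] <- expand
  dX
}

# ---- depthwise spatial convolution ----------------------------------------

# Collapses the channel axis: input (T, F1, C, n), weight (C, F1, D),
# output (T, F1 * D, n) where map (f, d) = sum_c W[c, f, d] * X[, f, c, ].
depthwise_fwd <- function(X, W) {
  d <- dim(X); T <- d[1L]; F1 <- d[2L]; C <- d[3L]; n <- d[4L]
  D <- dim(W)[3L]
  X3 <- X; dim(X3) <- c(T * F1, C, n)
  out <- array(0, dim = c(T, F1 * D, n))
  for (dd in seq_len(D))
    out[, (dd - 1L) * F1 + seq_len(F1), ] <-
      dw_fwd_cpp(X3, matrix(W[, , dd], C, F1), T)
  list(out = out, cache = list(X3 = X3, W = W, d = d))
}

depthwise_bwd <- function(cache, dY) {
  W <- cache$W; d <- cache$d
  T <- d[1L]; F1 <- d[2L]; C <- d[3L]; n <- d[4L]
  D <- dim(W)[3L]
  dX3 <- 0
  dW <- array(0, dim = dim(W))
  d3 <- c(T, F1, n)
  for (dd in seq_len(D)) {
    dYd <- dY[, (dd - 1L) * F1 + seq_len(F1), , drop = FALSE]
    dim(dYd) <- d3
    g <- dw_bwd_cpp(cache$X3, matrix(W[, , dd], C, F1), dYd, T)
    dX3 <- dX3 + g$dX
    dW[, , dd] <- g$dW
  }
  dim(dX3) <- d
  list(dX = dX3, dW = dW)
}

# ---- fully connected softmax head -----------------------------------------

# feat: (d, n); W: (M, d); b: length M. Log-softmax computed in log space.
dense_fwd <- function(feat, W, b) {
  logits <- W %*% feat + b                 # (M, n)
  mx <- apply(logits, 2L, max)
  z <- sweep(logits, 2L, mx)
  lse <- log(colSums(exp(z)))
  logp <- sweep(z, 2L, lse)
  list(logp = logp, cache = list(feat = feat, W = W, logp = logp))
}

# Cross-entropy gradient straight through the softmax.
dense_bwd_ce <- function(cache, labels, extra_dfeat = NULL) {
  logp <- cache$logp
  n <- ncol(logp)
  P <- exp(logp)
  Y <- matrix(0, nrow(P), n)
  Y[cbind(labels + 1L, seq_len(n))] <- 1
  dlogits <- (P - Y) / n                   # d(mean CE)/dlogits
  dW <- dlogits %*% t(cache$feat)
  db <- rowSums(dlogits)
  dfeat <- t(cache$W) %*% dlogits
  if (!is.null(extra_dfeat)) dfeat <- dfeat + extra_dfeat
  list(dfeat = dfeat, dW = dW, db = db)
}

# ---- channel concatenation (dense units) ----------------------------------

cat_channels <- function(A, B) {
  da <- dim(A); db <- dim(B)
  out <- array(0, dim = c(da[1L], da[2L] + db[2L], da[3L]))
  out[, seq_len(da[2L]), ] <- A
  out[, da[2L] + seq_len(db[2L]), ] <- B
  out
}
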