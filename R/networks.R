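#' Architecture hyperparameters for the teacher and student networks
#'
#' Both networks share a trunk: temporal convolution (F1 filters, kernel
#' width C1, "same" padding), depthwise spatial convolution collapsing the
#' electrode axis, two densely connected units (three time-convolutions each
#' with growth rate F2, dense concatenation, ELU + batch-norm + dropout,
#' average pooling of width \code{pool}), and a classifier (1x1 convolution
#' with F3 filters, ELU, flatten, fully connected softmax with a 0.25
#' max-norm on its weight rows). The teacher additionally starts with a
#' pointwise spectral-fusion convolution collapsing the Nb filter-bank bands
#' to one; the student consumes raw single-band input and its classifier
#' convolution has 2*F3 filters whose flattened output splits into the
#' internally invariant half z1 and the mutually invariant half z2.
#'
#' @param C Number of EEG channels.
#' @param T Number of timepoints per trial (>= 25 so \code{T \%/\% 25 >= 1}).
#' @param Nb Number of filter-bank bands feeding the teacher.
#' @param n_classes Number of classes.
#' @param F1 Temporal-convolution filter count.
#' @param D Depth multiplier of the depthwise spatial convolution.
#' @param F2 Growth rate of the densely connected units.
#' @param F3 Classifier 1x1-convolution filter count (student uses 2*F3).
#' @param C1 Temporal kernel width; default one quarter of the sampling rate
#'   rounded up to the nearest odd integer (250 Hz -> 63) so "same" padding
#'   is symmetric.
#' @param C2,C3 Kernel widths of dense units 1 and 2 (odd).
#' @param dropout_p Dropout probability in \code{[0, 1)}.
#' @param pool Average-pooling width (the architecture assumes 5).
#' @param fs Sampling rate in Hz (only used for the C1 default).
#' @return An object of class \code{network_config}.
#' @export
network_config <- function(C = 22L, T = 1000L, Nb = 4L, n_classes = 4L,
                           F1 = 24L, D = 1L, F2 = 12L, F3 = 32L,
                           C1 = NULL, C2 = 15L, C3 = 15L,
                           dropout_p = 0.5, pool = 5L, fs = 250) {
  if (is.null(C1)) {
    C1 <- as.integer(ceiling(fs / 4))
    if (C1 %% 2L == 0L) C1 <- C1 + 1L
  }
  cfg <- list(C = as.integer(C), T = as.integer(T), Nb = as.integer(Nb),
              n_classes = as.integer(n_classes), F1 = as.integer(F1),
              D = as.integer(D), F2 = as.integer(F2), F3 = as.integer(F3),
              C1 = as.integer(C1), C2 = as.integer(C2), C3 = as.integer(C3),
              dropout_p = as.numeric(dropout_p), pool = as.integer(pool),
              fs = as.numeric(fs))
  class(cfg) <- "network_config"
  validate_network_config(cfg)
  cfg
}

validate_network_config <- function(cfg) {
  counts <- c("C", "Nb", "n_classes", "F1", "D", "F2", "F3")
  for (f in counts)
    if (cfg[[f]] < 1L)
      stop("network_config: '", f, "' must be >= 1", call. = FALSE)
  if (cfg$T < cfg$pool^2)
    stop("network_config: T must be >= pool^2 (", cfg$pool^2,
         ") so the pooled length stays >= 1", call. = FALSE)
  for (f in c("C1", "C2", "C3"))
    if (cfg[[f]] < 1L || cfg[[f]] %% 2L == 0L)
      stop("network_config: kernel width '", f, "' must be a positive odd ",
           "integer", call. = FALSE)
  if (cfg$dropout_p < 0 || cfg$dropout_p >= 1)
    stop("network_config: dropout_p must lie in [0, 1)", call. = FALSE)
  if (cfg$n_classes < 2L)
    stop("network_config: need at least 2 classes", call. = FALSE)
  invisible(cfg)
}

glorot <- function(dims) {
  fan <- if (length(dims) >= 2L) prod(dims[-length(dims)]) + dims[length(dims)]
         else sum(dims)
  lim <- sqrt(6 / fan)
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

init_network <- function(cfg, kind) {
  p <- list()
  st <- list()
  if (kind == "teacher") {
    p$fus_W <- glorot(c(1L, cfg$Nb, 1L))
    p$fus_b <- 0
  }
  p$temp_W <- glorot(c(cfg$C1, 1L, cfg$F1))
  p$temp_b <- rep(0, cfg$F1)
  add_bn <- function(name, nchan) {
    p[[paste0(name, "_g")]] <<- rep(1, nchan)
    p[[paste0(name, "_b")]] <<- rep(0, nchan)
    st[[paste0(name, "_m")]] <<- rep(0, nchan)
    st[[paste0(name, "_v")]] <<- rep(1, nchan)
  }
  add_bn("bnt", cfg$F1)
  p$dw_W <- glorot(c(cfg$C, cfg$F1, cfg$D))
  k0 <- cfg$F1 * cfg$D
  add_bn("bns", k0)
  for (u in 1:2) {
    K <- if (u == 1L) cfg$C2 else cfg$C3
    kin <- k0 + (u - 1L) * 3L * cfg$F2
    for (l in 1:3) {
      cin <- kin + (l - 1L) * cfg$F2
      p[[sprintf("u%d_conv%d_W", u, l)]] <- glorot(c(K, cin, cfg$F2))
      p[[sprintf("u%d_conv%d_b", u, l)]] <- rep(0, cfg$F2)
      add_bn(sprintf("u%d_bn%d", u, l), cfg$F2)
    }
  }
  F3e <- if (kind == "student") 2L * cfg$F3 else cfg$F3
  cin_cls <- k0 + 6L * cfg$F2
  p$cls_W <- glorot(c(1L, cin_cls, F3e))
  p$cls_b <- rep(0, F3e)
  T25 <- (cfg$T %/% cfg$pool) %/% cfg$pool
  p$fc_W <- glorot(c(cfg$n_classes, F3e * T25))
  p$fc_b <- rep(0, cfg$n_classes)
  structure(list(cfg = cfg, kind = kind, params = p, stats = st),
            class = "dg_network")
}

#' Build the spectral-fusion teacher network
#'
#' @param cfg A [network_config()]. Weight initialization consumes the
#'   current R random stream; seed beforehand for reproducibility.
#' @return A \code{dg_network} of kind \code{"teacher"}.
#' @export
build_teacher <- function(cfg) {
  validate_network_config(cfg)
  init_network(cfg, "teacher")
}

#' Build the student network
#'
#' Identical to the teacher minus the spectral-fusion block; the classifier
#' 1x1 convolution has \code{2 * F3} filters whose flattened output splits
#' evenly into z1 (first F3 maps) and z2 (last F3 maps).
#'
#' @param cfg A [network_config()].
#' @return A \code{dg_network} of kind \code{"student"}.
#' @export
build_student <- function(cfg) {
  validate_network_config(cfg)
  init_network(cfg, "student")
}

#' Number of trainable parameters of a network
#' @param net A \code{dg_network}.
#' @return Integer count.
#' @export
n_parameters <- function(net) sum(vapply(net$params, length, 0L))

#' @export
print.dg_network <- function(x, ...) {
  cat(sprintf("dg_network (%s): C=%d T=%d Nb=%d classes=%d, %d parameters\n",
              x$kind, x$cfg$C, x$cfg$T, x$cfg$Nb, x$cfg$n_classes,
              n_parameters(x)))
  invisible(x)
}

run_bn <- function(x, net, name, train, cache) {
  pp <- list(gamma = net$params[[paste0(name, "_g")]],
             beta = net$params[[paste0(name, "_b")]],
             run_mean = net$stats[[paste0(name, "_m")]],
             run_var = net$stats[[paste0(name, "_v")]])
  bz <- bn_fwd(x, pp, train)
  net$stats[[paste0(name, "_m")]] <- bz$params$run_mean
  net$stats[[paste0(name, "_v")]] <- bz$params$run_var
  cache[[name]] <- bz$cache
  list(out = bz$out, net = net, cache = cache)
}

unit_fwd <- function(x, net, u, train, cache) {
  p <- net$params
  cur <- x
  cache[[sprintf("u%d_k0", u)]] <- dim(x)[2L]
  for (l in 1:3) {
    cz <- convt_fwd(cur, p[[sprintf("u%d_conv%d_W", u, l)]],
                    p[[sprintf("u%d_conv%d_b", u, l)]])
    az <- elu_fwd(cz$out)
    r <- run_bn(az$out, net, sprintf("u%d_bn%d", u, l), train, cache)
    net <- r$net; cache <- r$cache
    dz <- dropout_fwd(r$out, net$cfg$dropout_p, train)
    cache[[sprintf("u%d_conv%d", u, l)]] <- cz$cache
    cache[[sprintf("u%d_elu%d", u, l)]] <- az$cache
    cache[[sprintf("u%d_drop%d", u, l)]] <- dz$cache
    cur <- cat_channels(cur, dz$out)
  }
  list(out = cur, net = net, cache = cache)
}

unit_bwd <- function(cache, d_out, net, u, grads) {
  p <- net$params
  d_cur <- d_out
  for (l in 3:1) {
    W <- p[[sprintf("u%d_conv%d_W", u, l)]]
    F2 <- dim(W)[3L]
    nc <- dim(d_cur)[2L]
    d_y <- d_cur[, (nc - F2 + 1L):nc, , drop = FALSE]
    d_head <- d_cur[, seq_len(nc - F2), , drop = FALSE]
    d_y <- dropout_bwd(cache[[sprintf("u%d_drop%d", u, l)]], d_y)
    bb <- bn_bwd(cache[[sprintf("u%d_bn%d", u, l)]], d_y)
    grads[[sprintf("u%d_bn%d_g", u, l)]] <- bb$dgamma
    grads[[sprintf("u%d_bn%d_b", u, l)]] <- bb$dbeta
    d_a <- elu_bwd(cache[[sprintf("u%d_elu%d", u, l)]], bb$dX)
    cb <- convt_bwd(cache[[sprintf("u%d_conv%d", u, l)]], d_a)
    grads[[sprintf("u%d_conv%d_W", u, l)]] <- cb$dW
    grads[[sprintf("u%d_conv%d_b", u, l)]] <- cb$db
    d_cur <- d_head + cb$dX
  }
  list(dX = d_cur, grads = grads)
}

# Forward pass in the internal time-major layout.
# Teacher Xin: (T, C, Nb, n); student Xin: (T, C, n).
# Returns list(net, feat, z1, z2, logp, probs, cache).
net_forward <- function(net, Xin, train = FALSE) {
  cfg <- net$cfg; p <- net$params
  cache <- list()
  if (net$kind == "teacher") {
    d <- dim(Xin)
    stopifnot(length(d) == 4L, d[1L] == cfg$T, d[2L] == cfg$C,
              d[3L] == cfg$Nb)
    n <- d[4L]
    Xf <- Xin; dim(Xf) <- c(cfg$T * cfg$C, cfg$Nb, n)
    fz <- convt_fwd(Xf, p$fus_W, p$fus_b)
    cache$fus <- fz$cache
    x <- fz$out
  } else {
    d <- dim(Xin)
    stopifnot(length(d) == 3L, d[1L] == cfg$T, d[2L] == cfg$C)
    n <- d[3L]
    x <- Xin
  }
  dim(x) <- c(cfg$T, 1L, cfg$C * n)
  tz <- convt_fwd(x, p$temp_W, p$temp_b)
  cache$temp <- tz$cache
  r <- run_bn(tz$out, net, "bnt", train, cache); net <- r$net; cache <- r$cache
  x <- r$out
  dim(x) <- c(cfg$T, cfg$F1, cfg$C, n)
  dwz <- depthwise_fwd(x, p$dw_W)
  cache$dw <- dwz$cache
  az <- elu_fwd(dwz$out); cache$dw_elu <- az$cache
  r <- run_bn(az$out, net, "bns", train, cache); net <- r$net; cache <- r$cache
  x <- r$out
  u1 <- unit_fwd(x, net, 1L, train, cache); net <- u1$net; cache <- u1$cache
  p1 <- avgpool_fwd(u1$out, cfg$pool); cache$pool1 <- p1$cache
  u2 <- unit_fwd(p1$out, net, 2L, train, cache); net <- u2$net; cache <- u2$cache
  p2 <- avgpool_fwd(u2$out, cfg$pool); cache$pool2 <- p2$cache
  cz <- convt_fwd(p2$out, p$cls_W, p$cls_b); cache$cls <- cz$cache
  ez <- elu_fwd(cz$out); cache$cls_elu <- ez$cache
  A <- ez$out                                   # (T25, F3e, n)
  dA <- dim(A)
  feat <- A; dim(feat) <- c(dA[1L] * dA[2L], dA[3L])
  cache$featdim <- dA
  dz <- dense_fwd(feat, p$fc_W, p$fc_b)
  cache$dense <- dz$cache
  out <- list(net = net, feat = feat, logp = dz$logp,
              probs = exp(dz$logp), cache = cache)
  if (net$kind == "student") {
    half <- cfg$F3 * dA[1L]
    out$z1 <- feat[seq_len(half), , drop = FALSE]
    out$z2 <- feat[half + seq_len(half), , drop = FALSE]
  }
  out
}

# Backward pass: cross-entropy gradient through the softmax head plus an
# optional extra gradient w.r.t. the flattened classifier features (the
# distillation / alignment / divergence terms enter there).
# Returns a named list of gradients parallel to net$params.
net_backward <- function(net, cache, labels, dfeat_extra = NULL) {
  cfg <- net$cfg
  grads <- list()
  db <- dense_bwd_ce(cache$dense, labels, dfeat_extra)
  grads$fc_W <- db$dW; grads$fc_b <- db$db
  dA <- db$dfeat
  dim(dA) <- cache$featdim
  dA <- elu_bwd(cache$cls_elu, dA)
  cb <- convt_bwd(cache$cls, dA)
  grads$cls_W <- cb$dW; grads$cls_b <- cb$db
  dx <- avgpool_bwd(cache$pool2, cb$dX)
  u2 <- unit_bwd(cache, dx, net, 2L, grads); grads <- u2$grads
  dx <- avgpool_bwd(cache$pool1, u2$dX)
  u1 <- unit_bwd(cache, dx, net, 1L, grads); grads <- u1$grads
  bb <- bn_bwd(cache$bns, u1$dX)
  grads$bns_g <- bb$dgamma; grads$bns_b <- bb$dbeta
  dx <- elu_bwd(cache$dw_elu, bb$dX)
  dwb <- depthwise_bwd(cache$dw, dx)
  grads$dw_W <- dwb$dW
  dx <- dwb$dX
  n <- dim(dx)[4L]
  dim(dx) <- c(cfg$T, cfg$F1, cfg$C * n)
  bb <- bn_bwd(cache$bnt, dx)
  grads$bnt_g <- bb$dgamma; grads$bnt_b <- bb$dbeta
  tb <- convt_bwd(cache$temp, bb$dX)
  grads$temp_W <- tb$dW; grads$temp_b <- tb$db
  if (net$kind == "teacher") {
    dxf <- tb$dX
    dim(dxf) <- c(cfg$T * cfg$C, 1L, n)
    fb <- convt_bwd(cache$fus, dxf)
    grads$fus_W <- fb$dW; grads$fus_b <- fb$db
  }
  grads
}

#' Forward pass of the teacher network
#'
#' @param net A teacher \code{dg_network}.
#' @param X_MB Numeric array \code{[batch, Nb, C, T]} of fused multi-band
#'   trials (see [apply_filter_bank()]).
#' @param train_mode Logical; \code{FALSE} (default) uses batch-norm running
#'   statistics and no dropout, making the pass deterministic.
#' @return List with \code{feat} \code{[batch, F3 * (T \%/\% 25)]} (the
#'   post-ELU flattened classifier-convolution output used as the
#'   distillation target) and \code{probs} \code{[batch, n_classes]}.
#' @export
forward_teacher <- function(net, X_MB, train_mode = FALSE) {
  stopifnot(inherits(net, "dg_network"), net$kind == "teacher")
  d <- dim(X_MB)
  if (length(d) != 4L || d[2L] != net$cfg$Nb || d[3L] != net$cfg$C ||
      d[4L] != net$cfg$T)
    stop("forward_teacher: X_MB must be [batch, Nb, C, T] matching the ",
         "network config", call. = FALSE)
  Xin <- aperm(X_MB, c(4L, 3L, 2L, 1L))
  r <- net_forward(net, Xin, train = train_mode)
  list(feat = t(r$feat), probs = t(r$probs))
}

#' Forward pass of the student network
#'
#' @param net A student \code{dg_network}.
#' @param X Numeric array \code{[batch, C, T]} (or \code{[batch, 1, C, T]})
#'   of raw trials.
#' @param train_mode Logical; \code{FALSE} gives a deterministic pass.
#' @return List with \code{z1}, \code{z2} (each
#'   \code{[batch, F3 * (T \%/\% 25)]}) and \code{probs}
#'   \code{[batch, n_classes]}.
#' @export
forward_student <- function(net, X, train_mode = FALSE) {
  stopifnot(inherits(net, "dg_network"), net$kind == "student")
  d <- dim(X)
  if (length(d) == 4L) {
    if (d[2L] != 1L)
      stop("forward_student: 4-d input must be [batch, 1, C, T]",
           call. = FALSE)
    dim(X) <- d[-2L]
    d <- dim(X)
  }
  if (length(d) != 3L || d[2L] != net$cfg$C || d[3L] != net$cfg$T)
    stop("forward_student: X must be [batch, C, T] matching the network ",
         "config", call. = FALSE)
  Xin <- aperm(X, c(3L, 2L, 1L))
  r <- net_forward(net, Xin, train = train_mode)
  list(z1 = t(r$z1), z2 = t(r$z2), probs = t(r$probs))
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a named-parameter archive bundled with the
#' [network_config()] used to build it, so it round-trips exactly.
#'
#' @param net A \code{dg_network}.
#' @param path File path.
#' @return \code{save_checkpoint} returns \code{path} invisibly;
#'   \code{load_checkpoint} returns the restored \code{dg_network}.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "dg_network"))
  saveRDS(unclass(net), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  class(obj$cfg) <- "network_config"
  validate_network_config(obj$cfg)
  structure(obj, class = "dg_network")
}

# Fingerprint of a parameter list (CRC-32 over the serialized values);
# used to assert the frozen-teacher contract.
params_hash <- function(params) {
  raw <- serialize(params[order(names(params))], connection = NULL,
                   xdr = TRUE)
  crc32_raw(raw, 0)
}
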