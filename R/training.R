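#' Training protocol configuration
#'
#' Defaults follow the two-stage leave-one-subject-out protocol: Adam with
#' learning rate 0.001 in stage one (at most 1000 epochs, early stopping on
#' validation loss), then continued training on the pooled training +
#' validation data for at most 400 epochs with the learning rate dropping
#' from 0.001 to 1e-4 once the epoch count exceeds \code{lr_switch_epoch},
#' stopping as soon as the monitored loss falls below the validation loss
#' recorded in stage one.
#'
#' @param batch_size Mini-batch size (>= 2 * number of subdomains so every
#'   subdomain contributes at least two samples per batch).
#' @param lr_stage1 Stage-one learning rate.
#' @param lr_stage2_early,lr_stage2_late Stage-two learning rates before and
#'   after the switch epoch.
#' @param lr_switch_epoch Stage-two epoch after which the late rate applies.
#' @param max_epochs_stage1,max_epochs_stage2 Epoch budgets.
#' @param es_patience Early-stopping patience (epochs without validation
#'   improvement) in stage one.
#' @param n_subdomains Number of subdomain groups k; \code{NULL} (default)
#'   uses one subdomain per source subject.
#' @param val_fraction Fraction of source trials held out for validation.
#' @param n_folds Stage-one cross-validation folds when
#'   \code{stage1_mode = "cv"}.
#' @param stage1_mode \code{"cv"} (default): n_folds stratified folds, the
#'   fold with the highest validation accuracy seeds stage two. \code{"single"}:
#'   one stratified \code{1 - val_fraction} / \code{val_fraction} split.
#' @param stage2_scope \code{"both"} (default) continues teacher and student
#'   in stage two; \code{"student"} freezes the teacher permanently.
#' @param seed Integer seed governing splits, batch streams, weight
#'   initialization and dropout.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(batch_size = 64L, lr_stage1 = 1e-3,
                         lr_stage2_early = 1e-3, lr_stage2_late = 1e-4,
                         lr_switch_epoch = 150L,
                         max_epochs_stage1 = 1000L, max_epochs_stage2 = 400L,
                         es_patience = 50L, n_subdomains = NULL,
                         val_fraction = 0.2, n_folds = 5L,
                         stage1_mode = c("cv", "single"),
                         stage2_scope = c("both", "student"), seed = 1L) {
  cfg <- list(batch_size = as.integer(batch_size),
              lr_stage1 = lr_stage1,
              lr_stage2_early = lr_stage2_early,
              lr_stage2_late = lr_stage2_late,
              lr_switch_epoch = as.integer(lr_switch_epoch),
              max_epochs_stage1 = as.integer(max_epochs_stage1),
              max_epochs_stage2 = as.integer(max_epochs_stage2),
              es_patience = as.integer(es_patience),
              n_subdomains = if (is.null(n_subdomains)) NULL
                             else as.integer(n_subdomains),
              val_fraction = as.numeric(val_fraction),
              n_folds = as.integer(n_folds),
              stage1_mode = match.arg(stage1_mode),
              stage2_scope = match.arg(stage2_scope),
              seed = as.integer(seed))
  if (cfg$val_fraction <= 0 || cfg$val_fraction >= 1)
    stop("train_config: val_fraction must lie in (0, 1)", call. = FALSE)
  counts <- c("batch_size", "lr_switch_epoch", "max_epochs_stage1",
              "max_epochs_stage2", "es_patience", "n_folds")
  for (f in counts)
    if (cfg[[f]] < 1L)
      stop("train_config: '", f, "' must be >= 1", call. = FALSE)
  class(cfg) <- "train_config"
  cfg
}

#' Stage-two learning-rate schedule
#'
#' @param epoch Stage-two epoch (1-based).
#' @param cfg A [train_config()].
#' @return 0.001 while \code{epoch <= lr_switch_epoch}, 1e-4 after.
#' @export
lr_stage2 <- function(epoch, cfg) {
  if (epoch <= cfg$lr_switch_epoch) cfg$lr_stage2_early else cfg$lr_stage2_late
}

# run expr under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic sub-seed below 2^31
derive_seed <- function(base, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(base) * 7919 + h * 104729) %% 2147483563) + 1L
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: that subject's trials form the unseen target domain
#' and appear in no training or validation set of the fold.
#'
#' @param dataset An [eeg_dataset()] with at least 2 subjects.
#' @return List of folds, each \code{list(source, target)} of subject IDs.
#' @export
loso_splits <- function(dataset) {
  subjects <- sort(unique(dataset$subject))
  if (length(subjects) < 2L)
    stop("loso_splits: need at least 2 subjects", call. = FALSE)
  lapply(subjects, function(s)
    list(source = setdiff(subjects, s), target = s))
}

#' Randomly group source subjects into k subdomains
#'
#' Group sizes differ by at most one; the grouping is deterministic under the
#' seed.
#'
#' @param subjects Vector of subject IDs.
#' @param k Number of groups, \code{1 <= k <= length(subjects)}.
#' @param seed Integer seed.
#' @return List of k disjoint subject-ID vectors covering \code{subjects}.
#' @export
group_subdomains <- function(subjects, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 1L || k > length(subjects))
    stop("group_subdomains: k must lie in [1, number of subjects]",
         call. = FALSE)
  perm <- with_seed(seed, sample(subjects))
  sizes <- rep(length(subjects) %/% k, k)
  extra <- length(subjects) %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) sort(perm[starts[i]:ends[i]]))
}

#' Stratified subdomain batch stream
#'
#' Every batch contains at least two samples from every subdomain (the
#' minimum needed to form the per-subdomain covariances of the alignment
#' loss), with per-subdomain sampling, falling back to sampling with
#' replacement when a subdomain has fewer trials than its per-batch share.
#' One epoch is \code{ceiling(n / batch_size)} batches.
#'
#' @param subject Integer subject ID per trial (or an [eeg_dataset()]).
#' @param grouping List of subject-ID vectors from [group_subdomains()].
#' @param batch_size Batch size, \code{>= 2 * length(grouping)}.
#' @param seed Integer seed; a fixed seed yields an identical batch stream.
#' @param n_epochs Number of epochs to generate (default 1).
#' @return List over epochs; each epoch is a list of batches, each batch a
#'   list with \code{idx} (trial indices, grouped by subdomain) and
#'   \code{sizes} (samples per subdomain, in grouping order).
#' @export
make_stratified_batches <- function(subject, grouping, batch_size, seed = 1L,
                                    n_epochs = 1L) {
  if (inherits(subject, "eeg_dataset")) subject <- subject$subject
  k <- length(grouping)
  if (batch_size < 2L * k)
    stop("make_stratified_batches: batch_size must be >= 2 * k = ", 2L * k,
         " so every subdomain contributes at least 2 samples per batch ",
         "(required to form its covariance matrix)", call. = FALSE)
  sub_idx <- lapply(grouping, function(g) which(subject %in% g))
  if (any(vapply(sub_idx, length, 0L) == 0L))
    stop("make_stratified_batches: a subdomain has no trials", call. = FALSE)
  n <- length(subject)
  n_batches <- ceiling(n / batch_size)
  sizes <- rep(batch_size %/% k, k)
  rem <- batch_size %% k
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  with_seed(seed, {
    lapply(seq_len(n_epochs), function(e) {
      lapply(seq_len(n_batches), function(b) {
        idx <- unlist(lapply(seq_len(k), function(i) {
          pool <- sub_idx[[i]]
          sample(pool, sizes[i], replace = length(pool) < sizes[i])
        }))
        list(idx = idx, sizes = sizes)
      })
    })
  })
}

batch_stream_hash <- function(stream) {
  v <- unlist(lapply(stream, function(e) lapply(e, `[[`, "idx")))
  crc32_raw(writeBin(as.integer(v), raw(), size = 4L, endian = "little"), 0)
}

# ---- Adam optimizer with max-norm constraint -------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim2(p))),
       v = lapply(params, function(p) array(0, dim = dim2(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    step <- lr * mhat / (sqrt(vhat) + eps)
    dim(step) <- dim(params[[nm]])       # keep vectors vectors
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

# clip each row of the fully connected weight matrix to L2 norm <= maxnorm
apply_maxnorm <- function(params, maxnorm = 0.25) {
  W <- params$fc_W
  rn <- sqrt(rowSums(W^2))
  over <- rn > maxnorm
  if (any(over)) W[over, ] <- W[over, , drop = FALSE] * (maxnorm / rn[over])
  params$fc_W <- W
  params
}

# ---- tensor preparation ----------------------------------------------------

# internal time-major tensors for a dataset: Xs (T, C, n) raw and,
# when a bank is given, Xmb (T, C, Nb, n) multiband
prepare_tensors <- function(dataset, bank = NULL) {
  out <- list(Xs = aperm(dataset$X, c(3L, 2L, 1L)), y = dataset$y,
              subject = dataset$subject, fs = dataset$fs)
  if (!is.null(bank)) out$Xmb <- filter_dataset(dataset, bank)
  out
}

slice_student <- function(tens, idx) tens$Xs[, , idx, drop = FALSE]
slice_teacher <- function(tens, idx) tens$Xmb[, , , idx, drop = FALSE]

# chunked deterministic evaluation; returns list(loss, acc, probs)
eval_net <- function(net, tens, idx, chunk = 128L) {
  y <- tens$y[idx]
  probs <- NULL
  for (s in seq(1L, length(idx), by = chunk)) {
    ii <- idx[s:min(length(idx), s + chunk - 1L)]
    Xin <- if (net$kind == "teacher") slice_teacher(tens, ii)
           else slice_student(tens, ii)
    r <- net_forward(net, Xin, train = FALSE)
    probs <- cbind(probs, r$probs)
  }
  pred <- max.col(t(probs), ties.method = "first") - 1L
  list(loss = cross_entropy(t(probs), y), acc = 100 * mean(pred == y),
       probs = t(probs), pred = pred)
}

# ---- single-network (teacher) training loop --------------------------------

fit_teacher_loop <- function(net, tens, idx_train, idx_val, stream, cfg,
                             max_epochs, lr_fun, recorded_loss = NULL,
                             stage = 1L, adam = NULL, patience = NULL) {
  if (is.null(adam)) adam <- adam_init(net$params)
  if (is.null(patience)) patience <- cfg$es_patience
  best <- list(loss = Inf, params = net$params, stats = net$stats)
  wait <- 0L
  hist <- list()
  stop_reason <- "max_epochs"
  for (epoch in seq_len(max_epochs)) {
    lr <- lr_fun(epoch)
    ep_loss <- 0
    batches <- stream[[epoch]]
    for (b in batches) {
      Xin <- slice_teacher(tens, b$idx)
      yb <- tens$y[b$idx]
      fw <- net_forward(net, Xin, train = TRUE)
      net <- fw$net
      ep_loss <- ep_loss + cross_entropy(t(fw$probs), yb)
      grads <- net_backward(net, fw$cache, yb)
      upd <- adam_step(net$params, grads, adam, lr)
      net$params <- apply_maxnorm(upd$params)
      adam <- upd$state
    }
    ev <- eval_net(net, tens, idx_val)
    hist[[epoch]] <- data.frame(stage = stage, epoch = epoch,
                                lcls = ep_loss / length(batches),
                                val_loss = ev$loss, lr = lr)
    if (!is.null(recorded_loss)) {
      if (ev$loss < recorded_loss) { stop_reason <- "below_recorded_loss"; break }
    } else {
      if (ev$loss < best$loss - 1e-9) {
        best <- list(loss = ev$loss, params = net$params, stats = net$stats)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) { stop_reason <- "patience"; break }
      }
    }
  }
  if (is.null(recorded_loss)) {       # restore best checkpoint
    net$params <- best$params
    net$stats <- best$stats
  }
  list(net = net, best_val_loss = if (is.null(recorded_loss)) best$loss else NA,
       history = do.call(rbind, hist), stop_reason = stop_reason, adam = adam)
}

#' Train the teacher network on fused multi-band inputs
#'
#' Minimizes cross-entropy with Adam at \code{lr_stage1}, early-stopping on
#' the validation loss with patience \code{es_patience}, and returns the
#' best-validation checkpoint.
#'
#' @param dataset_train,dataset_val Disjoint [eeg_dataset()] splits.
#' @param net_cfg A [network_config()].
#' @param train_cfg A [train_config()].
#' @param bank A [filter_bank()]; default bank at the data's sampling rate.
#' @return List with \code{net} (best checkpoint), \code{best_val_loss},
#'   \code{history} (per-epoch data frame) and \code{stop_reason}.
#' @export
train_teacher <- function(dataset_train, dataset_val, net_cfg, train_cfg,
                          bank = filter_bank(fs = dataset_train$fs)) {
  if (length(dataset_train$y) == 0L || length(dataset_val$y) == 0L)
    stop("train_teacher: empty split", call. = FALSE)
  n_tr <- length(dataset_train$y)
  merged <- eeg_dataset(
    abind1(dataset_train$X, dataset_val$X),
    c(dataset_train$y, dataset_val$y),
    c(dataset_train$subject, dataset_val$subject), dataset_train$fs)
  tens <- prepare_tensors(merged, bank)
  idx_train <- seq_len(n_tr)
  idx_val <- n_tr + seq_len(length(dataset_val$y))
  grouping <- as.list(sort(unique(dataset_train$subject)))
  stream <- make_stratified_batches(
    dataset_train$subject, grouping,
    min(train_cfg$batch_size, max(2L * length(grouping), n_tr)),
    derive_seed(train_cfg$seed, "teacher_batches"),
    train_cfg$max_epochs_stage1)
  stream <- lapply(stream, function(e)
    lapply(e, function(b) { b$idx <- idx_train[b$idx]; b }))
  net <- with_seed(derive_seed(train_cfg$seed, "teacher_init"),
                   build_teacher(net_cfg))
  res <- with_seed(derive_seed(train_cfg$seed, "teacher_dropout"),
                   fit_teacher_loop(net, tens, idx_train, idx_val, stream,
                                    train_cfg, train_cfg$max_epochs_stage1,
                                    function(e) train_cfg$lr_stage1))
  res[c("net", "best_val_loss", "history", "stop_reason")]
}

# concatenate two trial arrays along dim 1
abind1 <- function(A, B) {
  da <- dim(A); db <- dim(B)
  out <- array(0, dim = c(da[1L] + db[1L], da[2L], da[3L]))
  out[seq_len(da[1L]), , ] <- A
  out[da[1L] + seq_len(db[1L]), , ] <- B
  out
}

# ---- student training loop -------------------------------------------------

# deterministic teacher features for a set of trials, chunked; (d, n) matrix
teacher_features <- function(teacher, tens, idx, chunk = 128L) {
  cols <- NULL
  for (s in seq(1L, length(idx), by = chunk)) {
    ii <- idx[s:min(length(idx), s + chunk - 1L)]
    r <- net_forward(teacher, slice_teacher(tens, ii), train = FALSE)
    cols <- cbind(cols, r$feat)
  }
  cols
}

# One optimizer step of the student on one subdomain batch. tfeat holds the
# frozen teacher's features for the batch trials (constant target).
student_step <- function(net, tfeat, tens, b, w, adam, lr) {
  idx <- b$idx
  Xin <- slice_student(tens, idx)
  yb <- tens$y[idx]
  fw <- net_forward(net, Xin, train = TRUE)
  net <- fw$net
  z1 <- fw$z1; z2 <- fw$z2
  d_half <- nrow(z1); nb <- ncol(z1)
  # subdomain feature list for the alignment loss (rows = samples)
  ends <- cumsum(b$sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  sub_feats <- lapply(seq_along(b$sizes), function(i)
    t(z2[, starts[i]:ends[i], drop = FALSE]))
  # a single subdomain has no pairs to align
  align <- if (length(sub_feats) >= 2L) coral_align(sub_feats) else 0
  comp <- c(cls = cross_entropy(t(fw$probs), yb),
            mse = mse_loss(z1, tfeat),
            align = align,
            div = divergence(t(z1), t(z2)))
  # gradients w.r.t. the flattened feature halves
  dz1 <- w$lambda1 * 2 * (z1 - tfeat) / (d_half * nb) -
    w$lambda3 * 2 * (z1 - z2) / nb
  dz2 <- w$lambda3 * 2 * (z1 - z2) / nb
  if (w$lambda2 > 0 && length(sub_feats) >= 2L) {
    cg <- coral_align_grad(sub_feats)
    for (i in seq_along(cg))
      dz2[, starts[i]:ends[i]] <- dz2[, starts[i]:ends[i]] +
        w$lambda2 * t(cg[[i]])
  }
  dfeat <- rbind(dz1, dz2)
  grads <- net_backward(net, fw$cache, yb, dfeat_extra = dfeat)
  upd <- adam_step(net$params, grads, adam, lr)
  net$params <- apply_maxnorm(upd$params)
  total <- comp[["cls"]] + w$lambda1 * comp[["mse"]] +
    w$lambda2 * comp[["align"]] + w$lambda3 * comp[["div"]]
  list(net = net, adam = upd$state, comp = comp, total = total)
}

fit_student_loop <- function(net, teacher, tens, idx_val, stream, cfg, w,
                             max_epochs, lr_fun, recorded_loss = NULL,
                             stage = 1L, adam = NULL) {
  if (is.null(adam)) adam <- adam_init(net$params)
  best <- list(loss = Inf, params = net$params, stats = net$stats)
  wait <- 0L
  hist <- list()
  stop_reason <- "max_epochs"
  tfeat_all <- teacher_features(teacher, tens, seq_along(tens$y))
  for (epoch in seq_len(max_epochs)) {
    lr <- lr_fun(epoch)
    batches <- stream[[epoch]]
    acc <- c(cls = 0, mse = 0, align = 0, div = 0); tot <- 0
    for (b in batches) {
      stp <- student_step(net, tfeat_all[, b$idx, drop = FALSE], tens, b, w,
                          adam, lr)
      net <- stp$net; adam <- stp$adam
      acc <- acc + stp$comp; tot <- tot + stp$total
    }
    nb <- length(batches)
    ev <- eval_net(net, tens, idx_val)
    hist[[epoch]] <- data.frame(stage = stage, epoch = epoch,
                                lcls = acc[["cls"]] / nb,
                                lmse = acc[["mse"]] / nb,
                                lalign = acc[["align"]] / nb,
                                ldiv = acc[["div"]] / nb,
                                total = tot / nb,
                                val_loss = ev$loss, lr = lr)
    if (!is.null(recorded_loss)) {
      if (ev$loss < recorded_loss) { stop_reason <- "below_recorded_loss"; break }
    } else {
      if (ev$loss < best$loss - 1e-9) {
        best <- list(loss = ev$loss, params = net$params, stats = net$stats)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$es_patience) { stop_reason <- "patience"; break }
      }
    }
  }
  if (is.null(recorded_loss)) {
    net$params <- best$params
    net$stats <- best$stats
  }
  list(net = net, best_val_loss = if (is.null(recorded_loss)) best$loss else NA,
       history = do.call(rbind, hist), stop_reason = stop_reason, adam = adam)
}

#' Train the student network under the full domain-generalization objective
#'
#' Per batch the frozen teacher consumes the fused multi-band trials and the
#' student the raw trials; the total loss is cross-entropy plus the weighted
#' distillation (MSE on z1 vs teacher features), pairwise subdomain
#' alignment (CORAL on z2 covariances) and divergence (z1 vs z2) terms.
#' Teacher parameters are bit-identical before and after.
#'
#' @param teacher A trained teacher \code{dg_network} (frozen).
#' @param dataset_train,dataset_val Disjoint [eeg_dataset()] splits drawn
#'   from the teacher's source subjects.
#' @param grouping Subdomain grouping from [group_subdomains()]; must only
#'   reference subjects present in the training data.
#' @param net_cfg,train_cfg,w [network_config()], [train_config()],
#'   [loss_weights()].
#' @param bank Filter bank for the teacher inputs.
#' @return List with \code{net}, \code{best_val_loss}, \code{history}
#'   (per-epoch loss components), \code{stop_reason}, \code{batch_hash}.
#' @export
train_student <- function(teacher, dataset_train, dataset_val, grouping,
                          net_cfg, train_cfg, w = loss_weights(),
                          bank = filter_bank(fs = dataset_train$fs)) {
  subj_train <- unique(dataset_train$subject)
  if (!all(unlist(grouping) %in% subj_train))
    stop("train_student: grouping references a subject absent from the ",
         "training data", call. = FALSE)
  n_tr <- length(dataset_train$y)
  merged <- eeg_dataset(
    abind1(dataset_train$X, dataset_val$X),
    c(dataset_train$y, dataset_val$y),
    c(dataset_train$subject, dataset_val$subject), dataset_train$fs)
  tens <- prepare_tensors(merged, bank)
  idx_train <- seq_len(n_tr)
  idx_val <- n_tr + seq_len(length(dataset_val$y))
  stream <- make_stratified_batches(
    dataset_train$subject, grouping,
    min(train_cfg$batch_size, max(2L * length(grouping), n_tr)),
    derive_seed(train_cfg$seed, "student_batches"),
    train_cfg$max_epochs_stage1)
  stream <- lapply(stream, function(e)
    lapply(e, function(b) { b$idx <- idx_train[b$idx]; b }))
  net <- with_seed(derive_seed(train_cfg$seed, "student_init"),
                   build_student(net_cfg))
  res <- with_seed(derive_seed(train_cfg$seed, "student_dropout"),
                   fit_student_loop(net, teacher, tens, idx_val, stream,
                                    train_cfg, w,
                                    train_cfg$max_epochs_stage1,
                                    function(e) train_cfg$lr_stage1))
  res$batch_hash <- batch_stream_hash(stream)
  res[c("net", "best_val_loss", "history", "stop_reason", "batch_hash")]
}

# stratified fold assignment by class x subject cells; returns integer fold
# id per trial in 1..n_folds
stratified_folds <- function(y, subject, n_folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cell in split(seq_along(y), list(y, subject), drop = TRUE)) {
      perm <- if (length(cell) > 1L) sample(cell) else cell
      fold[perm] <- rep_len(sample(n_folds), length(perm))
    }
  })
  fold
}

#' Two-stage fit of the full teacher + student system on source data
#'
#' Stage one fits the distillation system on stratified 80/20 splits (five
#' folds by default; the fold with the highest student validation accuracy
#' supplies the stage-two starting model and its recorded validation loss).
#' Stage two resumes that model on all source trials with the stage-two
#' learning-rate schedule, stopping as soon as the loss monitored on the
#' chosen fold's former validation subset falls below the recorded stage-one
#' loss, or after \code{max_epochs_stage2} epochs.
#'
#' @param dataset_source [eeg_dataset()] of all source-subject trials
#'   (>= 2 subjects recommended; the target subject must not be present).
#' @param net_cfg,train_cfg,w [network_config()], [train_config()],
#'   [loss_weights()].
#' @param bank Filter bank for the teacher inputs.
#' @param tensors Optional precomputed [prepare_tensors()] output for
#'   \code{dataset_source} (avoids refiltering across folds).
#' @return An object of class \code{dg_fit}: \code{teacher}, \code{student},
#'   \code{best_val_loss_stage1}, \code{history} (stage/epoch loss
#'   components), \code{stop_reason}
#'   (\code{patience}/\code{max_epochs}/\code{below_recorded_loss}),
#'   \code{batch_hash}, \code{grouping}, \code{fold_metrics}.
#' @export
two_stage_fit <- function(dataset_source, net_cfg, train_cfg,
                          w = loss_weights(),
                          bank = filter_bank(fs = dataset_source$fs),
                          tensors = NULL, teacher_cache = NULL,
                          cache_prefix = "") {
  subjects <- sort(unique(dataset_source$subject))
  k <- if (is.null(train_cfg$n_subdomains)) length(subjects)
       else train_cfg$n_subdomains
  grouping <- group_subdomains(subjects, k,
                               derive_seed(train_cfg$seed, "grouping"))
  if (is.null(tensors)) tensors <- prepare_tensors(dataset_source, bank)
  y <- dataset_source$y
  subject <- dataset_source$subject
  n <- length(y)
  n_folds <- if (train_cfg$stage1_mode == "single") 1L else train_cfg$n_folds
  fold_of <- stratified_folds(y, subject, max(n_folds,
                                              round(1 / train_cfg$val_fraction)),
                              derive_seed(train_cfg$seed, "folds"))
  # each stage-1 fold: one of the (1/val_fraction) stratified parts is the
  # validation set, the rest train
  n_parts <- max(n_folds, round(1 / train_cfg$val_fraction))
  best <- NULL
  fold_metrics <- data.frame()
  for (f in seq_len(n_folds)) {
    idx_val <- which(fold_of == f)
    idx_train <- setdiff(seq_len(n), idx_val)
    seed_f <- derive_seed(train_cfg$seed, paste0("fold", f))
    t_stream <- make_stratified_batches(
      subject[idx_train], lapply(subjects, identity),
      min(train_cfg$batch_size, max(2L * length(subjects),
                                    length(idx_train))),
      derive_seed(seed_f, "teacher_batches"), train_cfg$max_epochs_stage1)
    t_stream <- remap_stream(t_stream, idx_train)
    # the teacher fit is independent of the loss weights, so across ablation
    # variants it is deterministic given (seed, fold) and can be reused
    cache_key <- paste0(cache_prefix, "_s", train_cfg$seed, "_f", f)
    if (!is.null(teacher_cache) && exists(cache_key, envir = teacher_cache)) {
      t_res <- get(cache_key, envir = teacher_cache)
    } else {
      teacher <- with_seed(derive_seed(seed_f, "teacher_init"),
                           build_teacher(net_cfg))
      t_res <- with_seed(derive_seed(seed_f, "teacher_dropout"),
                         fit_teacher_loop(teacher, tensors, idx_train,
                                          idx_val, t_stream, train_cfg,
                                          train_cfg$max_epochs_stage1,
                                          function(e) train_cfg$lr_stage1))
      if (!is.null(teacher_cache))
        assign(cache_key, t_res, envir = teacher_cache)
    }
    s_stream <- make_stratified_batches(
      subject[idx_train], grouping,
      min(train_cfg$batch_size, max(2L * length(grouping),
                                    length(idx_train))),
      derive_seed(seed_f, "student_batches"), train_cfg$max_epochs_stage1)
    s_stream <- remap_stream(s_stream, idx_train)
    student <- with_seed(derive_seed(seed_f, "student_init"),
                         build_student(net_cfg))
    s_res <- with_seed(derive_seed(seed_f, "student_dropout"),
                       fit_student_loop(student, t_res$net, tensors, idx_val,
                                        s_stream, train_cfg, w,
                                        train_cfg$max_epochs_stage1,
                                        function(e) train_cfg$lr_stage1))
    ev <- eval_net(s_res$net, tensors, idx_val)
    fold_metrics <- rbind(fold_metrics,
                          data.frame(fold = f, val_acc = ev$acc,
                                     val_loss = s_res$best_val_loss))
    if (is.null(best) || ev$acc > best$val_acc) {
      best <- list(fold = f, teacher = t_res$net, student = s_res$net,
                   val_acc = ev$acc, val_loss = s_res$best_val_loss,
                   idx_val = idx_val,
                   history = rbind_hist(t_res$history, s_res$history),
                   batch_hash = batch_stream_hash(s_stream))
    }
  }
  # ---- stage 2: resume on all source data ----------------------------------
  teacher <- best$teacher; student <- best$student
  seed2 <- derive_seed(train_cfg$seed, "stage2")
  all_idx <- seq_len(n)
  s_stream2 <- make_stratified_batches(
    subject, grouping,
    min(train_cfg$batch_size, max(2L * length(grouping), n)),
    derive_seed(seed2, "student_batches"), train_cfg$max_epochs_stage2)
  t_stream2 <- make_stratified_batches(
    subject, lapply(subjects, identity),
    min(train_cfg$batch_size, max(2L * length(subjects), n)),
    derive_seed(seed2, "teacher_batches"), train_cfg$max_epochs_stage2)
  recorded <- best$val_loss
  hist2 <- list()
  stop_reason <- "max_epochs"
  adam_t <- adam_init(teacher$params)
  adam_s <- adam_init(student$params)
  with_seed(derive_seed(seed2, "dropout"), {
    for (epoch in seq_len(train_cfg$max_epochs_stage2)) {
      lr <- lr_stage2(epoch, train_cfg)
      if (train_cfg$stage2_scope == "both") {
        for (b in t_stream2[[epoch]]) {
          Xin <- slice_teacher(tensors, b$idx)
          yb <- tensors$y[b$idx]
          fw <- net_forward(teacher, Xin, train = TRUE)
          teacher <- fw$net
          grads <- net_backward(teacher, fw$cache, yb)
          upd <- adam_step(teacher$params, grads, adam_t, lr)
          teacher$params <- apply_maxnorm(upd$params)
          adam_t <- upd$state
        }
      }
      if (epoch == 1L || train_cfg$stage2_scope == "both")
        tfeat_all2 <- teacher_features(teacher, tensors, all_idx)
      acc <- c(cls = 0, mse = 0, align = 0, div = 0); tot <- 0
      for (b in s_stream2[[epoch]]) {
        stp <- student_step(student, tfeat_all2[, b$idx, drop = FALSE],
                            tensors, b, w, adam_s, lr)
        student <- stp$net; adam_s <- stp$adam
        acc <- acc + stp$comp; tot <- tot + stp$total
      }
      nb <- length(s_stream2[[epoch]])
      mon <- eval_net(student, tensors, best$idx_val)$loss
      hist2[[epoch]] <- data.frame(stage = 2L, epoch = epoch,
                                   lcls = acc[["cls"]] / nb,
                                   lmse = acc[["mse"]] / nb,
                                   lalign = acc[["align"]] / nb,
                                   ldiv = acc[["div"]] / nb,
                                   total = tot / nb, val_loss = mon, lr = lr)
      if (mon < recorded) { stop_reason <- "below_recorded_loss"; break }
    }
  })
  structure(list(teacher = teacher, student = student,
                 best_val_loss_stage1 = recorded,
                 history = rbind_hist(best$history, do.call(rbind, hist2)),
                 stop_reason = stop_reason,
                 batch_hash = best$batch_hash,
                 grouping = grouping,
                 fold_metrics = fold_metrics,
                 net_cfg = net_cfg, train_cfg = train_cfg, w = w),
            class = "dg_fit")
}

remap_stream <- function(stream, idx_map) {
  lapply(stream, function(e)
    lapply(e, function(b) { b$idx <- idx_map[b$idx]; b }))
}

# row-bind histories with differing columns (teacher has no mse/align/div)
rbind_hist <- function(a, b) {
  if (is.null(a$net)) a$net <- rep("teacher", nrow(a))
  if (is.null(b$net)) b$net <- rep("student", nrow(b))
  cols <- union(names(a), names(b))
  for (cl in setdiff(cols, names(a))) a[[cl]] <- NA_real_
  for (cl in setdiff(cols, names(b))) b[[cl]] <- NA_real_
  rbind(a[cols], b[cols])
}

#' @export
print.dg_fit <- function(x, ...) {
  cat(sprintf(
    "dg_fit: stage-1 recorded val loss %.4f; stop reason '%s'; %d epochs\n",
    x$best_val_loss_stage1, x$stop_reason, nrow(x$history)))
  invisible(x)
}
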