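#' Classification accuracy in percent
#'
#' @param pred,truth Equal-length label vectors (length >= 1).
#' @return \code{100 * matches / n}.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) == 0L || length(pred) != length(truth))
    stop("accuracy: need equal non-empty label vectors", call. = FALSE)
  100 * mean(pred == truth)
}

new_experiment_result <- function(per_subject, config, seeds) {
  vals <- unlist(per_subject)
  structure(list(per_subject_accuracy = per_subject,
                 mean = mean(vals),
                 std = stats::sd(vals) * sqrt((length(vals) - 1) /
                                                length(vals)),
                 config = config, seeds = seeds),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result (leave-one-subject-out)\n")
  for (s in names(x$per_subject_accuracy))
    cat(sprintf("  subject %-4s %6.2f %%\n", s, x$per_subject_accuracy[[s]]))
  cat(sprintf("  Avg %10.2f %%\n  Std %10.2f\n", x$mean, x$std))
  invisible(x)
}

#' Leave-one-subject-out domain-generalization experiment
#'
#' For each subject in turn, the remaining subjects form the source domain;
#' [two_stage_fit()] is run on the source data and the trained student is
#' evaluated on the held-out subject. Per-subject accuracies are averaged
#' over \code{seeds}. The reported std is the population standard deviation
#' of the per-subject column.
#'
#' @param dataset [eeg_dataset()] with at least 2 subjects.
#' @param net_cfg,train_cfg,w [network_config()], [train_config()],
#'   [loss_weights()].
#' @param seeds Integer vector of seeds (default: the seed in
#'   \code{train_cfg}).
#' @param bank Filter bank (defaults to the standard
#'   theta/alpha/beta/overall bank at the data's sampling rate).
#' @param fits_out Optional environment; if supplied, per-(seed, target)
#'   \code{dg_fit} objects are stored in it under "seed<seed>_subj<target>".
#' @return An \code{experiment_result} with per-subject accuracy (percent),
#'   mean, population std, the config snapshot, and the seed list.
#' @export
run_loso <- function(dataset, net_cfg, train_cfg, w = loss_weights(),
                     seeds = train_cfg$seed,
                     bank = filter_bank(fs = dataset$fs), fits_out = NULL,
                     teacher_cache = NULL) {
  folds <- loso_splits(dataset)
  tensors <- prepare_tensors(dataset, bank)
  per_subject <- list()
  for (fold in folds) {
    target <- fold$target
    idx_src <- which(dataset$subject %in% fold$source)
    idx_tgt <- which(dataset$subject == target)
    stopifnot(length(intersect(idx_src, idx_tgt)) == 0L)
    accs <- numeric(0)
    for (sd in seeds) {
      tc <- train_cfg; tc$seed <- as.integer(sd)
      src_tens <- list(Xs = tensors$Xs[, , idx_src, drop = FALSE],
                       Xmb = tensors$Xmb[, , , idx_src, drop = FALSE],
                       y = tensors$y[idx_src],
                       subject = tensors$subject[idx_src], fs = tensors$fs)
      src_ds <- eeg_dataset(dataset$X[idx_src, , , drop = FALSE],
                            dataset$y[idx_src], dataset$subject[idx_src],
                            dataset$fs)
      fit <- two_stage_fit(src_ds, net_cfg, tc, w, bank, tensors = src_tens,
                           teacher_cache = teacher_cache,
                           cache_prefix = paste0("t", target))
      ev <- eval_net(fit$student, tensors, idx_tgt)
      accs <- c(accs, ev$acc)
      if (!is.null(fits_out))
        assign(sprintf("seed%d_subj%d", as.integer(sd), target), fit,
               envir = fits_out)
    }
    per_subject[[as.character(target)]] <- mean(accs)
  }
  new_experiment_result(per_subject,
                        list(net = net_cfg, train = train_cfg, w = w),
                        seeds)
}

#' Ablation study over the loss components
#'
#' Runs [run_loso()] for the five canonical variants: the full model
#' (weights as configured), "wo_inter" (lambda1 = 0: no distillation of
#' internally invariant features), "wo_mutual" (lambda2 = 0: no subdomain
#' alignment), "wo_div" (lambda3 = 0: no divergence regularization), and
#' "wo_general" (all three zero: plain classification). All variants share
#' seeds and consume identical batch streams.
#'
#' @param dataset,net_cfg,train_cfg,seeds,bank As in [run_loso()].
#' @param w Full-model weights (default all 1).
#' @return Named list of \code{experiment_result}s, one per variant, with an
#'   attribute \code{batch_hashes} (named numeric) recording each variant's
#'   batch-stream fingerprint.
#' @export
run_ablation <- function(dataset, net_cfg, train_cfg, w = loss_weights(),
                         seeds = train_cfg$seed,
                         bank = filter_bank(fs = dataset$fs)) {
  variants <- list(
    full = w,
    wo_inter = loss_weights(0, w$lambda2, w$lambda3),
    wo_mutual = loss_weights(w$lambda1, 0, w$lambda3),
    wo_div = loss_weights(w$lambda1, w$lambda2, 0),
    wo_general = loss_weights(0, 0, 0))
  out <- list()
  hashes <- numeric(0)
  teacher_cache <- new.env()   # teacher fits do not depend on the lambdas
  for (nm in names(variants)) {
    fits <- new.env()
    out[[nm]] <- run_loso(dataset, net_cfg, train_cfg, variants[[nm]],
                          seeds, bank, fits_out = fits,
                          teacher_cache = teacher_cache)
    h <- vapply(sort(ls(fits)), function(k) get(k, fits)$batch_hash, 0)
    hashes[nm] <- crc32_raw(writeBin(h, raw()), 0)
  }
  attr(out, "batch_hashes") <- hashes
  out
}

#' Paired significance test between two per-subject accuracy vectors
#'
#' Two-sided paired Wilcoxon signed-rank test (exact for n <= 25, reported
#' as primary) plus a paired t-test. Identical vectors (all differences
#' zero) return p = 1 by policy.
#'
#' @param acc_a,acc_b Named per-subject accuracy vectors over the same
#'   subjects, length >= 3.
#' @return List with \code{p_value} (Wilcoxon), \code{p_wilcoxon},
#'   \code{p_ttest}.
#' @export
paired_test <- function(acc_a, acc_b) {
  if (!is.null(names(acc_a)) && !is.null(names(acc_b))) {
    if (!setequal(names(acc_a), names(acc_b)))
      stop("paired_test: subject sets differ", call. = FALSE)
    acc_b <- acc_b[names(acc_a)]
  } else if (length(acc_a) != length(acc_b)) {
    stop("paired_test: mismatched lengths", call. = FALSE)
  }
  n <- length(acc_a)
  if (n < 3L) stop("paired_test: need n >= 3 pairs", call. = FALSE)
  d <- acc_a - acc_b
  if (all(d == 0)) {
    return(list(p_value = 1, p_wilcoxon = 1, p_ttest = 1))
  }
  wx <- suppressWarnings(stats::wilcox.test(acc_a, acc_b, paired = TRUE,
                                            exact = n <= 25L))
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(p_value = wx$p.value, p_wilcoxon = wx$p.value, p_ttest = tt$p.value)
}

#' Sensitivity sweep over a loss weight or the subdomain count
#'
#' One [run_loso()] per value, everything else held fixed.
#'
#' @param dataset,net_cfg,train_cfg,w,seeds,bank As in [run_loso()].
#' @param parameter One of \code{"lambda1"}, \code{"lambda2"},
#'   \code{"lambda3"}, \code{"k"}.
#' @param values Non-empty numeric vector of parameter values.
#' @param file Optional path; if given, the sweep table (columns
#'   \code{parameter, value, mean, std}) is written as tab-separated text.
#' @return List with \code{table} (data frame) and \code{results} (list of
#'   \code{experiment_result} keyed by value).
#' @export
sweep_parameter <- function(dataset, parameter, values, net_cfg, train_cfg,
                            w = loss_weights(), seeds = train_cfg$seed,
                            bank = filter_bank(fs = dataset$fs),
                            file = NULL) {
  if (!parameter %in% c("lambda1", "lambda2", "lambda3", "k"))
    stop("sweep_parameter: unknown parameter '", parameter, "'",
         call. = FALSE)
  if (length(values) == 0L)
    stop("sweep_parameter: values must be non-empty", call. = FALSE)
  results <- list()
  rows <- list()
  for (v in values) {
    wv <- w; tc <- train_cfg
    if (parameter == "k") tc$n_subdomains <- as.integer(v)
    else wv[[parameter]] <- v
    res <- run_loso(dataset, net_cfg, tc, wv, seeds, bank)
    results[[as.character(v)]] <- res
    rows[[length(rows) + 1L]] <- data.frame(parameter = parameter,
                                            value = v, mean = res$mean,
                                            std = res$std)
  }
  tab <- do.call(rbind, rows)
  if (!is.null(file))
    utils::write.table(tab, file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  list(table = tab, results = results)
}

#' Export per-trial student features for external visualization
#'
#' Feature hook: returns the flattened pre-dense activations (z1 and z2) of
#' every trial, e.g. for embedding with t-SNE/UMAP outside this package.
#'
#' @param student A trained student \code{dg_network}.
#' @param dataset An [eeg_dataset()].
#' @return Data frame with subject, label and one column per feature.
#' @export
export_features <- function(student, dataset) {
  r <- forward_student(student, dataset$X, train_mode = FALSE)
  feats <- cbind(r$z1, r$z2)
  colnames(feats) <- c(paste0("z1_", seq_len(ncol(r$z1))),
                       paste0("z2_", seq_len(ncol(r$z2))))
  cbind(data.frame(subject = dataset$subject, label = dataset$y), feats)
}
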