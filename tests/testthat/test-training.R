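test_that("leave-one-subject-out folds partition the subjects", {
  ds <- generate_dataset(synth_config(n_subjects = 9, n_trials_per_class = 1,
                                      n_classes = 2, n_channels = 3,
                                      n_timepoints = 100, fs = 80, seed = 2))
  folds <- loso_splits(ds)
  expect_length(folds, 9)
  all_subjects <- sort(unique(ds$subject))
  for (f in folds) {
    expect_equal(sort(c(f$source, f$target)), all_subjects)
    expect_false(f$target %in% f$source)
  }
  expect_equal(sort(vapply(folds, `[[`, 0L, "target")), all_subjects)
  one <- eeg_dataset(ds$X[ds$subject == 0, , , drop = FALSE],
                     ds$y[ds$subject == 0],
                     ds$subject[ds$subject == 0], ds$fs)
  expect_error(loso_splits(one), "at least 2")
})

test_that("subdomain grouping balances sizes and is seed-deterministic", {
  g8 <- group_subdomains(0:7, 8, seed = 1)
  expect_length(g8, 8)
  expect_true(all(lengths(g8) == 1))
  g20 <- group_subdomains(1:53, 20, seed = 2)
  expect_length(g20, 20)
  expect_true(all(lengths(g20) %in% c(2, 3)))
  expect_setequal(unlist(g20), 1:53)
  expect_equal(sum(lengths(g20)), 53)   # pairwise disjoint given the union
  expect_identical(group_subdomains(1:10, 3, 7), group_subdomains(1:10, 3, 7))
  expect_error(group_subdomains(1:5, 6, 1), "k must lie")
  expect_error(group_subdomains(1:5, 0, 1), "k must lie")
})

test_that("stratified batches cover every subdomain with at least 2 samples", {
  subject <- rep(0:7, each = 10)
  grouping <- group_subdomains(0:7, 8, 1)
  stream <- make_stratified_batches(subject, grouping, 64, seed = 3)
  expect_length(stream, 1)
  expect_length(stream[[1]], ceiling(80 / 64))
  for (b in stream[[1]]) {
    expect_equal(b$sizes, rep(8L, 8))   # 64 / 8 per subdomain
    counts <- table(factor(subject[b$idx] + 1, levels = 1:8))
    expect_true(all(counts >= 2))
  }
  expect_identical(make_stratified_batches(subject, grouping, 64, seed = 3),
                   stream)
  expect_error(make_stratified_batches(subject, grouping, 15, seed = 1),
               "covariance")
})

test_that("stage-two learning rate switches from 1e-3 to 1e-4 after epoch 150", {
  tc <- train_config()
  expect_equal(lr_stage2(1, tc), 1e-3)
  expect_equal(lr_stage2(150, tc), 1e-3)
  expect_equal(lr_stage2(151, tc), 1e-4)
  expect_equal(lr_stage2(200, tc), 1e-4)
})

test_that("teacher training respects budgets and returns the best checkpoint", {
  ds <- tiny_dataset()
  tr <- which(seq_along(ds$y) %% 4 != 0)
  va <- which(seq_along(ds$y) %% 4 == 0)
  ds_tr <- eeg_dataset(ds$X[tr, , , drop = FALSE], ds$y[tr], ds$subject[tr],
                       ds$fs)
  ds_va <- eeg_dataset(ds$X[va, , , drop = FALSE], ds$y[va], ds$subject[va],
                       ds$fs)
  tc <- tiny_train_config(max_epochs_stage1 = 4)
  res <- train_teacher(ds_tr, ds_va, tiny_net_config(), tc, tiny_bank())
  expect_lte(nrow(res$history), 4)
  expect_true(res$stop_reason %in% c("patience", "max_epochs"))
  expect_lte(res$best_val_loss, min(res$history$val_loss) + 1e-12)
  expect_error(train_teacher(ds_tr, eeg_dataset(ds$X[integer(0), , ,
                                                     drop = FALSE],
                                                integer(0), integer(0),
                                                ds$fs),
                             tiny_net_config(), tc),
               "empty|missing|length")
})

test_that("student training freezes the teacher and logs all components", {
  ds <- tiny_dataset()
  tr <- which(seq_along(ds$y) %% 4 != 0)
  va <- which(seq_along(ds$y) %% 4 == 0)
  ds_tr <- eeg_dataset(ds$X[tr, , , drop = FALSE], ds$y[tr], ds$subject[tr],
                       ds$fs)
  ds_va <- eeg_dataset(ds$X[va, , , drop = FALSE], ds$y[va], ds$subject[va],
                       ds$fs)
  tc <- tiny_train_config()
  tea <- train_teacher(ds_tr, ds_va, tiny_net_config(), tc, tiny_bank())$net
  hash_before <- eegdg:::params_hash(tea$params)
  grouping <- as.list(sort(unique(ds_tr$subject)))
  res <- train_student(tea, ds_tr, ds_va, grouping, tiny_net_config(), tc,
                       loss_weights(0.5, 0.5, 0.01), tiny_bank())
  expect_identical(eegdg:::params_hash(tea$params), hash_before)
  expect_true(all(c("lcls", "lmse", "lalign", "ldiv", "total", "val_loss",
                    "lr") %in% names(res$history)))
  expect_false(anyNA(res$history$lmse))
  expect_error(train_student(tea, ds_tr, ds_va, list(0, 99), tiny_net_config(),
                             tc, loss_weights(), tiny_bank()),
               "unknown|absent")
})

test_that("zero-weight student training equals an independent plain loop", {
  ds <- tiny_dataset()
  tr <- which(seq_along(ds$y) %% 4 != 0)
  va <- which(seq_along(ds$y) %% 4 == 0)
  ds_tr <- eeg_dataset(ds$X[tr, , , drop = FALSE], ds$y[tr], ds$subject[tr],
                       ds$fs)
  ds_va <- eeg_dataset(ds$X[va, , , drop = FALSE], ds$y[va], ds$subject[va],
                       ds$fs)
  tc <- tiny_train_config(max_epochs_stage1 = 3)
  net_cfg <- tiny_net_config()
  tea <- train_teacher(ds_tr, ds_va, net_cfg, tc, tiny_bank())$net
  grouping <- as.list(sort(unique(ds_tr$subject)))
  res <- train_student(tea, ds_tr, ds_va, grouping, net_cfg, tc,
                       loss_weights(0, 0, 0), tiny_bank())
  # reference: hand-written classification-only loop consuming the same
  # initialization, batch stream and dropout stream
  merged <- eeg_dataset(
    eegdg:::abind1(ds_tr$X, ds_va$X), c(ds_tr$y, ds_va$y),
    c(ds_tr$subject, ds_va$subject), ds_tr$fs)
  tens <- eegdg:::prepare_tensors(merged, tiny_bank())
  stream <- make_stratified_batches(
    ds_tr$subject, grouping,
    min(tc$batch_size, max(2L * length(grouping), length(ds_tr$y))),
    eegdg:::derive_seed(tc$seed, "student_batches"), tc$max_epochs_stage1)
  net <- eegdg:::with_seed(eegdg:::derive_seed(tc$seed, "student_init"),
                           build_student(net_cfg))
  adam <- eegdg:::adam_init(net$params)
  idx_val <- length(ds_tr$y) + seq_along(ds_va$y)
  best <- list(loss = Inf)
  eegdg:::with_seed(eegdg:::derive_seed(tc$seed, "student_dropout"), {
    # the DG trainer draws no extra RNG, so trajectories must coincide
    for (ep in 1:3) {
      for (b in stream[[ep]]) {
        fw <- eegdg:::net_forward(net, tens$Xs[, , b$idx, drop = FALSE],
                                  train = TRUE)
        net <- fw$net
        g <- eegdg:::net_backward(net, fw$cache, tens$y[b$idx],
                                  dfeat_extra = matrix(0, nrow(fw$feat),
                                                       ncol(fw$feat)))
        upd <- eegdg:::adam_step(net$params, g, adam, tc$lr_stage1)
        net$params <- eegdg:::apply_maxnorm(upd$params)
        adam <- upd$state
      }
      ev <- eegdg:::eval_net(net, tens, idx_val)
      if (ev$loss < best$loss - 1e-9)
        best <- list(loss = ev$loss, params = net$params)
    }
  })
  expect_equal(res$net$params, best$params, tolerance = 1e-12)
  expect_equal(res$history$total, res$history$lcls)
})

test_that("two-stage fit honors budgets, stop contract and determinism", {
  ds <- tiny_dataset()
  tc <- tiny_train_config(max_epochs_stage1 = 3, max_epochs_stage2 = 2)
  fit <- two_stage_fit(ds, tiny_net_config(), tc, loss_weights(0.1, 0.1, 0.01),
                       tiny_bank())
  expect_s3_class(fit, "dg_fit")
  expect_true(fit$stop_reason %in%
                c("patience", "max_epochs", "below_recorded_loss"))
  h2 <- fit$history[fit$history$stage == 2, ]
  expect_lte(max(h2$epoch), 2)
  expect_lte(max(fit$history$epoch[fit$history$stage == 1]), 3)
  expect_true(is.finite(fit$best_val_loss_stage1))
  if (fit$stop_reason == "below_recorded_loss")
    expect_lt(tail(h2$val_loss, 1), fit$best_val_loss_stage1)
  # bit-identical CPU rerun under the same seeds
  fit2 <- two_stage_fit(ds, tiny_net_config(), tc,
                        loss_weights(0.1, 0.1, 0.01), tiny_bank())
  expect_identical(fit$student$params, fit2$student$params)
  expect_identical(fit$teacher$params, fit2$teacher$params)
  expect_identical(fit$history, fit2$history)
})

test_that("five-fold stage one selects a fold and stays within budget", {
  ds <- tiny_dataset()
  tc <- tiny_train_config(max_epochs_stage1 = 2, max_epochs_stage2 = 1,
                          stage1_mode = "cv", n_folds = 3)
  fit <- two_stage_fit(ds, tiny_net_config(), tc, loss_weights(0, 0, 0),
                       tiny_bank())
  expect_equal(nrow(fit$fold_metrics), 3)
  s1 <- fit$history[fit$history$stage == 1, ]
  expect_lte(nrow(s1), 3 * 2 * 2)   # folds x (teacher + student) x epochs
  expect_true(max(fit$fold_metrics$val_acc) >= 0)
})

test_that("stage-two learning rate in the history follows the schedule", {
  ds <- tiny_dataset()
  tc <- tiny_train_config(max_epochs_stage1 = 2, max_epochs_stage2 = 3,
                          lr_switch_epoch = 1)
  # force stage 2 to run its epochs by making the recorded loss unbeatable
  fit <- two_stage_fit(ds, tiny_net_config(), tc, loss_weights(0, 0, 0),
                       tiny_bank())
  h2 <- fit$history[fit$history$stage == 2, ]
  if (nrow(h2) >= 2) {
    expect_equal(h2$lr[h2$epoch == 1], tc$lr_stage2_early)
    expect_equal(unique(h2$lr[h2$epoch > 1]), tc$lr_stage2_late)
  }
  expect_equal(lr_stage2(1, tc), 1e-3)
  expect_equal(lr_stage2(2, tc), 1e-4)
})

test_that("no target-subject trial enters any training structure", {
  ds <- tiny_dataset()
  folds <- loso_splits(ds)
  for (f in folds) {
    idx_src <- which(ds$subject %in% f$source)
    idx_tgt <- which(ds$subject == f$target)
    expect_length(intersect(idx_src, idx_tgt), 0)
    # the batch stream for the fold's source data references source rows only
    grouping <- as.list(f$source)
    stream <- make_stratified_batches(ds$subject[idx_src], grouping, 12, 1, 2)
    used <- idx_src[unique(unlist(lapply(stream, function(e)
      lapply(e, `[[`, "idx"))))]
    expect_length(intersect(used, idx_tgt), 0)
  }
})
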