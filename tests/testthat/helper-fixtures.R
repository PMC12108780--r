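# Shared fixtures, built once per test run. Everything is generated in code;
# sizes are kept small so the default suite stays fast.

.fixtures <- new.env()

# tiny multi-subject dataset for training-protocol tests: 3 subjects,
# 2 classes, short trials, low sampling rate (bands still < fs/2)
tiny_dataset <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- generate_dataset(synth_config(
      n_subjects = 3, n_trials_per_class = 6, n_classes = 2,
      n_channels = 6, n_timepoints = 200, fs = 80, erd_depth = 0.8,
      subject_shift_scale = 0.5, noise_level = 1, seed = 42))
  }
  .fixtures$tiny
}

tiny_net_config <- function(...) {
  network_config(C = 6, T = 200, Nb = 4, n_classes = 2, F1 = 3, F2 = 2,
                 F3 = 3, C1 = 11, C2 = 7, C3 = 7, dropout_p = 0.25,
                 fs = 80, ...)
}

tiny_train_config <- function(...) {
  args <- utils::modifyList(
    list(batch_size = 12, max_epochs_stage1 = 3, max_epochs_stage2 = 2,
         es_patience = 3, stage1_mode = "single", seed = 5),
    list(...))
  do.call(train_config, args)
}

tiny_bank <- function() {
  if (is.null(.fixtures$bank80)) {
    .fixtures$bank80 <- filter_bank(fs = 80)
  }
  .fixtures$bank80
}

# deterministic random array helper
rand_array <- function(dims, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(prod(dims)), dim = dims)
}
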