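test_that("generated dataset has the configured dimensions and labels", {
  cfg <- synth_config(n_subjects = 4, n_trials_per_class = 20, n_classes = 4,
                      n_channels = 22, n_timepoints = 1000, fs = 250,
                      seed = 1)
  ds <- generate_dataset(cfg)
  expect_equal(dim(ds$X), c(320, 22, 1000))
  expect_equal(length(ds$y), 320)
  expect_equal(sort(unique(ds$y)), 0:3)
  expect_equal(sort(unique(ds$subject)), 0:3)
  expect_equal(as.vector(table(ds$y, ds$subject)), rep(20, 16))
  expect_false(anyNA(ds$X))
})

test_that("same configuration regenerates a bit-identical dataset", {
  cfg <- synth_config(n_subjects = 2, n_trials_per_class = 3, n_classes = 2,
                      n_channels = 4, n_timepoints = 128, fs = 128, seed = 9)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$X, b$X)
  expect_identical(a$y, b$y)
})

test_that("adding subjects does not perturb earlier subjects' data", {
  base <- list(n_trials_per_class = 3, n_classes = 2, n_channels = 4,
               n_timepoints = 128, fs = 128, seed = 9)
  a <- generate_dataset(do.call(synth_config, c(base, n_subjects = 2)))
  b <- generate_dataset(do.call(synth_config, c(base, n_subjects = 3)))
  n_a <- length(a$y)
  expect_identical(a$X, b$X[seq_len(n_a), , , drop = FALSE])
})

test_that("alpha-band ERD contrast is present and statistically detectable", {
  cfg <- synth_config(n_subjects = 2, n_trials_per_class = 20, n_classes = 4,
                      n_channels = 22, n_timepoints = 500, fs = 250,
                      erd_depth = 0.6, seed = 3)
  ds <- generate_dataset(cfg)
  mot <- eegdg:::motor_channels(22)
  alpha <- vapply(seq_along(ds$y), function(i)
    mean(vapply(mot$right, function(ch)
      band_power(ds$X[i, ch, ], ds$fs, c(7, 13)), 0)), 0)
  # class 0 = left-hand imagery: right-hemisphere alpha desynchronization
  expect_lt(mean(alpha[ds$y == 0]), mean(alpha[ds$y != 0]))
  s1 <- ds$subject == 0
  p <- stats::wilcox.test(alpha[s1 & ds$y == 0], alpha[s1 & ds$y == 1])$p.value
  expect_lt(p, 0.01)
})

test_that("subject mixing produces between-subject covariance shift", {
  cfg <- synth_config(n_subjects = 3, n_trials_per_class = 10, n_classes = 2,
                      n_channels = 8, n_timepoints = 250, fs = 125,
                      subject_shift_scale = 0.5, seed = 11)
  ds <- generate_dataset(cfg)
  subj_cov <- function(idx) {
    m <- do.call(cbind, lapply(idx, function(i) ds$X[i, , ]))
    stats::cov(t(m))
  }
  subs <- lapply(0:2, function(s) which(ds$subject == s))
  between <- c()
  within <- c()
  for (s in 1:3) {
    idx <- subs[[s]]
    h1 <- idx[seq_along(idx) %% 2 == 0]
    h2 <- idx[seq_along(idx) %% 2 == 1]
    within <- c(within, sqrt(sum((subj_cov(h1) - subj_cov(h2))^2)))
  }
  for (a in 1:2) for (b in (a + 1):3)
    between <- c(between,
                 sqrt(sum((subj_cov(subs[[a]]) - subj_cov(subs[[b]]))^2)))
  expect_gt(mean(between), mean(within))
})

test_that("band_power matches its closed-form sine expectations", {
  fs <- 250
  t <- seq_len(1000) / fs
  x <- sin(2 * pi * 10 * t)
  total <- band_power(x, fs, c(0.5, 124))
  expect_equal(band_power(rep(0, 256), fs, c(7, 13)), 0)
  expect_gte(band_power(x, fs, c(7, 13)) / total, 0.9)
  expect_lte(band_power(x, fs, c(20, 30)) / total, 0.05)
  expect_error(band_power(x, fs, c(13, 7)), "hi > lo|band")
  expect_error(band_power(x[1:32], fs, c(7, 13)), "64")
})

test_that("invalid synthetic configurations are rejected", {
  expect_error(synth_config(n_subjects = 0), "n_subjects")
  expect_error(synth_config(erd_depth = 1.5), "erd_depth")
  expect_error(synth_config(fs = -1), "fs")
  expect_error(synth_config(noise_level = -0.1), "noise_level")
})

test_that("eeg_dataset enforces its invariants", {
  X <- rand_array(c(4, 3, 100), seed = 2)
  expect_error(eeg_dataset(X, c(0, 1, 0), c(0, 0, 1, 1), 100), "length")
  expect_error(eeg_dataset(X, c(0, 1, 0, 1), c(0, 0, 1), 100), "length")
  Xb <- X; Xb[1, 1, 1] <- NaN
  expect_error(eeg_dataset(Xb, c(0, 1, 0, 1), c(0, 0, 1, 1), 100), "NaN")
  # subject 1 lacks class 0
  expect_error(eeg_dataset(X, c(0L, 1L, 1L, 1L), c(0L, 0L, 1L, 1L), 100),
               "missing")
  ok <- eeg_dataset(X, c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L), 100)
  expect_s3_class(ok, "eeg_dataset")
})
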