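#' Configuration for the synthetic multi-subject motor-imagery EEG generator
#'
#' The generator emulates the statistical structure that cross-subject
#' motor-imagery decoders exploit: class-conditional band-power modulation
#' (event-related desynchronization, ERD) of theta/alpha/beta oscillations
#' over motor channels, a 1/f (pink) plus white background spectrum, and a
#' subject-specific spatial mixing matrix and gain that create domain shift
#' between subjects.
#'
#' The fixed class-to-effect mapping is:
#' \itemize{
#'   \item class 0 ("left hand"): alpha ERD over right-hemisphere motor
#'     channels (contralateral desynchronization);
#'   \item class 1 ("right hand"): alpha ERD over left-hemisphere motor
#'     channels;
#'   \item class 2 ("feet"): beta ERD over both hemispheres;
#'   \item class 3 ("tongue"): theta enhancement over both hemispheres.
#' }
#' With fewer than 4 classes only the first \code{n_classes} effects are used.
#'
#' @param n_subjects Number of subjects (domains).
#' @param n_trials_per_class Trials per class per subject.
#' @param n_classes Number of motor-imagery classes (1--4).
#' @param n_channels Number of EEG channels.
#' @param n_timepoints Samples per trial.
#' @param fs Sampling rate in Hz.
#' @param erd_depth Fractional attenuation of band power in the designated
#'   channels for the affected class, in \[0, 1\]. 0 disables class effects.
#' @param subject_shift_scale Non-negative spread of the per-subject random
#'   spatial mixing perturbation and gain (0 = identical subjects).
#' @param noise_level Non-negative scale of the pink + white background noise.
#' @param seed Integer master seed; the same configuration (including seed)
#'   regenerates a bit-identical dataset.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n_subjects = 4L, n_trials_per_class = 20L,
                         n_classes = 4L, n_channels = 22L,
                         n_timepoints = 500L, fs = 250,
                         erd_depth = 0.8, subject_shift_scale = 0.5,
                         noise_level = 1.0, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_trials_per_class = as.integer(n_trials_per_class),
              n_classes = as.integer(n_classes),
              n_channels = as.integer(n_channels),
              n_timepoints = as.integer(n_timepoints),
              fs = as.numeric(fs),
              erd_depth = as.numeric(erd_depth),
              subject_shift_scale = as.numeric(subject_shift_scale),
              noise_level = as.numeric(noise_level),
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  counts <- c("n_subjects", "n_trials_per_class", "n_classes",
              "n_channels", "n_timepoints")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 1L)
      stop("synth_config: '", f, "' must be a count >= 1", call. = FALSE)
  }
  if (!is.finite(cfg$fs) || cfg$fs <= 0)
    stop("synth_config: 'fs' must be > 0", call. = FALSE)
  if (is.na(cfg$erd_depth) || cfg$erd_depth < 0 || cfg$erd_depth > 1)
    stop("synth_config: 'erd_depth' must lie in [0, 1]", call. = FALSE)
  if (is.na(cfg$subject_shift_scale) || cfg$subject_shift_scale < 0)
    stop("synth_config: 'subject_shift_scale' must be >= 0", call. = FALSE)
  if (is.na(cfg$noise_level) || cfg$noise_level < 0)
    stop("synth_config: 'noise_level' must be >= 0", call. = FALSE)
  if (cfg$n_classes > 4L)
    stop("synth_config: at most 4 classes have a defined effect mapping",
         call. = FALSE)
  invisible(cfg)
}

#' Construct an epoched multi-subject EEG dataset
#'
#' The universal exchange object: trials x channels x timepoints array with
#' integer class labels, integer subject identifiers and a sampling rate.
#'
#' @param X Numeric array \code{[n_trials, n_channels, n_timepoints]}.
#' @param y Integer class labels in \code{[0, n_classes)}, one per trial.
#' @param subject Integer subject identifier per trial.
#' @param fs Sampling rate in Hz.
#' @return An object of class \code{eeg_dataset}.
#' @export
eeg_dataset <- function(X, y, subject, fs) {
  if (length(dim(X)) != 3L)
    stop("eeg_dataset: X must be a 3-d array [trials, channels, timepoints]",
         call. = FALSE)
  y <- as.integer(y); subject <- as.integer(subject)
  if (length(y) != dim(X)[1L])
    stop("eeg_dataset: length(y) must equal the number of trials",
         call. = FALSE)
  if (length(subject) != dim(X)[1L])
    stop("eeg_dataset: length(subject) must equal the number of trials",
         call. = FALSE)
  if (anyNA(X) || any(!is.finite(X)))
    stop("eeg_dataset: X contains NaN or Inf", call. = FALSE)
  if (any(y < 0L))
    stop("eeg_dataset: labels must be non-negative integers", call. = FALSE)
  for (s in unique(subject)) {
    cls <- unique(y[subject == s])
    if (!setequal(cls, unique(y)))
      stop("eeg_dataset: subject ", s,
           " is missing at least one class present in the data",
           call. = FALSE)
  }
  structure(list(X = X, y = y, subject = subject, fs = as.numeric(fs)),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf(
    "eeg_dataset: %d trials, %d channels, %d timepoints @ %g Hz\n",
    d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  subjects: %s; classes: %s\n",
              paste(sort(unique(x$subject)), collapse = " "),
              paste(sort(unique(x$y)), collapse = " ")))
  invisible(x)
}

# Motor channel index sets: a small group on each hemisphere, placed at
# one quarter and three quarters of the montage. Deterministic in C.
motor_channels <- function(n_channels) {
  m <- max(1L, round(n_channels / 8))
  left <- pmin(n_channels, floor(n_channels / 4) + seq_len(m))
  right <- pmin(n_channels, floor(3 * n_channels / 4) + seq_len(m) - 1L)
  list(left = unique(left), right = unique(right))
}

# 1/f-amplitude (pink) noise of length T via spectral shaping.
pink_noise <- function(T) {
  w <- stats::rnorm(T)
  f <- stats::fft(w)
  k <- c(1, seq_len(T - 1))           # avoid div-by-zero at DC
  shaped <- f / sqrt(k)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / T
  x / stats::sd(x)
}

# Band oscillation: sinusoid with small frequency jitter, random phase and a
# smooth random amplitude envelope, so power is band-limited but not a pure
# line.
band_osc <- function(T, fs, f0, jitter = 0.5) {
  f <- f0 + stats::runif(1, -jitter, jitter)
  phase <- stats::runif(1, 0, 2 * pi)
  t <- seq_len(T) / fs
  env <- 1 + 0.2 * sin(2 * pi * stats::runif(1, 0.1, 0.4) * t +
                       stats::runif(1, 0, 2 * pi))
  env * sin(2 * pi * f * t + phase)
}

#' Generate a synthetic multi-subject motor-imagery EEG dataset
#'
#' Each subject's trials are produced as
#' \code{gain_s * M_s \%*\% (oscillations + background noise)} where
#' \code{M_s = I + subject_shift_scale * G} (G standard Gaussian,
#' rows L2-normalized) is the subject's spatial mixing matrix. Oscillatory
#' sources at theta (5 Hz), alpha (10 Hz) and beta (20 Hz) are placed on the
#' motor channel groups, and the class effect attenuates (or, for the theta
#' class, enhances) the relevant band amplitude by \code{erd_depth} according
#' to the mapping documented in [synth_config()]. One master seed spawns an
#' independent per-subject substream, so adding subjects leaves earlier
#' subjects' data unchanged.
#'
#' @param cfg A [synth_config()].
#' @return An [eeg_dataset()] with
#'   \code{n_subjects * n_classes * n_trials_per_class} trials.
#' @export
generate_dataset <- function(cfg) {
  validate_synth_config(cfg)
  C <- cfg$n_channels; T <- cfg$n_timepoints; fs <- cfg$fs
  n_per_subj <- cfg$n_classes * cfg$n_trials_per_class
  n_total <- cfg$n_subjects * n_per_subj
  X <- array(0, dim = c(n_total, C, T))
  y <- integer(n_total); subj <- integer(n_total)
  mot <- motor_channels(C)
  # baseline band amplitudes on motor channels (alpha dominant, as over
  # sensorimotor cortex at rest)
  amp <- c(theta = 1.0, alpha = 2.0, beta = 1.2)
  f0 <- c(theta = 5, alpha = 10, beta = 20)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  row <- 1L
  for (s in seq_len(cfg$n_subjects) - 1L) {
    # independent substream per subject derived from the master seed
    set.seed((cfg$seed %% 100000L) * 10007L + 31L * s)
    G <- matrix(stats::rnorm(C * C), C, C) / sqrt(C)
    M <- diag(C) + cfg$subject_shift_scale * G
    M <- M / sqrt(rowSums(M^2))
    gain <- exp(stats::rnorm(1, 0, 0.2 * cfg$subject_shift_scale))
    for (cls in seq_len(cfg$n_classes) - 1L) {
      for (tr in seq_len(cfg$n_trials_per_class)) {
        S <- matrix(0, C, T)
        for (ch in seq_len(C)) {
          S[ch, ] <- cfg$noise_level *
            (pink_noise(T) + 0.5 * stats::rnorm(T))
        }
        # per-hemisphere band amplitudes for this trial under the class effect
        a <- rbind(left = amp, right = amp)
        att <- 1 - cfg$erd_depth
        if (cls == 0L) a["right", "alpha"] <- a["right", "alpha"] * att
        if (cls == 1L) a["left", "alpha"] <- a["left", "alpha"] * att
        if (cls == 2L) a[, "beta"] <- a[, "beta"] * att
        if (cls == 3L) a[, "theta"] <- a[, "theta"] * (1 + cfg$erd_depth)
        for (hemi in c("left", "right")) {
          chans <- mot[[hemi]]
          for (b in names(f0)) {
            osc <- a[hemi, b] * band_osc(T, fs, f0[[b]])
            S[chans, ] <- S[chans, ] + rep(1, length(chans)) %o% osc
          }
        }
        X[row, , ] <- gain * (M %*% S)
        y[row] <- cls; subj[row] <- s
        row <- row + 1L
      }
    }
  }
  eeg_dataset(X, y, subj, fs)
}

#' Band power of a single signal via Welch's method
#'
#' Integrates a Welch power spectral density estimate (Hann window, 50%
#' overlap) over a frequency band. Serves as the spectral oracle used to
#' verify the class-conditional band-power structure of generated data.
#'
#' @param x Numeric vector (one channel of one trial), length >= 64.
#' @param fs Sampling rate in Hz.
#' @param band Numeric pair \code{c(lo, hi)} in Hz with \code{hi > lo}.
#' @param nperseg Welch segment length (default \code{min(256, length(x))}).
#' @return Non-negative scalar: the PSD integral over \code{[lo, hi]}.
#' @export
band_power <- function(x, fs, band, nperseg = min(256L, length(x))) {
  if (length(band) != 2L || !(band[2L] > band[1L]))
    stop("band_power: band must be c(lo, hi) with hi > lo", call. = FALSE)
  if (length(x) < 64L)
    stop("band_power: need at least 64 samples", call. = FALSE)
  ps <- welch_psd(x, fs, nperseg)
  sel <- ps$freq >= band[1L] & ps$freq <= band[2L]
  df <- ps$freq[2L] - ps$freq[1L]
  sum(ps$psd[sel]) * df
}

# Welch PSD: Hann window, 50% overlap, one-sided density in units^2/Hz.
welch_psd <- function(x, fs, nperseg = min(256L, length(x))) {
  nperseg <- as.integer(nperseg)
  step <- max(1L, nperseg %/% 2L)
  n <- length(x)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / (nperseg + 1)))  # Hann
  U <- sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2 / (fs * U)
    half <- sp[seq_len(nfreq)]
    # double the interior bins to fold negative frequencies in
    if (nperseg %% 2L == 0L) {
      half[2:(nfreq - 1L)] <- 2 * half[2:(nfreq - 1L)]
    } else {
      half[2:nfreq] <- 2 * half[2:nfreq]
    }
    acc <- acc + half
  }
  list(freq = (seq_len(nfreq) - 1L) * fs / nperseg, psd = acc / length(starts))
}
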