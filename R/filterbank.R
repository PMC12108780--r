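#' Construct a Butterworth band-pass filter bank
#'
#' Default bands are the motor-imagery-relevant rhythms: theta (4--7 Hz),
#' alpha (7--13 Hz), beta (13--32 Hz), plus the overall 4--32 Hz band as a
#' broadband view. Band edges are digital half-power (-3 dB) points of an
#' order-\code{order} Butterworth band-pass; filters are applied
#' forward--backward (zero phase) so temporal features are not lag-shifted.
#'
#' @param bands List of \code{c(lo, hi)} pairs in Hz, or a data frame with
#'   columns \code{lo}, \code{hi}. Every edge must satisfy
#'   \code{0 < lo < hi < fs/2}.
#' @param order Butterworth order (default 3).
#' @param fs Sampling rate in Hz.
#' @return An object of class \code{filter_bank} with elements \code{bands}
#'   (data frame \code{lo}, \code{hi}, \code{name}), \code{order}, \code{fs},
#'   and the designed filter coefficients.
#' @export
filter_bank <- function(bands = list(theta = c(4, 7), alpha = c(7, 13),
                                     beta = c(13, 32), overall = c(4, 32)),
                        order = 3L, fs = 250) {
  if (is.data.frame(bands))
    bands <- stats::setNames(
      lapply(seq_len(nrow(bands)), function(i) c(bands$lo[i], bands$hi[i])),
      if (!is.null(bands$name)) bands$name else NULL)
  if (!is.list(bands) || length(bands) < 1L)
    stop("filter_bank: need at least one band", call. = FALSE)
  order <- as.integer(order)
  if (order < 1L) stop("filter_bank: order must be >= 1", call. = FALSE)
  if (!is.finite(fs) || fs <= 0) stop("filter_bank: fs must be > 0",
                                      call. = FALSE)
  nm <- names(bands)
  if (is.null(nm)) nm <- paste0("band", seq_along(bands))
  nm[nm == ""] <- paste0("band", which(nm == ""))
  tab <- data.frame(lo = vapply(bands, `[`, 0, 1L),
                    hi = vapply(bands, `[`, 0, 2L),
                    name = nm, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    if (!(tab$lo[i] > 0 && tab$lo[i] < tab$hi[i] && tab$hi[i] < fs / 2))
      stop("filter_bank: band '", tab$name[i],
           "' violates 0 < lo < hi < fs/2", call. = FALSE)
  }
  filt <- lapply(seq_len(nrow(tab)), function(i)
    signal::butter(order, c(tab$lo[i], tab$hi[i]) / (fs / 2), type = "pass"))
  structure(list(bands = tab, order = order, fs = fs, filters = filt),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("filter_bank: %d band(s), Butterworth order %d, fs = %g Hz\n",
              nrow(x$bands), x$order, x$fs))
  for (i in seq_len(nrow(x$bands)))
    cat(sprintf("  %-8s %g-%g Hz\n", x$bands$name[i], x$bands$lo[i],
                x$bands$hi[i]))
  invisible(x)
}

#' Single-pass frequency response of one band-pass in the bank
#'
#' Evaluates the designed digital filter's transfer function at the requested
#' frequencies (one forward pass; the zero-phase application in
#' [apply_filter_bank()] squares this magnitude).
#'
#' @param bank A [filter_bank()].
#' @param band_index Which band (1-based).
#' @param freqs Frequencies in Hz, all below \code{fs/2}.
#' @return Complex vector of gains at \code{freqs}.
#' @export
frequency_response <- function(bank, band_index, freqs) {
  stopifnot(inherits(bank, "filter_bank"))
  if (band_index < 1L || band_index > nrow(bank$bands))
    stop("frequency_response: band_index out of range", call. = FALSE)
  if (any(freqs < 0) || any(freqs >= bank$fs / 2))
    stop("frequency_response: frequencies must lie in [0, fs/2)",
         call. = FALSE)
  flt <- bank$filters[[band_index]]
  w <- 2 * pi * freqs / bank$fs
  evalpoly <- function(coef, w) {
    k <- seq_along(coef) - 1
    vapply(w, function(wi) sum(coef * exp(-1i * wi * k)), complex(1))
  }
  evalpoly(flt$b, w) / evalpoly(flt$a, w)
}

# Zero-phase filtering of one vector: reflect-pad both ends, filter forward
# and backward, trim. Pad length is three filter lengths, enough for the
# order-3 band-pass transient to decay.
zerophase_filter <- function(flt, x) {
  np <- min(length(x) - 1L, 3L * length(flt$a))
  xp <- c(2 * x[1L] - x[(np + 1L):2L], x, 2 * x[length(x)] -
            x[(length(x) - 1L):(length(x) - np)])
  yf <- signal::filter(flt, xp)
  yb <- rev(signal::filter(flt, rev(yf)))
  yb[(np + 1L):(np + length(x))]
}

#' Apply the filter bank to one epoched trial
#'
#' Decomposes a trial into its sub-bands, producing the fused multi-band
#' representation consumed by the spectral-fusion teacher network: each band
#' is the zero-phase (forward--backward) band-pass of every channel, stacked
#' in bank order.
#'
#' @param X Numeric matrix \code{[channels, timepoints]}, finite.
#' @param bank A [filter_bank()].
#' @return Numeric array \code{[n_bands, channels, timepoints]}.
#' @export
apply_filter_bank <- function(X, bank) {
  stopifnot(inherits(bank, "filter_bank"))
  if (!is.matrix(X)) stop("apply_filter_bank: X must be a matrix [C, T]",
                          call. = FALSE)
  if (anyNA(X) || any(!is.finite(X)))
    stop("apply_filter_bank: X contains NaN or Inf", call. = FALSE)
  C <- nrow(X); T <- ncol(X)
  if (T <= 3L * bank$order)
    stop("apply_filter_bank: T must exceed 3 * order", call. = FALSE)
  Nb <- nrow(bank$bands)
  out <- array(0, dim = c(Nb, C, T))
  for (b in seq_len(Nb)) {
    flt <- bank$filters[[b]]
    for (ch in seq_len(C)) out[b, ch, ] <- zerophase_filter(flt, X[ch, ])
  }
  out
}

# Filter a whole dataset into the time-major multiband tensor (T, C, Nb, n)
# used internally by the teacher; cached by callers that fit many folds.
filter_dataset <- function(dataset, bank) {
  d <- dim(dataset$X)
  n <- d[1L]; C <- d[2L]; T <- d[3L]
  Nb <- nrow(bank$bands)
  out <- array(0, dim = c(T, C, Nb, n))
  for (b in seq_len(Nb)) {
    flt <- bank$filters[[b]]
    for (i in seq_len(n)) {
      for (ch in seq_len(C)) {
        out[, ch, b, i] <- zerophase_filter(flt, dataset$X[i, ch, ])
      }
    }
  }
  out
}
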