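#' Zero-phase band-pass (and optional notch) filtering
#'
#' Applies a zero-phase forward-backward Butterworth band-pass (4th order:
#' two poles per band edge) and, optionally, a 2nd-order notch biquad
#' (quality factor 30) at `notch` Hz.  Zero-phase filtering preserves the
#' temporal position of topographic features, which matters for microstate
#' boundaries.
#'
#' @param rec an [ms_recording].
#' @param band_lo,band_hi band edges in Hz, `0 < band_lo < band_hi < fs/2`.
#' @param notch optional notch frequency in Hz (e.g. 50 for mains), or
#'   `NULL` for none.
#' @return The filtered [ms_recording] (same length; truth labels carried).
#' @examples
#' mon <- montage_1010_64()
#' tpl <- canonical_templates(mon)
#' rec <- render_eeg(rep(1L, 1000), tpl, fs = 500, snr = Inf, montage = mon)
#' out <- filter_recording(rec, 2, 20)
#' dim(out$data)
#' @export
filter_recording <- function(rec, band_lo, band_hi, notch = NULL) {
  stopifnot(inherits(rec, "ms_recording"))
  fs <- rec$fs
  if (!(band_lo > 0 && band_lo < band_hi)) .stopf("need 0 < band_lo < band_hi")
  if (band_hi >= fs / 2)
    .stopf("band_hi (%.1f Hz) must be below the Nyquist frequency (%.1f Hz)", band_hi, fs / 2)
  bf <- signal::butter(2, c(band_lo, band_hi) / (fs / 2), type = "pass")
  X <- t(apply(rec$data, 1, function(ch) signal::filtfilt(bf, ch)))
  if (!is.null(notch)) {
    if (notch >= fs / 2) .stopf("notch frequency must be below Nyquist")
    w0 <- 2 * pi * notch / fs
    alpha <- sin(w0) / (2 * 30)            # Q = 30
    b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
    a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
    X <- t(apply(X, 1, function(ch) signal::filtfilt(b, a, ch)))
  }
  ms_recording(X, fs = fs, montage = rec$montage, truth_labels = rec$truth_labels)
}

#' Resample a recording to a lower rate
#'
#' Anti-aliased downsampling.  Integer decimation factors use an IIR
#' decimator; rational factors fall back to polyphase resampling.  The new
#' length is `round(T * target_fs / fs)`.  Upsampling is not supported.
#'
#' @param rec an [ms_recording].
#' @param target_fs target sampling rate (Hz), at most `rec$fs`.
#' @return The resampled [ms_recording]; truth labels are carried over by
#'   nearest-sample mapping.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "ms_recording"))
  fs <- rec$fs
  if (target_fs > fs) .stopf("upsampling not supported (%.0f -> %.0f Hz)", fs, target_fs)
  if (target_fs == fs) return(rec)
  n_old <- ncol(rec$data)
  n_new <- round(n_old * target_fs / fs)
  q <- fs / target_fs
  if (abs(q - round(q)) < 1e-9) {
    q <- as.integer(round(q))
    X <- t(apply(rec$data, 1, function(ch) signal::decimate(ch, q)))
  } else {
    gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
    p <- round(target_fs * 1000); qq <- round(fs * 1000)
    g <- gcd(p, qq)
    X <- t(apply(rec$data, 1, function(ch) signal::resample(ch, p / g, qq / g)))
  }
  if (ncol(X) > n_new) X <- X[, seq_len(n_new), drop = FALSE]
  if (ncol(X) < n_new) X <- cbind(X, X[, rep(ncol(X), n_new - ncol(X)), drop = FALSE])
  tl <- NULL
  if (!is.null(rec$truth_labels)) {
    idx <- pmin(n_old, floor((seq_len(n_new) - 1) * fs / target_fs) + 1L)
    tl <- rec$truth_labels[idx]
  }
  ms_recording(X, fs = target_fs, montage = rec$montage, truth_labels = tl)
}

#' Cut a recording into average-referenced epochs
#'
#' Takes the first `n_epochs` contiguous, non-overlapping epochs of
#' `epoch_length_s` seconds in temporal order and re-references every
#' sample to the instantaneous channel mean (common average reference).
#'
#' @param rec an [ms_recording].
#' @param epoch_length_s epoch length in seconds (default 2).
#' @param n_epochs number of epochs; default as many as fit.
#' @return An object of class `ms_epochs`: list with `epochs`
#'   (E x C x S array), `fs`, `epoch_length_s`, `montage`, and
#'   `truth_labels` (length E*S) when present in the input.
#' @export
epoch_recording <- function(rec, epoch_length_s = 2, n_epochs = NULL) {
  stopifnot(inherits(rec, "ms_recording"))
  s <- round(epoch_length_s * rec$fs)
  avail <- ncol(rec$data) %/% s
  if (is.null(n_epochs)) n_epochs <- avail
  if (n_epochs > avail)
    .stopf("requested %d epochs of %.3g s but only %d are available", n_epochs, epoch_length_s, avail)
  if (n_epochs < 1) .stopf("need at least one epoch")
  C <- nrow(rec$data)
  X <- rec$data[, seq_len(n_epochs * s), drop = FALSE]
  X <- sweep(X, 2, colMeans(X))            # common average reference per sample
  ep <- array(0, dim = c(n_epochs, C, s))
  for (e in seq_len(n_epochs))
    ep[e, , ] <- X[, ((e - 1) * s + 1):(e * s)]
  tl <- if (!is.null(rec$truth_labels)) rec$truth_labels[seq_len(n_epochs * s)] else NULL
  structure(list(epochs = ep, fs = rec$fs, epoch_length_s = epoch_length_s,
                 montage = rec$montage, truth_labels = tl),
            class = "ms_epochs")
}

#' @export
print.ms_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("Epoched EEG: %d epochs x %d channels x %d samples (%g s at %g Hz)\n",
              d[1], d[2], d[3], x$epoch_length_s, x$fs))
  invisible(x)
}

# flatten epochs to a (E*S) x C sample matrix, epoch-major in time
.epochs_to_samples <- function(epochs) {
  d <- dim(epochs$epochs)
  out <- matrix(0, d[1] * d[3], d[2])
  for (e in seq_len(d[1]))
    out[((e - 1) * d[3] + 1):(e * d[3]), ] <- t(epochs$epochs[e, , ])
  out
}

#' Flag epochs by amplitude threshold
#'
#' Pass-through artifact hook: returns the indices of epochs whose maximum
#' absolute amplitude exceeds `threshold` (in the recording's units).
#' With `threshold = Inf` (the default) no epoch is flagged; synthetic data
#' generated by this package is artifact-free by construction.
#'
#' @param epochs an `ms_epochs`.
#' @param threshold amplitude threshold; `Inf` disables flagging.
#' @return Integer vector of flagged epoch indices (possibly empty).
#' @export
flag_epochs <- function(epochs, threshold = Inf) {
  stopifnot(inherits(epochs, "ms_epochs"))
  mx <- apply(abs(epochs$epochs), 1, max)
  which(mx > threshold)
}
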