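#' Synthetic EEG recording container
#'
#' Holds a C x T data matrix (microvolt scale), the sampling rate, the
#' montage, and optionally the ground-truth per-sample class sequence for
#' synthetic data.
#'
#' @param data numeric C x T matrix (channels x samples), all finite.
#' @param fs sampling rate in Hz.
#' @param montage an [ms_montage] whose channels match `nrow(data)`.
#' @param truth_labels optional integer vector of length T with values 1..4.
#' @return An object of class `ms_recording`.
#' @export
ms_recording <- function(data, fs, montage, truth_labels = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) .stopf("recording data must be finite")
  if (!is.numeric(fs) || fs <= 0) .stopf("fs must be positive")
  stopifnot(inherits(montage, "ms_montage"))
  if (nrow(data) != nrow(montage))
    .stopf("data has %d channels but montage has %d", nrow(data), nrow(montage))
  if (!is.null(truth_labels)) {
    if (length(truth_labels) != ncol(data))
      .stopf("truth_labels length (%d) does not match sample count (%d)",
             length(truth_labels), ncol(data))
    if (!all(truth_labels %in% 1:4))
      .stopf("truth_labels must take values in 1..4 (classes A-D)")
  }
  rownames(data) <- montage$name
  structure(list(data = data, fs = fs, montage = montage,
                 truth_labels = truth_labels),
            class = "ms_recording")
}

#' @export
print.ms_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples (%.1f s at %g Hz)%s\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs,
              if (is.null(x$truth_labels)) "" else ", with ground-truth labels"))
  invisible(x)
}

#' Render a multichannel EEG from a class sequence
#'
#' Produces `data(t) = a(t) * T[label(t), ] + noise(t)`, where `a(t)` is a
#' phase-continuous 10 Hz sinusoid scaled to unit mean absolute amplitude.
#' The resulting global field power waveform is a rectified 10 Hz sinusoid
#' with peaks every 50 ms; because class assignment is polarity-invariant,
#' the sign of the carrier is immaterial for all downstream analysis, while
#' keeping the carrier signed concentrates the signal's spectral content at
#' 10 Hz, inside the 2-20 Hz microstate analysis band.
#'
#' Noise is spatially white Gaussian, re-referenced to the common average at
#' every sample, and scaled so that mean signal GFP / mean noise GFP equals
#' `snr`.  Use `snr = Inf` for noise-free data.
#'
#' @param labels integer class sequence (1..4), e.g. from
#'   [sample_state_sequence()].
#' @param templates an `ms_templates` (4 x C) from [canonical_templates()].
#' @param fs sampling rate in Hz.
#' @param snr ratio of mean signal GFP to mean noise GFP (> 0, may be `Inf`).
#' @param seed integer seed for the noise draw.
#' @param montage the montage carried into the recording; defaults to the
#'   one matching `ncol(templates)` channels of [montage_1010_64()] when the
#'   counts agree, otherwise must be supplied.
#' @param carrier_hz carrier frequency (default 10).
#' @return An [ms_recording] with `truth_labels` set.
#' @examples
#' mon <- montage_1010_64()
#' tpl <- canonical_templates(mon)
#' rec <- render_eeg(rep(1:4, each = 250), tpl, fs = 500, snr = Inf,
#'                   seed = 1, montage = mon)
#' max(abs(colMeans(rec$data)))  # average-referenced at every sample
#' @export
render_eeg <- function(labels, templates, fs, snr, seed = 1,
                       montage = NULL, carrier_hz = 10) {
  labels <- as.integer(labels)
  if (!all(labels %in% 1:4)) .stopf("labels must take values 1..4")
  if (!is.numeric(snr) || snr <= 0) .stopf("snr must be positive")
  tpl <- as.matrix(templates)
  if (nrow(tpl) != 4L) .stopf("templates must have 4 rows")
  if (is.null(montage)) {
    montage <- montage_1010_64()
    if (nrow(montage) != ncol(tpl))
      .stopf("templates have %d channels; supply the matching montage", ncol(tpl))
  }
  if (nrow(montage) != ncol(tpl))
    .stopf("template channel count (%d) does not match montage (%d)",
           ncol(tpl), nrow(montage))
  n <- length(labels)
  # half-sample phase offset: carrier zero-crossings (microstate boundaries)
  # fall between samples, so no sample carries an exactly vanishing field
  a <- sin(2 * pi * carrier_hz * (seq_len(n) - 0.5) / fs)
  a <- a / mean(abs(a))
  S <- tpl[labels, , drop = FALSE] * a           # n x C
  if (is.finite(snr)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sig_gfp <- mean(sqrt(rowMeans(.avg_ref_rows(S)^2)))
    E <- matrix(stats::rnorm(n * ncol(tpl)), n, ncol(tpl))
    E <- .avg_ref_rows(E)
    E <- E * (sig_gfp / snr) / mean(sqrt(rowMeans(E^2)))
    S <- S + E
  }
  ms_recording(t(S), fs = fs, montage = montage, truth_labels = labels)
}
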