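#' Semi-Markov specification of microstate dynamics
#'
#' Describes the generative law of a four-class microstate sequence: the
#' embedded (jump) chain between classes, the stationary probability that a
#' segment belongs to each class, and per-class mean segment durations.
#' Segment lengths follow a gamma law with a common shape parameter, so the
#' mean is planted exactly while durations keep a realistic right-skewed
#' spread.
#'
#' `segment_weights` must be the stationary distribution of
#' `embedded_transitions` (checked to within 0.02 at construction); this is
#' what makes long-run class frequencies, coverages and joint transition
#' percentages mutually consistent.
#'
#' @param mean_durations numeric(4), per-class mean segment duration in ms
#'   (all positive).
#' @param embedded_transitions 4 x 4 row-stochastic matrix with zero
#'   diagonal: probability that a segment of class i is followed by class j.
#' @param segment_weights numeric(4) summing to 1; defaults to the
#'   stationary distribution of `embedded_transitions`.
#' @param duration_shape gamma shape of the segment-length law (default 2).
#' @return An object of class `semi_markov_spec`.
#' @examples
#' sp <- semi_markov_spec(c(65, 65, 61, 64),
#'                        matrix(c(0, 1, 1, 1,
#'                                 1, 0, 1, 1,
#'                                 1, 1, 0, 1,
#'                                 1, 1, 1, 0) / 3, 4, byrow = TRUE))
#' sp$segment_weights
#' @export
semi_markov_spec <- function(mean_durations, embedded_transitions,
                             segment_weights = NULL, duration_shape = 2) {
  mean_durations <- as.numeric(mean_durations)
  if (length(mean_durations) != 4L || any(!is.finite(mean_durations)) ||
      any(mean_durations <= 0))
    .stopf("mean_durations must be 4 positive values (ms)")
  P <- as.matrix(embedded_transitions)
  if (!identical(dim(P), c(4L, 4L)) || any(!is.finite(P)) || any(P < 0))
    .stopf("embedded_transitions must be a non-negative 4 x 4 matrix")
  if (any(abs(diag(P)) > 1e-12))
    .stopf("embedded_transitions must have a zero diagonal (no self-transitions between segments)")
  if (any(abs(rowSums(P) - 1) > 1e-8))
    .stopf("embedded_transitions rows must sum to 1")
  statw <- stationary_distribution(P)
  if (is.null(segment_weights)) {
    segment_weights <- statw
  } else {
    segment_weights <- as.numeric(segment_weights)
    if (length(segment_weights) != 4L || any(segment_weights < 0) ||
        abs(sum(segment_weights) - 1) > 1e-8)
      .stopf("segment_weights must be 4 non-negative values summing to 1")
    if (max(abs(segment_weights - statw)) > 0.02)
      .stopf(paste("segment_weights deviate from the stationary distribution of",
                   "embedded_transitions by more than 0.02 (max deviation %.3f)"),
             max(abs(segment_weights - statw)))
  }
  if (!is.numeric(duration_shape) || duration_shape <= 0)
    .stopf("duration_shape must be positive")
  structure(list(mean_durations = mean_durations,
                 segment_weights = segment_weights,
                 embedded_transitions = unname(P),
                 duration_shape = duration_shape),
            class = "semi_markov_spec")
}

#' Stationary distribution of a transition matrix
#'
#' @param P a row-stochastic matrix.
#' @return The left eigenvector of eigenvalue 1, normalised to sum to 1.
#' @export
stationary_distribution <- function(P) {
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v / sum(v)
}

#' @export
print.semi_markov_spec <- function(x, ...) {
  cat("Semi-Markov microstate dynamics\n")
  cat("  mean durations (ms):", paste(sprintf("%s=%.2f", MS_CLASSES, x$mean_durations),
                                      collapse = " "), "\n")
  cat("  segment weights    :", paste(sprintf("%.3f", x$segment_weights), collapse = " "), "\n")
  cat("  duration shape     :", x$duration_shape, "\n")
  invisible(x)
}

# gamma mean that yields an exact target mean after probabilistic rounding of
# segment lengths to the alignment lattice with a floor of one lattice step
.calibrate_gamma_mean <- function(target_ms, align_ms, shape) {
  if (target_ms < align_ms)
    .stopf("mean duration %.1f ms is below the boundary lattice of %.1f ms", target_ms, align_ms)
  if (target_ms == align_ms) return(align_ms * 1e-6)  # degenerate: every run is one step
  f <- function(m) {
    sc <- m / shape
    # E[max(1, R)] with R the probabilistic rounding of L/align, L ~ gamma:
    # E[R] = m/align ; P(R = 0) = E[(1 - L/align) 1{L < align}]
    p0 <- stats::pgamma(align_ms, shape, scale = sc) -
      (m / align_ms) * stats::pgamma(align_ms, shape + 1, scale = sc)
    (m / align_ms + p0) * align_ms - target_ms
  }
  stats::uniroot(f, c(target_ms / 10, target_ms * 2), tol = 1e-10)$root
}

#' Sample a microstate class sequence
#'
#' Draws a per-sample sequence of classes 1..4 from a [semi_markov_spec]:
#' successive segment classes follow the embedded chain, and each segment's
#' length is drawn from a gamma law with the class's planted mean.
#'
#' Segment boundaries are aligned to a temporal lattice (`align_ms`,
#' default 50 ms = the half-period of the 10 Hz carrier used by
#' [render_eeg()]), mirroring the empirical observation that microstate
#' transitions coincide with polarity reversals of the dominant rhythm,
#' i.e. with troughs of the global field power.  Gamma draws are rounded to
#' the lattice probabilistically and the gamma mean is internally calibrated
#' so the planted per-class mean duration is preserved exactly.  Set
#' `align_ms = 0` for free (unaligned) gamma durations.
#'
#' @param spec a [semi_markov_spec].
#' @param length_s recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed; the draw is fully reproducible.
#' @param align_ms boundary lattice in ms (0 disables alignment).
#' @return Integer vector of length `round(length_s * fs)` with values 1..4
#'   (classes A-D).
#' @examples
#' sp <- semi_markov_spec(c(65, 65, 61, 64),
#'                        matrix(c(0, 1, 1, 1, 1, 0, 1, 1,
#'                                 1, 1, 0, 1, 1, 1, 1, 0) / 3, 4, byrow = TRUE))
#' labs <- sample_state_sequence(sp, length_s = 2, fs = 500, seed = 1)
#' table(labs)
#' @export
sample_state_sequence <- function(spec, length_s, fs, seed = 1, align_ms = 50) {
  stopifnot(inherits(spec, "semi_markov_spec"))
  if (!is.numeric(length_s) || length_s <= 0) .stopf("length_s must be positive")
  if (!is.numeric(fs) || fs <= 0) .stopf("fs must be positive")
  if (fs * min(spec$mean_durations) / 1000 < 2)
    .stopf("shortest mean duration (%.1f ms) is unresolvable at %.0f Hz (< 2 samples)",
           min(spec$mean_durations), fs)
  n <- round(length_s * fs)
  shape <- spec$duration_shape
  use_lattice <- align_ms > 0
  if (use_lattice) {
    hw <- fs * align_ms / 1000
    if (abs(hw - round(hw)) > 1e-9)
      .stopf("align_ms (%.1f) must be an integer number of samples at %.0f Hz", align_ms, fs)
    hw <- as.integer(round(hw))
    mcal <- vapply(spec$mean_durations, .calibrate_gamma_mean,
                   numeric(1), align_ms = align_ms, shape = shape)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  labels <- integer(n)
  t <- 0L
  cur <- sample.int(4L, 1L, prob = spec$segment_weights)
  while (t < n) {
    if (use_lattice) {
      L <- stats::rgamma(1, shape = shape, scale = mcal[cur] / shape) / align_ms
      k <- floor(L) + stats::rbinom(1, 1, L - floor(L))
      len <- max(1L, as.integer(k)) * hw
    } else {
      m <- spec$mean_durations[cur] * fs / 1000
      len <- max(1L, as.integer(round(stats::rgamma(1, shape = shape, scale = m / shape))))
    }
    labels[(t + 1L):min(n, t + len)] <- cur
    t <- t + len
    cur <- sample.int(4L, 1L, prob = spec$embedded_transitions[cur, ])
  }
  labels
}
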