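#' Back-fit microstate maps to every sample
#'
#' Assigns each sample of an epoched recording to one of the fitted maps,
#' independently within epochs, using polarity-invariant spatial
#' correlation.  Two labelling conventions are available:
#'
#' * `method = "sample"`: instantaneous assignment,
#'   `label(t) = argmax_k |r(v(t), m_k)|`, ties to the lowest map index.
#'   Samples with (numerically) zero spatial variance inherit the previous
#'   sample's label (leading zero-variance samples get map 1).  Exact in
#'   the noise-free limit, but fragile at GFP troughs, where the field
#'   passes through a polarity reversal and the topography is undefined.
#' * `method = "peaks"` (the convention used by the pipeline): assignment
#'   is computed at GFP peaks only, and every sample inherits the label of
#'   its nearest GFP peak within the epoch (ties toward the earlier peak).
#'   This is the standard segmentation convention for spontaneous EEG:
#'   microstate boundaries are placed at GFP troughs, where class
#'   membership genuinely changes.
#'
#' @param epochs an `ms_epochs` (average-referenced).
#' @param maps a k x C matrix of unit-norm maps (rows), e.g.
#'   `coef(microstate_fit(...))` or labelled group maps.
#' @param method `"sample"` or `"peaks"`.
#' @param min_sep_ms peak separation for `method = "peaks"`.
#' @return An object of class `ms_labels`: list with `labels` (integer per
#'   sample over concatenated epochs), `epoch_length` (samples), `n_epochs`,
#'   `fs`, `k`, and `abs_cor` (samples x k matrix of absolute spatial
#'   correlations, used by [smooth_labels()]).
#' @examples
#' mon <- montage_1010_64()
#' tpl <- canonical_templates(mon)
#' rec <- render_eeg(rep(c(1L, 2L), each = 500), tpl, fs = 500, snr = Inf,
#'                   montage = mon)
#' ep <- epoch_recording(rec, 2)
#' bf <- backfit(ep, tpl, method = "sample")
#' all(bf$labels == rec$truth_labels)
#' @export
backfit <- function(epochs, maps, method = c("sample", "peaks"),
                    min_sep_ms = 10) {
  stopifnot(inherits(epochs, "ms_epochs"))
  method <- match.arg(method)
  maps <- .unit_rows(.avg_ref_rows(as.matrix(maps)))
  d <- dim(epochs$epochs)
  if (ncol(maps) != d[2])
    .stopf("maps have %d channels, epochs have %d", ncol(maps), d[2])
  m <- .epochs_to_samples(epochs)
  S <- d[3]; ne <- d[1]
  nrm <- sqrt(rowSums(m^2))
  pr <- m %*% t(maps)
  ac <- abs(pr) / pmax(nrm, .Machine$double.xmin)
  k <- nrow(maps)
  if (method == "sample") {
    lab <- max.col(ac, ties.method = "first")
    zero <- nrm < max(nrm) * 1e-12
    if (any(zero)) {
      for (e in seq_len(ne)) {
        off <- (e - 1L) * S
        for (i in which(zero[(off + 1):(off + S)]))
          lab[off + i] <- if (i > 1) lab[off + i - 1L] else 1L
      }
    }
  } else {
    g <- sqrt(rowMeans(m^2))
    sep <- max(1L, ceiling(min_sep_ms / 1000 * epochs$fs))
    lab <- integer(nrow(m))
    for (e in seq_len(ne)) {
      off <- (e - 1L) * S
      pk <- .local_peaks(g[(off + 1):(off + S)], sep)
      if (!length(pk)) .stopf("no GFP peaks in epoch %d", e)
      pl <- max.col(ac[off + pk, , drop = FALSE], ties.method = "first")
      li <- findInterval(seq_len(S), pk)
      left <- ifelse(li >= 1L, pk[pmax(li, 1L)], NA_integer_)
      right <- pk[pmin(li + 1L, length(pk))]
      pick <- ifelse(is.na(left), right,
                     ifelse(seq_len(S) - left <= right - seq_len(S), left, right))
      lab[off + seq_len(S)] <- pl[match(pick, pk)]
    }
  }
  structure(list(labels = lab, epoch_length = S, n_epochs = ne,
                 fs = epochs$fs, k = k, abs_cor = ac),
            class = "ms_labels")
}

#' @export
print.ms_labels <- function(x, ...) {
  cat(sprintf("Microstate label series: %d epochs x %d samples at %g Hz\n",
              x$n_epochs, x$epoch_length, x$fs))
  print(round(100 * table(factor(x$labels, seq_len(x$k),
                                 MS_CLASSES[seq_len(x$k)])) / length(x$labels), 1))
  invisible(x)
}

# run-length encoding per epoch: data.frame(epoch, class, length, truncated)
.epoch_runs <- function(series) {
  S <- series$epoch_length
  out <- vector("list", series$n_epochs)
  for (e in seq_len(series$n_epochs)) {
    r <- rle(series$labels[((e - 1) * S + 1):(e * S)])
    nr <- length(r$values)
    out[[e]] <- data.frame(epoch = e, class = r$values, length = r$lengths,
                           truncated = seq_len(nr) %in% c(1L, nr))
  }
  do.call(rbind, out)
}

#' Absorb runs shorter than a duration threshold
#'
#' Temporal smoothing by short-segment rejection: any run shorter than
#' `min_duration_ms` is dissolved, each of its samples being reassigned to
#' whichever of the two flanking runs' classes has the higher absolute
#' spatial correlation at that sample; this repeats until no run violates
#' the threshold.  `min_duration_ms = 0` is the identity.
#'
#' @param series an `ms_labels` from [backfit()].
#' @param min_duration_ms minimum admissible run duration in ms.
#' @return The smoothed `ms_labels`.
#' @export
smooth_labels <- function(series, min_duration_ms) {
  stopifnot(inherits(series, "ms_labels"))
  if (min_duration_ms < 0) .stopf("min_duration_ms must be non-negative")
  if (min_duration_ms == 0) return(series)
  min_len <- ceiling(min_duration_ms / 1000 * series$fs)
  if (min_len > series$epoch_length)
    .stopf("threshold (%g ms) exceeds the epoch length", min_duration_ms)
  S <- series$epoch_length
  lab <- series$labels
  ac <- series$abs_cor
  for (e in seq_len(series$n_epochs)) {
    off <- (e - 1L) * S
    le <- lab[(off + 1):(off + S)]
    repeat {
      r <- rle(le)
      nr <- length(r$values)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      bad <- which(r$lengths < min_len)
      if (!length(bad) || nr == 1L) break
      i <- bad[which.min(r$lengths[bad])]
      cand <- unique(c(if (i > 1) r$values[i - 1L], if (i < nr) r$values[i + 1L]))
      for (s in starts[i]:ends[i]) {
        le[s] <- cand[which.max(ac[off + s, cand])]
      }
    }
    lab[(off + 1):(off + S)] <- le
  }
  out <- series
  out$labels <- lab
  out
}

#' Temporal microstate parameters
#'
#' Computes, per class: mean duration (ms), occurrence (runs per second of
#' analysis time) and time coverage (percent of samples).  Runs are
#' computed within epochs (no run spans an epoch boundary).  With
#' `exclude_truncated = FALSE` (default) the identity
#' `occurrence * duration(s) = coverage/100` holds exactly; with
#' `TRUE`, runs touching an epoch boundary are dropped from the duration
#' and occurrence statistics (coverage is unaffected).
#'
#' A class absent from the series gets `NA` duration and zero occurrence
#' and coverage.
#'
#' @param series an `ms_labels`.
#' @param exclude_truncated drop epoch-boundary runs from duration and
#'   occurrence?
#' @return A data frame with one row per class: `class`, `duration_ms`,
#'   `occurrence_per_s`, `coverage_pct`.
#' @export
compute_parameters <- function(series, exclude_truncated = FALSE) {
  stopifnot(inherits(series, "ms_labels"))
  runs <- .epoch_runs(series)
  total_s <- series$n_epochs * series$epoch_length / series$fs
  total_n <- series$n_epochs * series$epoch_length
  kk <- seq_len(series$k)
  dur_runs <- if (exclude_truncated) runs[!runs$truncated, ] else runs
  out <- data.frame(
    class = MS_CLASSES[kk],
    duration_ms = vapply(kk, function(j) {
      l <- dur_runs$length[dur_runs$class == j]
      if (!length(l)) NA_real_ else mean(l) * 1000 / series$fs
    }, numeric(1)),
    occurrence_per_s = vapply(kk, function(j)
      sum(dur_runs$class == j) / total_s, numeric(1)),
    coverage_pct = vapply(kk, function(j)
      100 * sum(runs$length[runs$class == j]) / total_n, numeric(1)),
    stringsAsFactors = FALSE
  )
  out
}

#' Transition-syntax percentages
#'
#' Counts every ordered change between consecutive runs within an epoch
#' (changes across epoch boundaries are not counted) and normalises the 12
#' ordered-pair counts jointly to sum to 100.
#'
#' @param series an `ms_labels` with 4 classes.
#' @return A data frame with columns `from`, `to`, `percent` (12 rows).
#' @export
compute_transitions <- function(series) {
  stopifnot(inherits(series, "ms_labels"))
  runs <- .epoch_runs(series)
  counts <- matrix(0, 4, 4)
  for (e in unique(runs$epoch)) {
    v <- runs$class[runs$epoch == e]
    if (length(v) > 1)
      for (i in seq_len(length(v) - 1L))
        counts[v[i], v[i + 1L]] <- counts[v[i], v[i + 1L]] + 1
  }
  if (sum(counts) == 0) .stopf("no transitions in the label series")
  pct <- counts / sum(counts) * 100
  idx <- which(diag(4) == 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), ]
  data.frame(from = MS_CLASSES[idx[, 1]], to = MS_CLASSES[idx[, 2]],
             percent = pct[idx], stringsAsFactors = FALSE)
}
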