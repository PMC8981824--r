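#' Global field power
#'
#' GFP(t) is the spatial standard deviation of the scalp potential across
#' channels at sample t:
#' `sqrt(mean((v_c(t) - mean_c v(t))^2))`.
#'
#' @param x an `ms_epochs` (GFP is computed per epoch and concatenated), an
#'   [ms_recording], or a samples x channels matrix.
#' @return A numeric vector of non-negative GFP values with attribute `fs`
#'   when the input carries a sampling rate.
#' @examples
#' compute_gfp(matrix(c(1, -1), 1))        # 1
#' compute_gfp(matrix(c(2, 0, -2, 0), 1))  # sqrt(2)
#' @export
compute_gfp <- function(x) {
  if (inherits(x, "ms_epochs")) {
    m <- .epochs_to_samples(x)
    fs <- x$fs
  } else if (inherits(x, "ms_recording")) {
    m <- t(x$data)
    fs <- x$fs
  } else {
    m <- as.matrix(x)
    fs <- NULL
  }
  if (!all(is.finite(m))) .stopf("non-finite values in input")
  g <- sqrt(rowMeans(.avg_ref_rows(m)^2))
  if (!is.null(fs)) attr(g, "fs") <- fs
  g
}

# strict local maxima of g with a minimum separation (in samples);
# ties and conflicts resolved toward the larger peak, then the earlier sample
.local_peaks <- function(g, sep) {
  n <- length(g)
  if (n < 3) return(integer(0))
  loc <- which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] > g[3:n]) + 1L
  if (!length(loc) || sep <= 1) return(loc)
  ord <- loc[order(-g[loc], loc)]
  acc <- integer(0)
  for (p in ord)
    if (!length(acc) || min(abs(acc - p)) >= sep) acc <- c(acc, p)
  sort(acc)
}

#' Topographies at GFP peaks
#'
#' Finds strict local maxima of the GFP within each epoch (peaks never span
#' epoch boundaries), enforcing a minimum inter-peak separation of
#' `min_sep_ms` (conflicts resolved in favour of the larger peak, ties
#' toward the earlier sample), and extracts the topography at each peak.
#'
#' @param epochs an `ms_epochs`.
#' @param min_sep_ms minimum inter-peak separation in ms (default 10).
#' @return An object of class `ms_peaks`: list with `topographies` (P x C,
#'   average-referenced), `peak_gfp` (length P), `peak_indices` (global
#'   sample indices over the concatenated epochs), `epoch` (epoch index per
#'   peak), `fs`, and `n_samples`.
#' @export
find_gfp_peaks <- function(epochs, min_sep_ms = 10) {
  stopifnot(inherits(epochs, "ms_epochs"))
  d <- dim(epochs$epochs)
  S <- d[3]
  if (S < 3) .stopf("need at least 3 samples per epoch")
  sep <- max(1L, ceiling(min_sep_ms / 1000 * epochs$fs))
  m <- .epochs_to_samples(epochs)
  g <- sqrt(rowMeans(.avg_ref_rows(m)^2))
  idx <- integer(0); epk <- integer(0)
  for (e in seq_len(d[1])) {
    ge <- g[((e - 1) * S + 1):(e * S)]
    pk <- .local_peaks(ge, sep)
    idx <- c(idx, pk + (e - 1L) * S)
    epk <- c(epk, rep(e, length(pk)))
  }
  if (!length(idx)) .stopf("no GFP peaks found")
  topo <- .avg_ref_rows(m[idx, , drop = FALSE])
  if (!is.null(epochs$montage)) colnames(topo) <- epochs$montage$name
  structure(list(topographies = topo, peak_gfp = g[idx], peak_indices = idx,
                 epoch = epk, fs = epochs$fs, n_samples = nrow(m)),
            class = "ms_peaks")
}

#' @export
print.ms_peaks <- function(x, ...) {
  cat(sprintf("GFP peaks: %d peaks over %d samples (%.1f peaks/s)\n",
              length(x$peak_indices), x$n_samples,
              length(x$peak_indices) / (x$n_samples / x$fs)))
  invisible(x)
}
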