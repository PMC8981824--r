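#' Fit microstate maps by polarity-invariant modified K-means
#'
#' Clusters GFP-peak topographies into `k` microstate maps with the
#' polarity-invariant ("modified") K-means:
#'
#' * assignment: each topography goes to the map with the largest squared
#'   spatial correlation (so a map and its sign flip are equivalent);
#' * update: each map becomes the dominant eigenvector of the outer-product
#'   sum of its assigned topographies (the polarity-blind analogue of the
#'   cluster mean);
#' * objective: the global explained variance (GEV), iterated until the
#'   relative GEV change falls below `tol` or `max_iter` is reached.
#'
#' The best of `restarts` random initialisations (each seeded with `k`
#' distinct peak topographies) is kept; the whole procedure is
#' deterministic for a fixed `seed`.
#'
#' @param x an `ms_epochs` (peaks are extracted first), an `ms_peaks`, or a
#'   plain P x C matrix of topographies (rows are average-referenced
#'   internally; unweighted GFP is used for plain matrices).
#' @param k number of maps (default 4, the canonical A-D solution).
#' @param restarts random restarts (default 50).
#' @param max_iter maximum iterations per restart (default 500).
#' @param tol relative GEV convergence threshold (default 1e-8).
#' @param seed integer seed.
#' @param min_sep_ms peak separation passed to [find_gfp_peaks()] when `x`
#'   is an `ms_epochs`.
#' @return An object of class `microstate_fit` with components `maps`
#'   (k x C unit-norm, average-referenced), `peak_labels`, `gev`, `peaks`
#'   (the `ms_peaks` used), `k`, `restarts`, `iterations`, `gev_trace`
#'   (per-iteration GEV of the winning restart) and `call`.
#' @seealso [predict.microstate_fit()] for back-fitting,
#'   [aggregate_group_maps()], [label_maps()], [compute_gev()].
#' @examples
#' mon <- montage_1010_64()
#' tpl <- canonical_templates(mon)
#' set.seed(1)
#' X <- tpl[sample(1:4, 200, TRUE), ] * sample(c(-1, 1), 200, TRUE)
#' fit <- microstate_fit(X, k = 4, restarts = 10, seed = 1)
#' fit$gev   # 1 in the noise-free limit
#' @export
microstate_fit <- function(x, k = 4, restarts = 50, max_iter = 500,
                           tol = 1e-8, seed = 1, min_sep_ms = 10) {
  if (inherits(x, "ms_epochs")) x <- find_gfp_peaks(x, min_sep_ms)
  if (inherits(x, "ms_peaks")) {
    topo <- x$topographies
    peaks <- x
  } else {
    topo <- .avg_ref_rows(as.matrix(x))
    peaks <- NULL
  }
  P <- nrow(topo)
  if (!.is_count(k)) .stopf("k must be a positive integer")
  if (k > P) .stopf("k = %d exceeds the number of topographies (%d)", k, P)
  nrm2 <- rowSums(topo^2)
  if (any(nrm2 == 0)) .stopf("all-zero topographies cannot be clustered")
  denom <- sum(nrm2)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  best <- NULL
  for (r in seq_len(restarts)) {
    maps <- .unit_rows(topo[sample.int(P, k), , drop = FALSE])
    gev_prev <- -Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      pr <- topo %*% t(maps)
      lab <- max.col(pr^2, ties.method = "first")
      for (j in seq_len(k)) {
        idx <- which(lab == j)
        if (!length(idx)) next
        # dominant eigenvector of the scatter sum(v v') over assigned maps
        ev <- eigen(crossprod(topo[idx, , drop = FALSE]), symmetric = TRUE)
        maps[j, ] <- ev$vectors[, 1]
      }
      pr <- topo %*% t(maps)
      lab <- max.col(pr^2, ties.method = "first")
      gev <- sum(pr[cbind(seq_len(P), lab)]^2) / denom
      trace <- c(trace, gev)
      if (is.finite(gev_prev) && gev - gev_prev < tol * max(gev, .Machine$double.xmin)) break
      gev_prev <- gev
    }
    if (is.null(best) || gev > best$gev)
      best <- list(maps = maps, lab = lab, gev = gev, iterations = it, trace = trace)
  }
  maps <- .unit_rows(.avg_ref_rows(best$maps))
  rownames(maps) <- paste0("M", seq_len(k))
  if (!is.null(peaks)) colnames(maps) <- colnames(peaks$topographies)
  structure(list(maps = maps, peak_labels = best$lab, gev = best$gev,
                 peaks = peaks, k = k, restarts = restarts,
                 iterations = best$iterations, gev_trace = best$trace,
                 call = match.call()),
            class = "microstate_fit")
}

#' Global explained variance
#'
#' `GEV = sum_p (GFP_p * r_p)^2 / sum_p GFP_p^2`, where `r_p` is the
#' spatial (Pearson) correlation between topography p and its assigned map.
#' GEV is polarity-invariant and lies in `[0, 1]`.
#'
#' @param peaks an `ms_peaks`, or a P x C matrix of topographies (GFP is
#'   then computed from the rows).
#' @param maps a k x C matrix of maps.
#' @param labels integer assignment of each topography to a map row; by
#'   default the GEV-optimal assignment (argmax squared correlation).
#' @return A single number in `[0, 1]`.
#' @export
compute_gev <- function(peaks, maps, labels = NULL) {
  topo <- if (inherits(peaks, "ms_peaks")) peaks$topographies else .avg_ref_rows(as.matrix(peaks))
  maps <- .unit_rows(.avg_ref_rows(as.matrix(maps)))
  if (ncol(topo) != ncol(maps)) .stopf("channel mismatch between topographies and maps")
  nrm2 <- rowSums(topo^2)
  if (sum(nrm2) == 0) .stopf("zero total GFP")
  pr <- topo %*% t(maps)
  if (is.null(labels)) labels <- max.col(pr^2, ties.method = "first")
  if (length(labels) != nrow(topo)) .stopf("labels length mismatch")
  sum(pr[cbind(seq_len(nrow(topo)), labels)]^2) / sum(nrm2)
}

#' @export
print.microstate_fit <- function(x, ...) {
  cat(sprintf("Microstate fit: k = %d maps over %d channels\n", x$k, ncol(x$maps)))
  if (!is.null(x$peaks))
    cat(sprintf("  fitted on %d GFP-peak topographies\n", nrow(x$peaks$topographies)))
  cat(sprintf("  GEV = %.4f  (%d restarts, winning run: %d iterations)\n",
              x$gev, x$restarts, x$iterations))
  invisible(x)
}

#' @export
summary.microstate_fit <- function(object, ...) {
  out <- list(fit = object,
              label_table = table(factor(object$peak_labels, seq_len(object$k),
                                         rownames(object$maps))),
              map_correlations = spatial_correlation(object$maps))
  class(out) <- "summary.microstate_fit"
  out
}

#' @export
print.summary.microstate_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPeak assignment counts:\n")
  print(x$label_table)
  cat("\nInter-map spatial correlations:\n")
  print(round(x$map_correlations, 3))
  invisible(x)
}

#' @export
coef.microstate_fit <- function(object, ...) object$maps

#' Back-fit new data with fitted maps
#'
#' @param object a `microstate_fit`.
#' @param newdata an `ms_epochs` to label; defaults to labelling the
#'   fitted peaks (in which case the peak labels are returned).
#' @param method passed to [backfit()]: `"peaks"` (default) or `"sample"`.
#' @param ... passed to [backfit()].
#' @return An `ms_labels` object (see [backfit()]), or the peak label
#'   vector when `newdata` is missing.
#' @export
predict.microstate_fit <- function(object, newdata = NULL,
                                   method = c("peaks", "sample"), ...) {
  if (is.null(newdata)) return(object$peak_labels)
  backfit(newdata, object$maps, method = match.arg(method), ...)
}

#' Simulate recordings from fitted maps
#'
#' Uses the fitted maps as generating templates and draws recordings with
#' planted semi-Markov dynamics, inverting the analysis: useful for
#' parametric-bootstrap checks of the pipeline.
#'
#' @param object a `microstate_fit` with `k = 4`.
#' @param nsim number of recordings.
#' @param seed integer seed.
#' @param dynamics a [semi_markov_spec] (default [preset_dynamics()]`("mwoa")`).
#' @param fs,length_s,snr recording parameters.
#' @param montage montage for the simulated recordings.
#' @param ... unused.
#' @return A list of [ms_recording]s.
#' @export
simulate.microstate_fit <- function(object, nsim = 1, seed = 1,
                                    dynamics = preset_dynamics("mwoa"),
                                    fs = 500, length_s = 240, snr = 5,
                                    montage = montage_1010_64(), ...) {
  if (object$k != 4L) .stopf("simulation requires a 4-class fit")
  seeds <- .derive_seeds(seed, 2L * nsim)
  tpl <- as_templates(object$maps)
  lapply(seq_len(nsim), function(i) {
    labs <- sample_state_sequence(dynamics, length_s, fs, seed = seeds[i])
    render_eeg(labs, tpl, fs = fs, snr = snr, seed = seeds[nsim + i],
               montage = montage)
  })
}

#' Plot fitted microstate maps
#'
#' Draws each map as coloured electrode discs on the head outline (red
#' positive, blue negative).  Microstate maps are sign-ambiguous; the
#' rendering fixes the sign so the maximum-absolute channel is positive.
#'
#' @param x a `microstate_fit`, or any k x C matrix of maps via
#'   [as_templates()].
#' @param montage the electrode montage (default [montage_1010_64()] when
#'   the channel count matches).
#' @param ... unused.
#' @export
plot.microstate_fit <- function(x, montage = NULL, ...) {
  maps <- if (inherits(x, "microstate_fit")) x$maps else as.matrix(x)
  if (is.null(montage)) {
    montage <- montage_1010_64()
    if (nrow(montage) != ncol(maps)) .stopf("supply the montage for these maps")
  }
  k <- nrow(maps)
  op <- graphics::par(mfrow = c(1, k), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  th <- seq(0, 2 * pi, length.out = 181)
  for (j in seq_len(k)) {
    v <- maps[j, ]
    if (v[which.max(abs(v))] < 0) v <- -v
    col <- grDevices::rgb(pmax(v, 0) / max(abs(v)), 0, pmax(-v, 0) / max(abs(v)))
    graphics::plot(cos(th), sin(th), type = "l", asp = 1, axes = FALSE,
                   xlab = "", ylab = "",
                   main = rownames(maps)[j] %||% paste0("M", j))
    graphics::points(montage$x, montage$y, pch = 19, cex = 1.2, col = col)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
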