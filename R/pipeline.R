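#' Full microstate analysis pipeline
#'
#' Runs the complete chain on a set of recordings: acquisition-stage
#' band-pass + notch, microstate-stage band-pass, epoching with common
#' average reference, GFP-peak extraction, per-subject polarity-invariant
#' K-means, per-group aggregation into group maps, canonical A-D
#' labelling, back-fitting, and the temporal-parameter and
#' transition-syntax tables.
#'
#' @param recordings list of [ms_recording]s.
#' @param groups character/factor of group membership per recording, or
#'   `NULL` for a single group.
#' @param pre_band acquisition band-pass in Hz (`NULL` to skip).
#' @param notch notch frequency in Hz (`NULL` to skip).
#' @param band microstate analysis band-pass in Hz.
#' @param epoch_s epoch length (s).
#' @param n_epochs epochs per subject (`NULL` = all available).
#' @param k,restarts,tol,max_iter clustering settings (see
#'   [microstate_fit()]).
#' @param seed integer master seed.
#' @param templates canonical templates for labelling; default
#'   [canonical_templates()] on the recordings' montage.
#' @param backfit_method `"peaks"` (default) or `"sample"`, see [backfit()].
#' @param smooth_ms short-segment rejection threshold in ms (0 = off).
#' @param exclude_truncated passed to [compute_parameters()].
#' @return A list of class `ms_pipeline`:
#'   `parameters` (long data frame: subject, group, class, duration_ms,
#'   occurrence_per_s, coverage_pct), `transitions` (long data frame:
#'   subject, group, from, to, percent), `group_maps` (named list of
#'   labelled 4 x C matrices), `subject_maps` (list of labelled per-subject
#'   maps), `gev` (per-subject GEV of the group maps on the subject's
#'   peaks), `fit_gev` (per-subject K-means GEV), `labels` (list of
#'   `ms_labels`).
#' @export
microstate_pipeline <- function(recordings, groups = NULL,
                                pre_band = c(0.5, 70), notch = 50,
                                band = c(2, 20), epoch_s = 2, n_epochs = 60,
                                k = 4, restarts = 50, tol = 1e-8,
                                max_iter = 500, seed = 1,
                                templates = NULL,
                                backfit_method = c("peaks", "sample"),
                                smooth_ms = 0, exclude_truncated = FALSE) {
  backfit_method <- match.arg(backfit_method)
  n <- length(recordings)
  if (!n) .stopf("no recordings")
  if (is.null(groups)) groups <- rep("all", n)
  if (length(groups) != n) .stopf("groups must have one entry per recording")
  groups <- as.character(groups)
  if (is.null(templates))
    templates <- canonical_templates(recordings[[1]]$montage)
  seeds <- .derive_seeds(seed, n + length(unique(groups)))

  epochs <- vector("list", n)
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- recordings[[i]]
    if (!is.null(pre_band) && pre_band[2] < rec$fs / 2)
      rec <- filter_recording(rec, pre_band[1], pre_band[2], notch = notch)
    rec <- filter_recording(rec, band[1], band[2])
    epochs[[i]] <- epoch_recording(rec, epoch_s, n_epochs)
    fits[[i]] <- microstate_fit(epochs[[i]], k = k, restarts = restarts,
                                tol = tol, max_iter = max_iter,
                                seed = seeds[i])
  }

  glev <- unique(groups)
  group_maps <- list()
  for (gi in seq_along(glev)) {
    idx <- which(groups == glev[gi])
    gm <- if (length(idx) >= 2) {
      aggregate_group_maps(fits[idx], seed = seeds[n + gi])
    } else fits[[idx]]$maps
    group_maps[[glev[gi]]] <- label_maps(gm, templates)$maps
  }
  subject_maps <- lapply(seq_len(n), function(i)
    label_maps(fits[[i]]$maps, templates)$maps)

  params <- list(); trans <- list()
  gev <- numeric(n); labels_out <- vector("list", n)
  for (i in seq_len(n)) {
    gm <- group_maps[[groups[i]]]
    lab <- backfit(epochs[[i]], gm, method = backfit_method)
    if (smooth_ms > 0) lab <- smooth_labels(lab, smooth_ms)
    labels_out[[i]] <- lab
    gev[i] <- compute_gev(fits[[i]]$peaks, gm)
    p <- compute_parameters(lab, exclude_truncated = exclude_truncated)
    p <- cbind(subject = i, group = groups[i], p, stringsAsFactors = FALSE)
    tr <- compute_transitions(lab)
    tr <- cbind(subject = i, group = groups[i], tr, stringsAsFactors = FALSE)
    params[[i]] <- p
    trans[[i]] <- tr
  }
  structure(list(parameters = do.call(rbind, params),
                 transitions = do.call(rbind, trans),
                 group_maps = group_maps,
                 subject_maps = subject_maps,
                 gev = gev,
                 fit_gev = vapply(fits, function(f) f$gev, numeric(1)),
                 labels = labels_out,
                 groups = groups),
            class = "ms_pipeline")
}

#' @export
print.ms_pipeline <- function(x, ...) {
  n <- length(x$gev)
  cat(sprintf("Microstate pipeline result: %d subjects, groups: %s\n",
              n, paste(names(x$group_maps), collapse = ", ")))
  cat(sprintf("  mean GEV of group maps on subject peaks: %.3f\n", mean(x$gev)))
  agg <- stats::aggregate(x$parameters[, c("duration_ms", "occurrence_per_s", "coverage_pct")],
                          by = list(class = x$parameters$class), FUN = mean)
  cat("  mean temporal parameters across subjects:\n")
  print(agg, row.names = FALSE)
  invisible(x)
}
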