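#' Read and write microstate maps as CSV
#'
#' Maps are stored with one row per class (rownames A-D) and one column
#' per channel.
#'
#' @param maps a k x C matrix of maps.
#' @param path output file.
#' @export
write_maps_csv <- function(maps, path) {
  utils::write.csv(as.matrix(maps), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_maps_csv
#' @export
read_maps_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

#' Write a recording as plain-text matrix CSV
#'
#' One row per channel, one column per sample, with channel names as row
#' names; ground-truth labels (when present) go to a sidecar TSV with
#' columns `sample`, `class`.
#'
#' @param rec an [ms_recording].
#' @param path output CSV path; the sidecar is `paste0(path, ".labels.tsv")`.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "ms_recording"))
  utils::write.csv(rec$data, path, row.names = TRUE)
  if (!is.null(rec$truth_labels)) {
    utils::write.table(
      data.frame(sample = seq_along(rec$truth_labels),
                 class = MS_CLASSES[rec$truth_labels]),
      paste0(path, ".labels.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @param fs sampling rate of the stored recording (Hz).
#' @param montage the montage matching the stored channels.
#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path, fs, montage) {
  d <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  lp <- paste0(path, ".labels.tsv")
  tl <- NULL
  if (file.exists(lp)) {
    ld <- utils::read.table(lp, header = TRUE, sep = "\t")
    tl <- match(ld$class, MS_CLASSES)
  }
  ms_recording(d, fs = fs, montage = montage, truth_labels = tl)
}

#' Write tidy parameter / transition / clinical tables as TSV
#'
#' @param table a data frame (e.g. `parameters` or `transitions` from
#'   [microstate_pipeline()], or the clinical table of
#'   [generate_cohort()]).
#' @param path output TSV path.
#' @export
write_table_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
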