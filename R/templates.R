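#' Canonical microstate template maps
#'
#' Builds the four canonical microstate topographies A-D on a given montage.
#' Each template is the difference of two isotropic Gaussian bumps
#' (sigma = 0.6 head radii) evaluated at the projected electrode positions,
#' then average-referenced and scaled to unit norm:
#'
#' * **A** - left-posterior positive / right-frontal negative diagonal dipole,
#' * **B** - the left-right mirror image of A,
#' * **C** - occipital positive / frontal negative anterior-posterior pattern,
#' * **D** - fronto-central maximum against a broad posterior negativity
#'   (the negative bump centred well behind the head rim, so it acts as a
#'   near-uniform posterior baseline).
#'
#' By construction every row has zero channel mean and unit Euclidean norm,
#' and reflecting the montage left-right exchanges A and B exactly.
#'
#' @param montage an [ms_montage] with at least 8 channels.
#' @param sigma Gaussian bump width in head radii (default 0.6).
#' @return A `ms_templates` object: a 4 x C numeric matrix with rownames
#'   `A`, `B`, `C`, `D` and column names equal to the channel names.
#' @examples
#' tpl <- canonical_templates(montage_1010_64())
#' round(rowSums(tpl), 12)      # average reference
#' round(sqrt(rowSums(tpl^2)))  # unit norm
#' @export
canonical_templates <- function(montage, sigma = 0.6) {
  stopifnot(inherits(montage, "ms_montage"))
  if (nrow(montage) < 8L)
    .stopf("montage with fewer than 8 channels")
  centers <- list(
    A = c(-0.8, -0.5,  0.8,  0.6),
    B = c( 0.8, -0.5, -0.8,  0.6),
    C = c( 0.0, -0.8,  0.0,  0.9),
    D = c( 0.0,  0.2,  0.0, -2.5)
  )
  bump <- function(cx, cy)
    exp(-((montage$x - cx)^2 + (montage$y - cy)^2) / (2 * sigma^2))
  maps <- t(vapply(centers,
                   function(ct) bump(ct[1], ct[2]) - bump(ct[3], ct[4]),
                   numeric(nrow(montage))))
  maps <- .unit_rows(.avg_ref_rows(maps))
  dimnames(maps) <- list(MS_CLASSES, montage$name)
  structure(maps, class = c("ms_templates", "matrix"))
}

#' Coerce a plain matrix of maps to an ms_templates object
#'
#' Rows are average-referenced and unit-normed; rownames default to A-D.
#'
#' @param maps a k x C numeric matrix (k topographies over C channels).
#' @param labels optional row labels (length k).
#' @return An `ms_templates` object.
#' @export
as_templates <- function(maps, labels = NULL) {
  maps <- as.matrix(maps)
  maps <- .unit_rows(.avg_ref_rows(maps))
  if (is.null(labels))
    labels <- if (nrow(maps) <= 4) MS_CLASSES[seq_len(nrow(maps))] else paste0("M", seq_len(nrow(maps)))
  rownames(maps) <- labels
  structure(maps, class = c("ms_templates", "matrix"))
}

#' Spatial correlation matrix between two sets of maps
#'
#' @param a,b matrices of topographies (rows are maps over the same channels).
#' @return A `nrow(a)` x `nrow(b)` matrix of Pearson spatial correlations.
#' @export
spatial_correlation <- function(a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) .stopf("channel counts differ (%d vs %d)", ncol(a), ncol(b))
  ac <- .unit_rows(.avg_ref_rows(a))
  bc <- .unit_rows(.avg_ref_rows(b))
  ac %*% t(bc)
}
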