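#' Electrode montage
#'
#' An `ms_montage` is a data frame with one row per electrode and columns
#' `name`, `x`, `y`.  Coordinates are an azimuthal-equidistant projection of
#' scalp positions onto the unit disc: the vertex (Cz) maps to the origin and
#' a point 90 degrees from the vertex maps to radius 1, so all scalp
#' electrodes satisfy `sqrt(x^2 + y^2) <= 1`.  `+y` is anterior (nasion),
#' `+x` is the right ear.
#'
#' @param name character vector of unique electrode labels (10-20/10-10
#'   names for standard caps, but any unique labels are accepted).
#' @param x,y numeric projected coordinates, finite, with norm at most 1.
#' @return An object of class `ms_montage`.
#' @examples
#' mon <- ms_montage(c("Fz", "Cz", "Pz", "Oz", "C3", "C4", "F3", "F4"),
#'                   x = c(0, 0, 0, 0, -.4, .4, -.3, .3),
#'                   y = c(.4, 0, -.4, -.8, 0, 0, .35, .35))
#' nrow(mon)
#' @seealso [montage_1010_64()] for the packaged 64-channel standard layout.
#' @export
ms_montage <- function(name, x, y) {
  name <- as.character(name)
  if (length(name) < 8L)
    .stopf("a montage needs at least 8 channels, got %d", length(name))
  if (anyDuplicated(name))
    .stopf("duplicated channel names: %s",
           paste(unique(name[duplicated(name)]), collapse = ", "))
  if (length(x) != length(name) || length(y) != length(name))
    .stopf("name, x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    .stopf("montage coordinates must be finite")
  r <- sqrt(x^2 + y^2)
  if (any(r > 1 + 1e-8))
    .stopf("montage coordinates must lie within the unit head disc (max radius %.3f)", max(r))
  structure(data.frame(name = name, x = as.numeric(x), y = as.numeric(y),
                       stringsAsFactors = FALSE),
            class = c("ms_montage", "data.frame"))
}

#' Standard 64-channel 10-10 montage
#'
#' Returns the packaged 64-channel extended 10-20 (10-10) montage.  The
#' layout follows the usual construction: the 10% circumference circle
#' (Fpz..Oz) sits 72 degrees from the vertex, midline electrodes are spaced
#' along the nasion-inion arc, and lateral electrodes are spaced evenly
#' along coronal arcs between the two circumference crossings of their row.
#'
#' @return An [ms_montage] with 64 rows.
#' @examples
#' mon <- montage_1010_64()
#' head(mon)
#' @export
montage_1010_64 <- function() {
  path <- system.file("extdata", "montage_1010_64.csv", package = "eegmicrostate",
                      mustWork = TRUE)
  read_montage(path)
}

#' Read a montage from CSV
#'
#' The file must have columns `name`, `x`, `y` (projected unit-disc
#' coordinates, see [ms_montage()]).
#'
#' @param path path to a CSV file.
#' @return An [ms_montage].
#' @export
read_montage <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y")
  if (!all(need %in% names(d)))
    .stopf("montage file must have columns name, x, y")
  ms_montage(d$name, d$x, d$y)
}

#' Mirror a montage left-right
#'
#' Reflects all electrode positions across the midline (x -> -x), keeping
#' names.  Useful for symmetry checks of topographic constructions.
#'
#' @param montage an [ms_montage].
#' @return The reflected [ms_montage].
#' @export
mirror_montage <- function(montage) {
  stopifnot(inherits(montage, "ms_montage"))
  ms_montage(montage$name, -montage$x, montage$y)
}
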