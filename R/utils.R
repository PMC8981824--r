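# Internal helpers shared across the package.

MS_CLASSES <- c("A", "B", "C", "D")

# centre each row (average reference across channels)
.avg_ref_rows <- function(m) m - rowMeans(m)

# scale each row to unit Euclidean norm; zero rows are left untouched
.unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

# spatial (Pearson) correlation between topography vectors
.spatial_cor <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# all permutations of 1:n, in lexicographic order (n is tiny: 2..4)
.perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  dimnames(out) <- NULL
  out
}

# reproducible per-unit seeds derived from one master seed
.derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
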