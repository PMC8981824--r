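# shared fixtures, built in code

MS_CLASSES <- c("A", "B", "C", "D")

# small montage for fast tests: 12 electrodes on two rings
tiny_montage <- function() {
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  ms_montage(
    name = c(paste0("O", 1:8), paste0("I", 1:4)),
    x = c(0.8 * cos(ang), 0.4 * cos(ang[c(1, 3, 5, 7)])),
    y = c(0.8 * sin(ang), 0.4 * sin(ang[c(1, 3, 5, 7)]))
  )
}

# k mutually orthogonal, average-referenced, unit-norm topographies
orth_maps_exact <- function(C, k, seed = 1) {
  set.seed(seed)
  B <- qr.Q(qr(cbind(1, matrix(rnorm(C * k), C, k))))[, -1, drop = FALSE]
  t(B) / 1                      # columns orthonormal and orthogonal to 1
}

# uniform 4-class dynamics with equal durations
uniform_dynamics <- function(dur = 60) {
  P <- matrix(1 / 3, 4, 4); diag(P) <- 0
  semi_markov_spec(rep(dur, 4), P)
}

# label series wrapper for parameter tests
make_labels <- function(labels, fs = 500, epoch_length = length(labels),
                        k = 4, abs_cor = NULL) {
  n_ep <- length(labels) / epoch_length
  stopifnot(n_ep == round(n_ep))
  if (is.null(abs_cor)) abs_cor <- matrix(0, length(labels), k)
  structure(list(labels = as.integer(labels), epoch_length = epoch_length,
                 n_epochs = as.integer(n_ep), fs = fs, k = k,
                 abs_cor = abs_cor),
            class = "ms_labels")
}

mwoa_durations <- c(65.13, 64.99, 61.44, 63.61)

# brute-force oracle: best GEV over all labelled 2-partitions with
# eigenvector map updates (independent of the k-means implementation)
brute_force_gev2 <- function(X) {
  X <- X - rowMeans(X)
  P <- nrow(X)
  denom <- sum(rowSums(X^2))
  best <- -Inf
  for (code in 1:(2^P - 2)) {
    lab <- as.integer(intToBits(code))[1:P] + 1L
    if (length(unique(lab)) < 2) next
    num <- 0
    for (j in 1:2) {
      sub <- X[lab == j, , drop = FALSE]
      ev <- eigen(crossprod(sub), symmetric = TRUE)
      num <- num + sum((sub %*% ev$vectors[, 1])^2)
    }
    best <- max(best, num / denom)
  }
  best
}

# long-format parameter table generator
sim_param_table <- function(n1, n2, k = 4, seed = 1, sd_subj = 1, sd_noise = 1,
                            group_shift = 0, class_shift = rep(0, k)) {
  set.seed(seed)
  n <- n1 + n2
  subj_eff <- rnorm(n, sd = sd_subj)
  grp <- rep(c("g1", "g2"), c(n1, n2))
  rows <- expand.grid(subject = seq_len(n), class = MS_CLASSES[seq_len(k)],
                      stringsAsFactors = FALSE)
  rows$group <- grp[rows$subject]
  kidx <- match(rows$class, MS_CLASSES)
  rows$value <- 60 + subj_eff[rows$subject] + class_shift[kidx] +
    ifelse(rows$group == "g1", group_shift, 0) +
    rnorm(nrow(rows), sd = sd_noise)
  rows
}
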