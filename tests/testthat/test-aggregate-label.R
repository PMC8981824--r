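test_that("identical subject maps in shuffled order are re-aligned perfectly", {
  tpl <- canonical_templates(montage_1010_64())
  orders <- list(c(1, 2, 3, 4), c(3, 1, 4, 2), c(2, 4, 1, 3), c(4, 3, 2, 1))
  subj <- lapply(orders, function(o) tpl[o, ] * rep(c(1, -1), 2))
  gm <- aggregate_group_maps(subj, seed = 1)
  cr <- abs(spatial_correlation(gm, tpl))
  # each group map matches exactly one template up to sign
  expect_equal(unname(sort(apply(cr, 2, max))), rep(1, 4), tolerance = 1e-9)
  # every subject's permutation is recovered
  P <- attr(gm, "permutations")
  slot_class <- apply(cr, 1, which.max)       # which template each slot holds
  for (s in seq_along(orders))
    expect_equal(orders[[s]][P[s, ]], unname(slot_class))
})

# exhaustive alignment oracle for 3 subjects x 2 maps: maximise the mean
# squared correlation between subject maps and the slot eigenvector
brute_force_align <- function(subj) {
  k <- nrow(subj[[1]]); ns <- length(subj)
  perms <- rbind(1:2, 2:1)
  combos <- expand.grid(rep(list(1:2), ns))
  best <- -Inf
  for (r in seq_len(nrow(combos))) {
    crit <- 0
    for (j in seq_len(k)) {
      M <- do.call(rbind, lapply(seq_len(ns), function(s)
        subj[[s]][perms[combos[r, s], j], , drop = FALSE]))
      ev <- eigen(crossprod(M), symmetric = TRUE)
      crit <- crit + sum((M %*% ev$vectors[, 1])^2)
    }
    best <- max(best, crit / (ns * k))
  }
  best
}

test_that("group alignment attains the exhaustive-search optimum for 3 subjects, 2 maps", {
  for (s in 1:3) {
    set.seed(s)
    subj <- lapply(1:3, function(i) {
      m <- matrix(rnorm(2 * 10), 2)
      m <- m - rowMeans(m)
      m / sqrt(rowSums(m^2))
    })
    gm <- aggregate_group_maps(subj, seed = s)
    expect_equal(attr(gm, "criterion"), brute_force_align(subj), tolerance = 1e-8)
  }
})

test_that("group maps are invariant to the order of subjects", {
  tpl <- canonical_templates(montage_1010_64())
  set.seed(9)
  subj <- lapply(1:5, function(i) {
    m <- tpl + matrix(rnorm(4 * 64, sd = 0.05), 4)
    m[sample(4), ]
  })
  g1 <- aggregate_group_maps(subj, seed = 2)
  g2 <- aggregate_group_maps(rev(subj), seed = 2)
  cr <- abs(spatial_correlation(g1, g2))
  expect_equal(unname(sort(apply(cr, 2, max))), rep(1, 4), tolerance = 1e-6)
  expect_error(aggregate_group_maps(subj[1]), "at least 2")
})

test_that("canonical labelling recovers permutations and ignores polarity", {
  tpl <- canonical_templates(montage_1010_64())
  # identity
  r0 <- label_maps(tpl, tpl)
  expect_identical(unname(r0$order), 1:4)
  expect_equal(unname(r0$maps), unname(unclass(tpl)), tolerance = 1e-12)
  # sign flips: identity labelling, signs restored
  r1 <- label_maps(tpl * c(-1, 1, -1, 1), tpl)
  expect_identical(unname(r1$order), 1:4)
  expect_equal(unname(r1$maps), unname(unclass(tpl)), tolerance = 1e-12)
  # shuffled order (B, A, D, C) is recovered
  r2 <- label_maps(tpl[c(2, 1, 4, 3), ], tpl)
  expect_identical(unname(r2$order), c(2L, 1L, 4L, 3L))
  expect_equal(rownames(r2$maps), c("A", "B", "C", "D"))
  expect_equal(unname(r2$maps), unname(unclass(tpl)), tolerance = 1e-12)
})
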