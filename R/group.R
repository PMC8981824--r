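#' Aggregate subject microstate maps into group maps
#'
#' Two-level aggregation: subjects' individual map sets are permuted (and,
#' implicitly, sign-flipped - all criteria are polarity-invariant) so that
#' corresponding maps line up across subjects, maximising the common
#' variance, i.e. the mean squared spatial correlation between each
#' subject's map and its group-map slot.  Group maps are recomputed as the
#' dominant eigenvector across subjects per slot, and permutation and
#' update alternate until the criterion stops improving.  Initial slots
#' come from a polarity-invariant K-means over the pooled subject maps.
#'
#' @param maps a list with one element per subject: either a k x C matrix
#'   of maps or a `microstate_fit`.
#' @param seed integer seed (initialisation).
#' @param restarts restarts of the initial pooled clustering.
#' @param max_iter maximum alternation sweeps.
#' @return A k x C matrix of unit-norm group maps with attributes
#'   `permutations` (subjects x k matrix: slot j of the group takes subject
#'   row `permutations[s, j]`) and `criterion` (mean squared spatial
#'   correlation attained).
#' @export
aggregate_group_maps <- function(maps, seed = 1, restarts = 20, max_iter = 100) {
  maps <- lapply(maps, function(m) {
    if (inherits(m, "microstate_fit")) m <- m$maps
    .unit_rows(.avg_ref_rows(as.matrix(m)))
  })
  ns <- length(maps)
  if (ns < 2L) .stopf("need at least 2 subjects")
  k <- nrow(maps[[1]])
  C <- ncol(maps[[1]])
  if (!all(vapply(maps, function(m) ncol(m) == C && nrow(m) == k, logical(1))))
    .stopf("all subjects must have the same map dimensions")
  perms <- .perms(k)
  np <- nrow(perms)
  # criterion and slot eigen-maps for a fixed permutation configuration
  eval_config <- function(P) {
    crit <- 0
    gm <- matrix(0, k, C)
    for (j in seq_len(k)) {
      M <- t(vapply(seq_len(ns), function(s) maps[[s]][P[s, j], ], numeric(C)))
      ev <- eigen(crossprod(M), symmetric = TRUE)
      gm[j, ] <- ev$vectors[, 1]
      crit <- crit + ev$values[1]
    }
    list(crit = crit / (ns * k), gm = gm)
  }
  refine <- function(gm) {
    # alternate subject re-permutation and slot eigen update to convergence
    P <- matrix(0L, ns, k)
    crit_prev <- -Inf
    res <- NULL
    for (it in seq_len(max_iter)) {
      for (s in seq_len(ns)) {
        cr2 <- (maps[[s]] %*% t(gm))^2        # subject row vs slot
        sc <- apply(perms, 1, function(p) sum(cr2[cbind(p, seq_len(k))]))
        P[s, ] <- perms[which.max(sc), ]
      }
      res <- eval_config(P)
      gm <- res$gm
      if (res$crit - crit_prev < 1e-12) break
      crit_prev <- res$crit
    }
    list(crit = res$crit, gm = gm, P = P)
  }
  if (np^ns <= 4096) {
    # small problems: exhaustive search over all permutation configurations
    combos <- as.matrix(expand.grid(rep(list(seq_len(np)), ns)))
    best <- NULL
    for (r in seq_len(nrow(combos))) {
      P <- t(vapply(seq_len(ns), function(s) perms[combos[r, s], ], integer(k)))
      res <- eval_config(P)
      if (is.null(best) || res$crit > best$crit)
        best <- list(crit = res$crit, gm = res$gm, P = P)
    }
  } else {
    # initialise from a polarity-invariant clustering of the pooled maps,
    # plus a few random permutation configurations, keep the best refinement
    init <- microstate_fit(do.call(rbind, maps), k = k, restarts = restarts,
                           seed = seed)
    best <- refine(init$maps)
    rs <- .derive_seeds(seed, 5L)
    for (r in 1:5) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(rs[r])
      P0 <- t(vapply(seq_len(ns), function(s) perms[sample.int(np, 1), ], integer(k)))
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      cand <- refine(eval_config(P0)$gm)
      if (cand$crit > best$crit) best <- cand
    }
  }
  gm <- .unit_rows(.avg_ref_rows(best$gm))
  P <- best$P
  crit_prev <- best$crit
  rownames(gm) <- paste0("M", seq_len(k))
  colnames(gm) <- colnames(maps[[1]])
  attr(gm, "permutations") <- P
  attr(gm, "criterion") <- crit_prev
  gm
}

#' Label maps against canonical templates
#'
#' Finds the assignment of maps to the canonical classes A-D that maximises
#' the summed absolute spatial correlation over all `k!` permutations (ties
#' broken by the lexicographically smallest permutation), and returns the
#' maps reordered to A-D with signs aligned to the templates (positive
#' correlation).
#'
#' @param maps a 4 x C matrix of maps.
#' @param canonical a 4 x C `ms_templates` (default
#'   [canonical_templates()] on the packaged 64-channel montage).
#' @return A list with `maps` (relabelled, sign-aligned, rownames A-D),
#'   `order` (integer: class j took input row `order[j]`), and
#'   `correlation` (per-class |spatial correlation| achieved).
#' @export
label_maps <- function(maps, canonical = canonical_templates(montage_1010_64())) {
  maps <- .unit_rows(.avg_ref_rows(as.matrix(maps)))
  tpl <- .unit_rows(.avg_ref_rows(as.matrix(canonical)))
  if (nrow(maps) != nrow(tpl)) .stopf("maps and templates must have the same number of rows")
  if (ncol(maps) != ncol(tpl)) .stopf("channel mismatch")
  k <- nrow(maps)
  cr <- maps %*% t(tpl)                       # row i of maps vs template j
  perms <- .perms(k)
  sc <- apply(perms, 1, function(p) sum(abs(cr[cbind(p, seq_len(k))])))
  best <- perms[which.max(sc), ]              # template j <- map row best[j]
  out <- maps[best, , drop = FALSE]
  for (j in seq_len(k)) if (cr[best[j], j] < 0) out[j, ] <- -out[j, ]
  rownames(out) <- rownames(tpl)
  list(maps = out, order = best,
       correlation = abs(cr[cbind(best, seq_len(k))]))
}

#' Topographic analysis of variance (TANOVA)
#'
#' Randomisation test for topographic differences between two groups of
#' labelled, sign-aligned microstate map sets.  Subject maps are
#' L2-normalised; the test statistics are
#'
#' * `group`: GFP of the difference between the two groups' grand-mean
#'   maps after averaging each subject's maps over classes;
#' * `interaction`: mean over classes of the GFP of the class-wise group
#'   difference after removing each group's overall mean map;
#' * `class`: mean over classes of the GFP of the class grand mean around
#'   the overall grand mean (within-subject effect).
#'
#' The null distribution reassigns subjects to groups (`group`,
#' `interaction`) or shuffles class labels within subjects (`class`);
#' `p = (1 + #(perm >= observed)) / (1 + n_perm)`.
#'
#' @param group1_maps,group2_maps lists of 4 x C matrices (one per subject),
#'   labelled and sign-aligned (see [label_maps()]).
#' @param n_perm number of permutations (default 5000, minimum 100).
#' @param seed integer seed.
#' @param effects subset of `c("group", "class", "interaction")`.
#' @return A data frame with columns `effect`, `observed_stat`, `p`,
#'   `n_perm`.
#' @export
tanova <- function(group1_maps, group2_maps, n_perm = 5000, seed = 1,
                   effects = c("group", "class", "interaction")) {
  effects <- match.arg(effects, several.ok = TRUE)
  if (length(group1_maps) < 2L || length(group2_maps) < 2L)
    .stopf("each group needs at least 2 subjects")
  if (n_perm < 100) .stopf("n_perm must be at least 100")
  norm1 <- function(m) .unit_rows(.avg_ref_rows(as.matrix(m)))
  g1 <- lapply(group1_maps, norm1)
  g2 <- lapply(group2_maps, norm1)
  k <- nrow(g1[[1]])
  n1 <- length(g1); n2 <- length(g2)
  all_maps <- c(g1, g2)
  n <- n1 + n2
  C <- ncol(g1[[1]])
  gfp <- function(v) sqrt(mean((v - mean(v))^2))
  # precomputed reductions: the null only regroups subjects
  SM <- do.call(rbind, lapply(all_maps, colMeans))      # n x C subject means
  CM <- lapply(seq_len(k), function(j)                   # per class: n x C
    do.call(rbind, lapply(all_maps, function(m) m[j, ])))

  stat_group <- function(idx1) {
    gfp(colMeans(SM[idx1, , drop = FALSE]) - colMeans(SM[-idx1, , drop = FALSE]))
  }
  stat_inter <- function(idx1) {
    o1 <- colMeans(SM[idx1, , drop = FALSE])
    o2 <- colMeans(SM[-idx1, , drop = FALSE])
    mean(vapply(CM, function(M)
      gfp((colMeans(M[idx1, , drop = FALSE]) - o1) -
          (colMeans(M[-idx1, , drop = FALSE]) - o2)), numeric(1)))
  }
  stat_class <- function(lst) {
    G <- do.call(rbind, lapply(seq_len(k), function(j)
      colMeans(do.call(rbind, lapply(lst, function(m) m[j, ])))))
    D <- sweep(G, 2, colMeans(G))
    mean(apply(D, 1, gfp))
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- list()
  for (eff in effects) {
    if (eff %in% c("group", "interaction")) {
      f <- if (eff == "group") stat_group else stat_inter
      obs <- f(seq_len(n1))
      ge <- 0L
      for (b in seq_len(n_perm)) {
        idx1 <- sample.int(n1 + n2, n1)
        if (f(idx1) >= obs) ge <- ge + 1L
      }
    } else {
      obs <- stat_class(all_maps)
      ge <- 0L
      for (b in seq_len(n_perm)) {
        shuf <- lapply(all_maps, function(m) m[sample.int(k), , drop = FALSE])
        if (stat_class(shuf) >= obs) ge <- ge + 1L
      }
    }
    out[[eff]] <- data.frame(effect = eff, observed_stat = obs,
                             p = (1 + ge) / (1 + n_perm), n_perm = n_perm,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
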