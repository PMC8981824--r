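#' Mixed-design ANOVA with Greenhouse-Geisser correction
#'
#' 2 (group, between-subjects) x k (microstate class, within-subjects)
#' mixed ANOVA on one temporal parameter, returning the between-group,
#' within-class and interaction F tests with Greenhouse-Geisser epsilon
#' estimated from the pooled within-subject covariance, the GG-corrected
#' p-value, and the Mauchly sphericity test.  Fitted through the
#' multivariate linear model machinery (`car::Anova`, type III), the
#' standard approach for this design.
#'
#' @param table a parameter table in long format with columns `subject`,
#'   `group`, `class` and the metric columns, as produced by
#'   [microstate_pipeline()] (or any data frame with those columns).
#' @param metric which column to analyse, e.g. `"duration_ms"`,
#'   `"occurrence_per_s"`, `"coverage_pct"`.
#' @return A data frame with one row per effect (`group`, `class`,
#'   `group:class`): `F`, `df1`, `df2`, `epsilon_gg`, `p_uncorrected`,
#'   `p_gg`, `mauchly_p`, `sphericity_violated`.
#' @export
mixed_anova <- function(table, metric) {
  need <- c("subject", "group", "class", metric)
  if (!all(need %in% names(table)))
    .stopf("table must have columns %s", paste(need, collapse = ", "))
  wide <- stats::reshape(table[, need], idvar = c("subject", "group"),
                         timevar = "class", direction = "wide")
  ycols <- setdiff(names(wide), c("subject", "group"))
  Y <- as.matrix(wide[, ycols])
  if (anyNA(Y)) .stopf("missing cells: every subject needs all classes")
  k <- ncol(Y)
  grp <- factor(wide$group)
  if (nlevels(grp) != 2L) .stopf("exactly two groups are required")
  # sum-to-zero coding so type-III within-subject effects are evaluated at
  # the unweighted group mean
  mod <- stats::lm(Y ~ grp, contrasts = list(grp = "contr.sum"))
  idata <- data.frame(class = factor(seq_len(k)))
  av <- car::Anova(mod, idata = idata, idesign = ~class, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  pa <- s$pval.adjustments
  sph <- s$sphericity.tests
  eff_map <- c(grp = "group", class = "class", `grp:class` = "group:class")
  rows <- intersect(rownames(ut), names(eff_map))
  out <- do.call(rbind, lapply(rows, function(r) {
    gg_eps <- if (r %in% rownames(pa)) unname(pa[r, "GG eps"]) else NA_real_
    gg_p <- if (r %in% rownames(pa)) unname(pa[r, "Pr(>F[GG])"]) else NA_real_
    mp <- if (!is.null(sph) && r %in% rownames(sph)) unname(sph[r, "p-value"]) else NA_real_
    data.frame(effect = eff_map[[r]],
               F = unname(ut[r, "F value"]),
               df1 = unname(ut[r, "num Df"]),
               df2 = unname(ut[r, "den Df"]),
               epsilon_gg = gg_eps,
               p_uncorrected = unname(ut[r, "Pr(>F)"]),
               p_gg = gg_p,
               mauchly_p = mp,
               sphericity_violated = if (is.na(mp)) NA else mp < 0.05,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-class simple effects (two-sample t-tests)
#'
#' Pooled-variance two-sample t-tests comparing the two groups within each
#' microstate class, `df = N - 2`.  Computed unconditionally; interpret
#' alongside the interaction test of [mixed_anova()].
#'
#' @inheritParams mixed_anova
#' @return A data frame with one row per class: `class`, `t`, `df`,
#'   `p_raw`, `mean_group1`, `mean_group2`.
#' @export
simple_effects <- function(table, metric) {
  need <- c("group", "class", metric)
  if (!all(need %in% names(table))) .stopf("table must have columns %s", paste(need, collapse = ", "))
  grp <- factor(table$group)
  if (nlevels(grp) != 2L) .stopf("exactly two groups are required")
  lv <- levels(grp)
  out <- lapply(split(table, table$class), function(d) {
    x <- d[[metric]][d$group == lv[1]]
    y <- d[[metric]][d$group == lv[2]]
    if (!length(x) || !length(y)) .stopf("a group is empty for class %s", d$class[1])
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(class = d$class[1], t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value,
               mean_group1 = mean(x), mean_group2 = mean(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected transition t-tests
#'
#' Pooled two-sample t-tests on each of the 12 ordered transition
#' percentages, Bonferroni-corrected with m = 12.  A transition constant
#' across all subjects has an undefined t and is reported as `NA`.
#'
#' @param table transition table in long format with columns `subject`,
#'   `group`, `from`, `to`, `percent`.
#' @return A data frame with one row per ordered pair: `from`, `to`, `t`,
#'   `df`, `p_raw`, `p_bonferroni`.
#' @export
transition_tests <- function(table) {
  need <- c("subject", "group", "from", "to", "percent")
  if (!all(need %in% names(table))) .stopf("table must have columns %s", paste(need, collapse = ", "))
  grp <- factor(table$group)
  if (nlevels(grp) != 2L) .stopf("exactly two groups are required")
  lv <- levels(grp)
  key <- interaction(table$from, table$to, drop = TRUE)
  m <- 12L
  out <- lapply(split(table, key), function(d) {
    x <- d$percent[d$group == lv[1]]
    y <- d$percent[d$group == lv[2]]
    res <- data.frame(from = d$from[1], to = d$to[1], t = NA_real_,
                      df = length(x) + length(y) - 2, p_raw = NA_real_,
                      p_bonferroni = NA_real_, stringsAsFactors = FALSE)
    if (stats::sd(c(x, y)) > 0) {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      res$t <- unname(tt$statistic)
      res$df <- unname(tt$parameter)
      res$p_raw <- tt$p.value
      res$p_bonferroni <- min(1, m * tt$p.value)
    }
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$from, out$to), ]
}

#' Pooled two-sample t from summary statistics
#'
#' `t = (mean1 - mean2) / (sp * sqrt(1/n1 + 1/n2))` with the pooled SD
#' `sp^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)`.  Useful to
#' verify printed group comparisons from reported means and SDs.
#'
#' @param mean1,sd1,n1 first sample moments and size.
#' @param mean2,sd2,n2 second sample moments and size.
#' @return A data frame with `t`, `df`, `p` (two-sided).
#' @examples
#' t_from_summary(31.44, 4.63, 66, 32.79, 6.83, 61)  # t(125) = -1.31
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) .stopf("need n >= 2 in both samples")
  if (sd1 <= 0 || sd2 <= 0) .stopf("standard deviations must be positive")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  data.frame(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' 2 x 2 chi-square test
#'
#' Pearson chi-square on a 2 x 2 contingency table (df = 1), with optional
#' Yates continuity correction.
#'
#' @param counts a 2 x 2 matrix of non-negative integer counts.
#' @param yates apply the continuity correction? (default `TRUE`).
#' @return A data frame with `chi2`, `df`, `p`, `yates`.
#' @examples
#' chi_square_2x2(matrix(c(50, 11, 50, 16), 2, byrow = TRUE))  # 0.41
#' @export
chi_square_2x2 <- function(counts, yates = TRUE) {
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(2L, 2L))) .stopf("counts must be 2 x 2")
  if (any(counts < 0) || any(counts != round(counts))) .stopf("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) .stopf("zero marginal")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  data.frame(chi2 = unname(ct$statistic), df = unname(ct$parameter),
             p = ct$p.value, yates = yates)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3), finite, with
#'   non-zero variance.
#' @return A data frame with `r`, `n`, `p` (two-sided).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  if (length(x) < 3) .stopf("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) .stopf("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) .stopf("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}
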