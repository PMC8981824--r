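# split-plot oracle by explicit projections (balanced groups only):
# between F from subject means; within/interaction F from orthonormal
# within-subject contrasts
split_plot_oracle <- function(tab) {
  wide <- stats::reshape(tab[, c("subject", "group", "class", "value")],
                         idvar = c("subject", "group"), timevar = "class",
                         direction = "wide")
  Y <- as.matrix(wide[, -(1:2)])
  g <- factor(wide$group)
  N <- nrow(Y); k <- ncol(Y)
  M <- qr.Q(qr(cbind(1, contr.helmert(k))))[, -1, drop = FALSE]
  Z <- Y %*% M
  zg <- apply(Z, 2, tapply, g, mean)
  ng <- table(g)
  zbar <- colMeans(Z)
  ss_class <- N * sum(zbar^2)
  ss_int <- sum(ng * rowSums(sweep(zg, 2, zbar)^2))
  R <- Z - zg[g, , drop = FALSE]
  ss_err <- sum(R^2)
  w <- rowMeans(Y)
  f_btw <- anova(lm(w ~ g))$`F value`[1]
  list(
    f_group = f_btw,
    f_class = (ss_class / (k - 1)) / (ss_err / ((k - 1) * (N - 2))),
    f_int = (ss_int / (k - 1)) / (ss_err / ((k - 1) * (N - 2)))
  )
}

test_that("mixed ANOVA reproduces the design degrees of freedom", {
  tab <- sim_param_table(61, 66, seed = 2)
  res <- mixed_anova(tab, "value")
  expect_equal(res$df1[res$effect == "group"], 1)
  expect_equal(res$df2[res$effect == "group"], 125)
  expect_equal(res$df1[res$effect == "group:class"], 3)
  expect_equal(res$df2[res$effect == "group:class"], 375)
  expect_true(all(res$F >= 0))
  eps <- res$epsilon_gg[res$effect == "class"]
  expect_gte(eps, 1 / 3); expect_lte(eps, 1)
})

test_that("mixed ANOVA agrees with an explicit split-plot projection oracle", {
  for (s in 1:3) {
    tab <- sim_param_table(6, 6, seed = s, group_shift = 0.5,
                           class_shift = c(0, 0.5, -0.5, 0.2))
    res <- mixed_anova(tab, "value")
    orc <- split_plot_oracle(tab)
    expect_equal(res$F[res$effect == "group"], orc$f_group, tolerance = 1e-10)
    expect_equal(res$F[res$effect == "class"], orc$f_class, tolerance = 1e-10)
    expect_equal(res$F[res$effect == "group:class"], orc$f_int, tolerance = 1e-10)
  }
})

test_that("compound-symmetric data satisfy sphericity (epsilon near 1)", {
  tab <- sim_param_table(20, 20, seed = 4, sd_subj = 2, sd_noise = 1)
  res <- mixed_anova(tab, "value")
  expect_equal(res$epsilon_gg[res$effect == "class"], 1, tolerance = 0.08)
  expect_false(res$sphericity_violated[res$effect == "class"])
})

test_that("mixed ANOVA F is invariant to location and scale changes", {
  tab <- sim_param_table(8, 8, seed = 5, group_shift = 1)
  res0 <- mixed_anova(tab, "value")
  tab2 <- tab; tab2$value <- 3 * tab$value + 100
  res2 <- mixed_anova(tab2, "value")
  expect_equal(res0$F, res2$F, tolerance = 1e-9)
  expect_equal(res0$p_uncorrected, res2$p_uncorrected, tolerance = 1e-9)
})

test_that("between-group F equals the squared pooled t on subject means", {
  tab <- sim_param_table(10, 12, seed = 6, group_shift = 0.8)
  res <- mixed_anova(tab, "value")
  w <- aggregate(value ~ subject + group, tab, mean)
  tt <- t.test(value ~ group, w, var.equal = TRUE)
  expect_equal(res$F[res$effect == "group"], unname(tt$statistic)^2,
               tolerance = 1e-9)
  expect_error(mixed_anova(tab[-1, ], "value"), "missing cells")
})

test_that("simple effects are pooled per-class two-sample t-tests", {
  tab <- sim_param_table(61, 66, seed = 7)
  se <- simple_effects(tab, "value")
  expect_equal(se$df, rep(125, 4))
  # identical groups: t = 0
  tabA <- sim_param_table(5, 5, seed = 8)
  for (cl in MS_CLASSES) {
    i1 <- which(tabA$class == cl & tabA$subject <= 5)
    i2 <- which(tabA$class == cl & tabA$subject > 5)
    tabA$value[i2] <- tabA$value[i1]
  }
  se0 <- simple_effects(tabA, "value")
  expect_equal(se0$t, rep(0, 4), tolerance = 1e-12)
  # hand formula on a 6-subject table
  tab6 <- sim_param_table(3, 3, seed = 9)
  se6 <- simple_effects(tab6, "value")
  d <- tab6[tab6$class == "A", ]
  x <- d$value[d$group == "g1"]; y <- d$value[d$group == "g2"]
  sp <- sqrt(((2) * var(x) + (2) * var(y)) / 4)
  expect_equal(se6$t[se6$class == "A"], (mean(x) - mean(y)) / (sp * sqrt(2 / 3)),
               tolerance = 1e-12)
})

test_that("transition tests Bonferroni-correct with m = 12 and cap at 1", {
  set.seed(10)
  tab <- expand.grid(subject = 1:20, from = MS_CLASSES, to = MS_CLASSES,
                     stringsAsFactors = FALSE)
  tab <- tab[tab$from != tab$to, ]
  tab$group <- ifelse(tab$subject <= 10, "g1", "g2")
  tab$percent <- rnorm(nrow(tab), 100 / 12, 1)
  res <- transition_tests(tab)
  expect_equal(nrow(res), 12)
  expect_equal(res$df, rep(18, 12))
  ok <- !is.na(res$p_raw)
  expect_equal(res$p_bonferroni[ok], pmin(1, 12 * res$p_raw[ok]), tolerance = 1e-12)
  # constant transition -> undefined t reported as missing
  tab$percent[tab$from == "A" & tab$to == "B"] <- 5
  res2 <- transition_tests(tab)
  expect_true(is.na(res2$t[res2$from == "A" & res2$to == "B"]))
})

test_that("t from printed summary statistics reproduces reference values", {
  # age row: HC minus patients
  expect_equal(round(t_from_summary(31.44, 4.63, 66, 32.79, 6.83, 61)$t, 2), -1.31)
  # cognitive screening row
  expect_equal(round(t_from_summary(28.50, 0.90, 66, 28.18, 1.12, 61)$t, 2), 1.78)
  expect_equal(t_from_summary(28.50, 0.90, 66, 28.18, 1.12, 61)$df, 125)
  expect_equal(t_from_summary(5, 1, 10, 5, 1, 10)$t, 0)
  expect_error(t_from_summary(1, 0, 10, 2, 1, 10), "positive")
})

test_that("2x2 chi-square matches the reference value and a permutation oracle", {
  sex <- matrix(c(50, 11, 50, 16), 2, byrow = TRUE)
  expect_equal(round(chi_square_2x2(sex, yates = TRUE)$chi2, 2), 0.41)
  expect_gt(chi_square_2x2(sex, yates = FALSE)$chi2, 0.7)  # uncorrected differs
  expect_equal(chi_square_2x2(matrix(c(10, 5, 10, 5), 2), yates = FALSE)$chi2, 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "marginal")
  # Monte-Carlo permutation oracle: fixed-margin label shuffling realises
  # the conditional test, which the continuity-corrected p approximates
  p_obs <- chi_square_2x2(sex, yates = TRUE)$p
  x <- rep(c("F", "M", "F", "M"), c(50, 11, 50, 16))
  g <- rep(c(1, 2), c(61, 66))
  set.seed(11)
  stat0 <- suppressWarnings(chisq.test(table(g, x), correct = FALSE)$statistic)
  perm <- replicate(2000, {
    suppressWarnings(chisq.test(table(g, sample(x)), correct = FALSE)$statistic)
  })
  expect_equal(mean(perm >= stat0 - 1e-12), p_obs, tolerance = 0.02 / p_obs)
})

test_that("Pearson correlation helper matches closed forms", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -2 * x + 7)$r, -1)
  r <- pearson_correlation(x, rev(x))
  expect_equal(r$n, 5)
  expect_error(pearson_correlation(x, rep(1, 5)), "zero variance")
  expect_error(pearson_correlation(x[1:2], x[1:2]), "at least 3")
})
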