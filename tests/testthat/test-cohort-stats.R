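test_that("rm_two_way_anova matches a textbook sums-of-squares oracle", {
  # 3 subjects (structures) x 2 within conditions (datasources)
  vals <- data.frame(structure = rep(c("S1", "S2", "S3"), 2),
                     datasource = rep(c("control", "deserts"), each = 3),
                     value = c(4.1, 5.0, 4.6, 5.2, 6.1, 5.4))
  t <- mean_expression_table(vals$structure, vals$datasource, vals$value)
  got <- rm_two_way_anova(t)

  # oracle: one-within-factor repeated-measures decomposition by hand
  y <- matrix(vals$value, nrow = 3) # subjects x conditions
  grand <- mean(y)
  ss_cond <- 3 * sum((colMeans(y) - grand)^2)
  ss_subj <- 2 * sum((rowMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f_oracle <- (ss_cond / 1) / (ss_err / 2)
  expect_equal(got$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(got$df1, 1)
  expect_equal(got$df2, 2)
  expect_equal(got$p, stats::pf(f_oracle, 1, 2, lower.tail = FALSE),
               tolerance = 1e-10)

  # identical values across datasources
  same <- mean_expression_table(rep(c("S1", "S2", "S3"), 2),
                                rep(c("control", "deserts"), each = 3),
                                rep(c(4, 5, 6), 2))
  got0 <- rm_two_way_anova(same)
  expect_equal(got0$statistic, 0)
  expect_equal(got0$p, 1)

  # unbalanced design errors, naming the hole
  expect_error(rm_two_way_anova(mean_expression_table(
    c("S1", "S2", "S1"), c("control", "control", "deserts"), 1:3)),
    "S2:deserts")
})

test_that("a planted datasource shift is detected below 0.01", {
  set.seed(12)
  sts <- paste0("S", 1:6)
  t <- mean_expression_table(
    structure = rep(sts, 2),
    datasource = rep(c("control", "deserts"), each = 6),
    value = rnorm(12, 5, 0.1) + rep(c(0, 0.8), each = 6))
  expect_lt(rm_two_way_anova(t)$p, 0.01)
})

test_that("posthoc_pairwise_anova Bonferroni-corrects per-structure ANOVAs", {
  set.seed(7)
  sts <- c("S1", "S2", "S3")
  n_rep <- 8
  df <- expand.grid(rep = 1:n_rep, datasource = c("control", "deserts"),
                    structure = sts, stringsAsFactors = FALSE)
  df$value <- rnorm(nrow(df), 5, 0.2)
  # shift only S2's deserts values
  df$value[df$structure == "S2" & df$datasource == "deserts"] <-
    df$value[df$structure == "S2" & df$datasource == "deserts"] + 3
  t <- mean_expression_table(df$structure, df$datasource, df$value,
                             replicate = df$rep)
  got <- posthoc_pairwise_anova(t)
  expect_equal(got$adj_p, pmin(1, got$p * length(sts)))
  expect_lt(got$adj_p[got$group == "S2"], 0.01)
  expect_true(all(got$adj_p[got$group != "S2"] > 0.05))

  # a structure with identical sources reports p = 1
  df2 <- df[df$structure == "S1", ]
  df2$value <- rep(rep(c(4, 5), each = 1), n_rep)[seq_len(nrow(df2))]
  df2$value <- rep(4, nrow(df2))
  t2 <- mean_expression_table(df2$structure, df2$datasource, df2$value,
                              replicate = df2$rep)
  got2 <- suppressWarnings(posthoc_pairwise_anova(t2)) # perfect fit warns
  expect_equal(got2$p, 1)
})

test_that("grubbs_test matches the closed-form oracle on both sides", {
  x <- c(1, 2, 3, 100)
  got <- grubbs_test(x)
  o_max <- oracle_grubbs(x, "max")
  expect_equal(got$statistic[got$term == "max"], o_max$g, tolerance = 1e-12)
  expect_equal(got$p[got$term == "max"], o_max$p, tolerance = 1e-12)
  expect_lt(got$p[got$term == "max"], 0.01) # flagged at alpha = 0.01
  expect_equal(got$statistic[got$term == "min"],
               oracle_grubbs(x, "min")$g, tolerance = 1e-12)

  sym <- grubbs_test(c(-1, 0, 1))
  expect_true(all(sym$p > 0.01)) # inside the expected range

  expect_error(grubbs_test(rep(2, 5)), "zero variance")
  expect_error(grubbs_test(c(1, 2)), "n >= 3")
})

test_that("kruskal_wallis matches hand-ranked oracles, with and without ties", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  got <- kruskal_wallis(v, g)
  expect_equal(got$statistic, oracle_kruskal_h(v, g), tolerance = 1e-12)
  expect_equal(got$p, stats::pchisq(got$statistic, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  vt <- c(1, 2, 2, 3, 3, 3, 5, 6, 2)
  gt <- rep(c("a", "b", "c"), each = 3)
  expect_equal(kruskal_wallis(vt, gt)$statistic, oracle_kruskal_h(vt, gt),
               tolerance = 1e-12)

  expect_equal(kruskal_wallis(rep(1, 6), g)$statistic, 0)
  expect_equal(kruskal_wallis(rep(1, 6), g)$p, 1)
})

test_that("kruskal_wallis with 2 groups tracks the wilcoxon decision at n >= 20", {
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(22)
    y <- rnorm(25, 0.4)
    kw <- kruskal_wallis(c(x, y), rep(c("x", "y"), c(22, 25)))$p
    wx <- wilcoxon_rank_sum(x, y)$p
    expect_equal(kw < 0.05, wx < 0.05, info = sprintf("case %d", i))
  }
})

test_that("nested_model_comparison isolates the extra factor's contribution", {
  set.seed(9)
  sts <- paste0("S", 1:6)
  base <- expand.grid(structure = sts,
                      datasource = c("deserts", "deserts_sweeps"),
                      rep = 1:5, stringsAsFactors = FALSE)
  # planted structure effect
  eff <- setNames(seq(0, 2.5, length.out = 6), sts)
  v <- rnorm(nrow(base), 5, 0.2) + eff[base$structure]
  t <- mean_expression_table(base$structure, base$datasource, v,
                             replicate = base$rep)
  got <- nested_model_comparison(t, "structure")
  cmp <- got[got$test == "nested_model_comparison", ]
  expect_lt(cmp$p, 0.01)
  # oracle: base-R nested lm F-test
  d <- data.frame(value = v, datasource = factor(base$datasource),
                  fac = factor(base$structure))
  a <- anova(lm(value ~ datasource, d), lm(value ~ datasource + fac, d))
  expect_equal(cmp$statistic, a$F[2], tolerance = 1e-10)
  expect_equal(cmp$p, a$`Pr(>F)`[2], tolerance = 1e-10)
  expect_true(any(got$test == "datasource_coef"))

  # degenerate: single-level factor, reduced == full
  t1 <- mean_expression_table(rep("S1", 10),
                              rep(c("deserts", "deserts_sweeps"), 5),
                              rnorm(10))
  cmp1 <- nested_model_comparison(t1, "structure")
  expect_equal(cmp1$statistic[1], 0)
  expect_equal(cmp1$p[1], 1)
})

test_that("tukey_posthoc contrasts stages on per-structure means", {
  sts <- paste0("S", 1:5)
  stages <- c("Fetal1", "Fetal2", "Adulthood")
  base <- expand.grid(structure = sts, stage = stages,
                      stringsAsFactors = FALSE)

  # identical stage means -> all adjusted p = 1
  t0 <- mean_expression_table(base$structure, "deserts",
                              rep(c(4, 5, 4.5, 4.2, 4.8), 3),
                              stage = base$stage)
  expect_true(all(tukey_posthoc(t0)$adj_p > 0.999))

  # one shifted stage: only its contrasts significant
  set.seed(2)
  v <- rnorm(nrow(base), 5, 0.1) + ifelse(base$stage == "Fetal1", 2, 0)
  t1 <- mean_expression_table(base$structure, "deserts", v, stage = base$stage)
  got <- tukey_posthoc(t1)
  hit <- grepl("Fetal1", got$term)
  expect_true(all(got$adj_p[hit] < 0.05))
  expect_true(all(got$adj_p[!hit] > 0.05))

  # adjusted p is never below the raw pairwise-t p on the same contrast
  agg <- stats::aggregate(value ~ structure + stage, as.data.frame(t1), mean)
  fit <- stats::aov(value ~ stage, agg)
  sigma2 <- sum(fit$residuals^2) / fit$df.residual
  n_per <- length(sts)
  for (i in seq_len(nrow(got))) {
    raw_t <- abs(got$statistic[i]) / sqrt(2 * sigma2 / n_per)
    raw_p <- 2 * stats::pt(raw_t, fit$df.residual, lower.tail = FALSE)
    expect_gte(got$adj_p[i] + 1e-12, raw_p)
  }

  # single level -> empty report
  t2 <- mean_expression_table(sts, "deserts", rnorm(5),
                              stage = rep("Fetal1", 5))
  expect_equal(nrow(tukey_posthoc(t2)), 0)
})
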