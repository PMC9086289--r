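# Cohort statistics battery comparing gene subsets (deserts, deserts with
# sweep overlap) against matched control regions: repeated-measures ANOVA,
# per-structure post-hocs with Bonferroni, Grubbs outlier test,
# Kruskal-Wallis, nested linear-model comparison, Tukey post-hoc on stages.
# Every function returns test_report rows (test, term, statistic, df1, df2,
# p, adj_p, group).

#' Construct a mean-expression table
#'
#' One row per (structure[, stage], datasource, replicate) holding a mean
#' log2 expression value. `datasource` distinguishes control regions from
#' the gene subsets of interest.
#'
#' @param structure brain structure label.
#' @param datasource one of `"control"`, `"deserts"`, `"deserts_sweeps"`
#'   (other labels allowed but logged).
#' @param value mean log2 expression.
#' @param stage optional stage label.
#' @param replicate optional replicate id (e.g. random-region set index).
#' @return data frame of class `mean_expression_table`.
#' @export
mean_expression_table <- function(structure, datasource, value, stage = NULL,
                                  replicate = NULL) {
  df <- data.frame(structure = as.character(structure),
                   datasource = as.character(datasource),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  df$stage <- if (is.null(stage)) NA_character_ else as.character(stage)
  df$replicate <- if (is.null(replicate)) 1L else as.integer(replicate)
  known <- c("control", "deserts", "deserts_sweeps")
  unknown <- setdiff(unique(df$datasource), known)
  if (length(unknown)) {
    ds_log("mean_expression_table",
           sprintf("non-standard datasource label(s): %s",
                   paste(unknown, collapse = ", ")))
  }
  structure(df, class = c("mean_expression_table", "data.frame"))
}

check_balanced <- function(t) {
  tab <- table(t$structure, t$datasource)
  missing <- which(tab == 0, arr.ind = TRUE)
  if (nrow(missing)) {
    cells <- apply(missing, 1, function(i) {
      paste(rownames(tab)[i[1]], colnames(tab)[i[2]], sep = ":")
    })
    stop("unbalanced design, missing cell(s): ",
         paste(cells, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Repeated-measures two-way ANOVA of mean expression by datasource
#'
#' Datasource is the within-subject factor and structure the subject
#' identifier: `aov(value ~ datasource + Error(structure))` on per-cell
#' means. Requires every structure observed in every datasource.
#'
#' @param t a `mean_expression_table` with >= 2 datasources.
#' @return a `test_report` row for the datasource effect (F, df, p).
#' @export
rm_two_way_anova <- function(t) {
  ds_stopifnot(length(unique(t$datasource)) >= 2,
               "rm_two_way_anova: need >= 2 datasources")
  check_balanced(t)
  # one value per (structure, datasource): average over replicates/stages
  agg <- stats::aggregate(value ~ structure + datasource, data = t, FUN = mean)
  agg$structure <- factor(agg$structure)
  agg$datasource <- factor(agg$datasource)
  fit <- aov(value ~ datasource + Error(structure), data = agg)
  s <- summary(fit)
  tab <- s[["Error: Within"]][[1]]
  rn <- trimws(rownames(tab))
  f <- tab[rn == "datasource", "F value"]
  p <- tab[rn == "datasource", "Pr(>F)"]
  # guard: an effect sum-of-squares at rounding-noise level is zero
  if (tab[rn == "datasource", "Sum Sq"] <= 1e-12 * max(sum(agg$value^2), 1)) {
    f <- 0
    p <- 1
  }
  if (!is.finite(f)) { # zero between- and within-source variance
    f <- 0
    p <- 1
  }
  test_report("rm_two_way_anova", "datasource", statistic = f,
              df1 = tab[rn == "datasource", "Df"],
              df2 = tab[rn == "Residuals", "Df"], p = p)
}

#' Post-hoc per-structure ANOVA with Bonferroni correction
#'
#' One one-way ANOVA (datasource effect) per structure over replicate
#' values, with the Bonferroni family equal to the number of structures.
#'
#' @param t a `mean_expression_table` with replicate values per cell.
#' @return `test_report` rows, one per structure (`group` column).
#' @export
posthoc_pairwise_anova <- function(t) {
  check_balanced(t)
  sts <- sort(unique(t$structure))
  rows <- lapply(sts, function(s) {
    sub <- t[t$structure == s, , drop = FALSE]
    sub$datasource <- factor(sub$datasource)
    ds_stopifnot(nrow(sub) > length(levels(sub$datasource)),
                 "posthoc_pairwise_anova: no residual df for structure ", s,
                 " (need replicate values)")
    a <- anova(lm(value ~ datasource, data = sub))
    f <- a["datasource", "F value"]
    p <- a["datasource", "Pr(>F)"]
    if (!is.finite(f) ||
        a["datasource", "Sum Sq"] <= 1e-12 * max(sum(sub$value^2), 1)) {
      f <- 0
      p <- 1
    }
    test_report("posthoc_pairwise_anova", "datasource", statistic = f,
                df1 = a["datasource", "Df"], df2 = a["Residuals", "Df"],
                p = p, group = s)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bonferroni(out$p, length(sts))
  out
}

#' Grubbs outlier test (both sides)
#'
#' `G = max |x - mean| / sd`; the one-sided p-value uses the classical
#' t-distribution relation `t^2 = n (n-2) G^2 / ((n-1)^2 - n G^2)` with
#' `p = min(1, n * P(T_{n-2} > t))`. Both the maximum-side and
#' minimum-side variants are reported. Assumes approximate normality.
#'
#' @param values numeric vector, `n >= 3`, non-zero variance.
#' @param alpha flagging threshold (an outlier is declared when p < alpha).
#' @return `test_report` rows for terms `max` and `min`; `statistic` is G.
#' @export
grubbs_test <- function(values, alpha = 0.01) {
  n <- length(values)
  ds_stopifnot(n >= 3, "grubbs_test: need n >= 3")
  s <- sd(values)
  ds_stopifnot(s > 0, "grubbs_test: zero variance")
  m <- mean(values)
  g_p <- function(g) {
    denom <- (n - 1)^2 - n * g^2
    if (denom <= 0) return(0)
    t <- sqrt(n * (n - 2) * g^2 / denom)
    min(1, n * (1 - pt(t, n - 2)))
  }
  g_max <- (max(values) - m) / s
  g_min <- (m - min(values)) / s
  rbind(
    test_report("grubbs", "max", statistic = g_max, df1 = n - 2,
                p = g_p(g_max)),
    test_report("grubbs", "min", statistic = g_min, df1 = n - 2,
                p = g_p(g_min)))
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H with a chi-square p-value (via [stats::kruskal.test()]).
#' All values identical returns H = 0, p = 1 by convention.
#'
#' @param values numeric vector.
#' @param groups group labels, >= 2 groups each with >= 1 value.
#' @return a `test_report` row (statistic = H, df1 = k - 1).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  ds_stopifnot(nlevels(droplevels(groups)) >= 2,
               "kruskal_wallis: need >= 2 groups")
  if (length(unique(values)) == 1) {
    return(test_report("kruskal_wallis", "group", statistic = 0,
                       df1 = nlevels(droplevels(groups)) - 1, p = 1))
  }
  k <- kruskal.test(values, groups)
  test_report("kruskal_wallis", "group",
              statistic = unname(k$statistic), df1 = unname(k$parameter),
              p = k$p.value)
}

#' Nested linear-model comparison
#'
#' Fits `value ~ datasource` (reduced) and `value ~ datasource + factor`
#' (full) as fixed-effect linear models and compares them with an F-test
#' (`anova(reduced, full)`): does the factor (structure or stage) explain
#' variability beyond selection status? Also reports the datasource
#' coefficient p-value from the full model.
#'
#' @param t a `mean_expression_table`.
#' @param with_factor `"structure"` or `"stage"`.
#' @return `test_report` rows: `model_comparison` (F-test between fits) and
#'   `datasource_coef` rows.
#' @export
nested_model_comparison <- function(t, with_factor = c("structure", "stage")) {
  with_factor <- match.arg(with_factor)
  fac <- t[[with_factor]]
  ds_stopifnot(!anyNA(fac), "nested_model_comparison: missing ", with_factor,
               " values")
  d <- data.frame(value = t$value, datasource = factor(t$datasource),
                  fac = factor(fac))
  reduced <- lm(value ~ datasource, data = d)
  if (nlevels(d$fac) < 2) {
    cmp <- test_report("nested_model_comparison", with_factor, statistic = 0,
                       p = 1)
    full <- reduced
  } else {
    full <- lm(value ~ datasource + fac, data = d)
    alias <- is.na(coef(full))
    if (any(alias)) {
      stop("nested_model_comparison: rank-deficient design, collinear: ",
           paste(names(coef(full))[alias], collapse = ", "), call. = FALSE)
    }
    a <- anova(reduced, full)
    cmp <- test_report("nested_model_comparison", with_factor,
                       statistic = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2],
                       p = a$`Pr(>F)`[2])
  }
  cs <- summary(full)$coefficients
  coef_rows <- grep("^datasource", rownames(cs))
  coefs <- do.call(rbind, lapply(coef_rows, function(i) {
    test_report("datasource_coef", rownames(cs)[i], statistic = cs[i, "t value"],
                df1 = full$df.residual, p = cs[i, "Pr(>|t|)"])
  }))
  rbind(cmp, coefs)
}

#' Tukey post-hoc on stage contrasts, corrected for repeated measures
#'
#' Contrasts are computed on per-subject stage means (one value per
#' structure x stage, averaging replicates first) and adjusted with the
#' studentized-range (Tukey HSD) procedure.
#'
#' @param t a `mean_expression_table` with a `stage` column.
#' @param factor contrast factor (only `"stage"` supported).
#' @return `test_report` rows, one per stage pair (`term` = "a-b";
#'   `statistic` is the mean difference); empty for a single level.
#' @export
tukey_posthoc <- function(t, factor = "stage") {
  ds_stopifnot(identical(factor, "stage"), "tukey_posthoc: factor must be 'stage'")
  ds_stopifnot(!anyNA(t$stage), "tukey_posthoc: missing stage values")
  agg <- stats::aggregate(value ~ structure + stage, data = t, FUN = mean)
  agg$stage <- base::factor(agg$stage)
  if (nlevels(agg$stage) < 2) {
    return(test_report("tukey_posthoc", "none")[0, , drop = FALSE])
  }
  fit <- aov(value ~ stage, data = agg)
  tk <- TukeyHSD(fit)$stage
  out <- do.call(rbind, lapply(seq_len(nrow(tk)), function(i) {
    test_report("tukey_posthoc", rownames(tk)[i], statistic = tk[i, "diff"],
                p = tk[i, "p adj"], adj_p = tk[i, "p adj"])
  }))
  out
}
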