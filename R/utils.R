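#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov anova binom.test coef dist kruskal.test lm lm.fit
#'   median prcomp pt pnorm pwilcox rnorm runif sd setNames TukeyHSD
#' @importFrom utils read.table write.table head combn
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# one structured log line per pipeline stage; suppress with options(desertscope.quiet = TRUE)
ds_log <- function(stage, ...) {
  if (isTRUE(getOption("desertscope.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[desertscope:%s] %s", stage, paste0(...)))
  invisible(NULL)
}

ds_stopifnot <- function(ok, ...) {
  if (!isTRUE(ok)) stop(paste0(...), call. = FALSE)
  invisible(NULL)
}

# uniform row container for every statistical test in the package
test_report <- function(test, term, statistic = NA_real_, df1 = NA_real_,
                        df2 = NA_real_, p = NA_real_, adj_p = NA_real_,
                        group = NA_character_) {
  data.frame(test = test, term = term, statistic = statistic,
             df1 = df1, df2 = df2, p = p, adj_p = adj_p, group = group,
             stringsAsFactors = FALSE)
}

#' Bonferroni adjustment
#'
#' Multiplies raw p-values by the family size and caps at 1.
#'
#' @param p numeric vector of raw p-values.
#' @param m family size; defaults to `length(p)`.
#' @return adjusted p-values, same length as `p`.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, m * p)
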