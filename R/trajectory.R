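# Segmented (breakpoint) regression of single-gene expression time courses.
# Continuous piecewise-linear least squares with breakpoints placed at
# observed time values; exhaustive search over placements for k = 0..3
# breakpoints, BIC model selection across k, adjusted R^2 reporting gate.

#' Construct a time series for one gene in one structure
#'
#' @param time numeric time indices (stage rank or age rank); repeated
#'   values are allowed (replicate samples at one stage) and kept.
#' @param value expression values, same length.
#' @param gene,structure labels carried along.
#' @return list of class `time_series`, sorted by time.
#' @export
time_series <- function(time, value, gene = "gene", structure = "structure") {
  ds_stopifnot(length(time) == length(value), "time_series: length mismatch")
  o <- order(time)
  structure(list(time = as.numeric(time)[o], value = as.numeric(value)[o],
                 gene = gene, structure = structure), class = "time_series")
}

# hinge design matrix for breakpoints b (values on the time axis):
# y ~ 1 + t + pmax(t - b_j, 0)
hinge_design <- function(t, breaks) {
  x <- cbind(1, t)
  for (b in breaks) x <- cbind(x, pmax(t - b, 0))
  x
}

# points at exactly a breakpoint belong to the left segment
segment_index <- function(t, breaks) {
  findInterval(t, c(-Inf, breaks), left.open = TRUE, rightmost.closed = FALSE)
}

valid_breaksets <- function(t, k, min_seg) {
  cand <- unique(t)
  cand <- cand[-length(cand)] # a break at the last time leaves an empty segment
  if (k == 0) return(list(numeric(0)))
  if (length(cand) < k) return(list())
  sets <- combn(cand, k, simplify = FALSE)
  Filter(function(b) {
    seg <- segment_index(t, b)
    length(unique(seg)) == k + 1 && min(table(seg)) >= min_seg
  }, sets)
}

#' Fit a segmented regression to one gene's trajectory
#'
#' Exhaustive search over breakpoint placements at observed time points for
#' `k = 0..max_breakpoints`, requiring at least `min_seg_samples` points
#' per segment; continuous piecewise-linear least squares within each
#' candidate. Selection across `k` is forward-stepwise by extended BIC:
#' each estimated breakpoint location counts as a parameter and the
#' `choose(C, k)` multiplicity of the placement search enters the penalty
#' (a plain BIC on an exhaustively searched changepoint model is known to
#' overfit pure noise); stepping stops at the first k that fails to
#' improve. Genes whose mean expression is below `min_mean_expr` are
#' rejected without fitting, mirroring the minimum-mean-expression gate of
#' the source workflow. The adjusted R-squared uses the effective model
#' size (slopes, intercept and breakpoints).
#'
#' @param ts a `time_series`.
#' @param max_breakpoints maximum number of slope changes (default 3).
#' @param min_seg_samples minimum points per segment (default 2).
#' @param min_mean_expr minimum mean expression to attempt a fit (default 2).
#' @param slope_alpha significance level for the per-segment direction call.
#' @return list of class `trajectory_fit` with `k`, `breakpoints`, `slopes`,
#'   `slope_p`, `directions` (`"up"`/`"down"`/`"flat"`), `fitted`,
#'   `adj_r2`, `bic`, `rejected = FALSE`; or a rejected stub with
#'   `rejected = TRUE` and `reason` (`"low_expression"` / `"too_short"`).
#' @export
fit_segmented <- function(ts, max_breakpoints = 3, min_seg_samples = 2,
                          min_mean_expr = 2, slope_alpha = 0.05) {
  stopifnot(inherits(ts, "time_series"))
  reject <- function(reason) {
    structure(list(gene = ts$gene, structure = ts$structure,
                   rejected = TRUE, reason = reason, adj_r2 = NA_real_),
              class = "trajectory_fit")
  }
  if (mean(ts$value) < min_mean_expr) return(reject("low_expression"))
  t <- ts$time
  y <- ts$value
  n <- length(y)
  if (n < 3 || length(unique(t)) < 2) return(reject("too_short"))
  tss <- sum((y - mean(y))^2)
  # floor the RSS so numerically-perfect fits tie and the parameter
  # penalty (hence the smallest k) decides
  rss_floor <- max(1e-10, 1e-10 * tss)
  n_cand <- length(unique(t)) - 1
  best_at_k <- function(k) {
    best <- NULL
    for (breaks in valid_breaksets(t, k, min_seg_samples)) {
      x <- hinge_design(t, breaks)
      if (qr(x)$rank < ncol(x)) next
      fit <- lm.fit(x, y)
      rss <- max(sum(fit$residuals^2), rss_floor)
      p_eff <- ncol(x) + k # breakpoint locations are parameters too
      ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
      bic <- -2 * ll + log(n) * (p_eff + 1) + 2 * lchoose(n_cand, k)
      if (is.null(best) || bic < best$bic - 1e-9) {
        best <- list(k = k, breaks = breaks, x = x, fit = fit, bic = bic,
                     p_eff = p_eff)
      }
    }
    best
  }
  best <- best_at_k(0)
  if (!is.null(best)) {
    for (k in seq_len(max_breakpoints)) {
      cand <- best_at_k(k)
      if (is.null(cand) || cand$bic >= best$bic - 1e-9) break
      best <- cand
    }
  }
  if (is.null(best)) return(reject("too_short"))
  k <- best$k
  x <- best$x
  fit <- best$fit
  rss <- sum(fit$residuals^2)
  p <- ncol(x)
  df_res <- n - p
  df_eff <- n - best$p_eff
  adj_r2 <- if (tss == 0) 1 else
    1 - (rss / max(df_eff, 1)) / (tss / (n - 1))
  sigma2 <- if (df_res > 0) rss / df_res else 0
  xtx_inv <- chol2inv(chol(crossprod(x)))
  beta <- fit$coefficients
  # slope of segment j = beta_t + sum of the first (j-1) hinge coefficients
  slopes <- numeric(k + 1)
  slope_p <- numeric(k + 1)
  for (j in seq_len(k + 1)) {
    cvec <- rep(0, p)
    cvec[2] <- 1
    if (j > 1) cvec[2 + seq_len(j - 1)] <- 1
    slopes[j] <- sum(cvec * beta)
    se <- sqrt(sigma2 * drop(t(cvec) %*% xtx_inv %*% cvec))
    slope_p[j] <- if (df_res > 0 && se > 0) {
      2 * (1 - pt(abs(slopes[j] / se), df_res))
    } else if (se == 0 && abs(slopes[j]) > 1e-12) 0 else 1
  }
  directions <- ifelse(slope_p < slope_alpha & slopes > 0, "up",
                       ifelse(slope_p < slope_alpha & slopes < 0, "down",
                              "flat"))
  out <- structure(list(gene = ts$gene, structure = ts$structure,
                        rejected = FALSE, reason = NA_character_,
                        k = k, breakpoints = best$breaks,
                        intercept = beta[1], slopes = slopes,
                        slope_p = slope_p, directions = directions,
                        fitted = drop(x %*% beta), time = t, value = y,
                        adj_r2 = adj_r2, bic = best$bic),
                   class = "trajectory_fit")
  out$shape <- classify_shape(out)
  out
}

#' @export
print.trajectory_fit <- function(x, ...) {
  if (isTRUE(x$rejected)) {
    cat(sprintf("<trajectory_fit> %s / %s: rejected (%s)\n", x$gene,
                x$structure, x$reason))
  } else {
    cat(sprintf("<trajectory_fit> %s / %s: k = %d [%s], adj R^2 = %.3f, shape = %s\n",
                x$gene, x$structure, x$k,
                paste(x$breakpoints, collapse = ", "), x$adj_r2, x$shape))
  }
  invisible(x)
}

#' Retain trajectory fits passing the adjusted R-squared gate
#'
#' Keeps accepted fits with adjusted R^2 >= `r2_min`; an exact boundary hit
#' is retained and logged. Rejected fits never pass.
#'
#' @param fits list of `trajectory_fit`s.
#' @param r2_min gate (default 0.5).
#' @return the retained sublist.
#' @export
filter_fits <- function(fits, r2_min = 0.5) {
  if (inherits(fits, "trajectory_fit")) fits <- list(fits)
  keep <- vapply(fits, function(f) {
    if (isTRUE(f$rejected) || !is.finite(f$adj_r2)) return(FALSE)
    if (abs(f$adj_r2 - r2_min) < 1e-12) {
      ds_log("filter_fits", sprintf("%s/%s at the R^2 boundary (%.3f), retained",
                                    f$gene, f$structure, f$adj_r2))
    }
    f$adj_r2 >= r2_min
  }, logical(1))
  fits[keep]
}

#' Classify a fitted trajectory's shape
#'
#' Maps the per-segment direction sequence (flats removed, runs collapsed)
#' to a label: `monotone-up`, `monotone-down`, `peak` (up then down),
#' `V-shape` (down then up), `flat`, or `complex`.
#'
#' @param fit an accepted `trajectory_fit`.
#' @return character shape label.
#' @export
classify_shape <- function(fit) {
  ds_stopifnot(!isTRUE(fit$rejected), "classify_shape: rejected fit")
  d <- fit$directions[fit$directions != "flat"]
  d <- rle(d)$values
  if (length(d) == 0) return("flat")
  if (identical(d, "up")) return("monotone-up")
  if (identical(d, "down")) return("monotone-down")
  if (identical(d, c("up", "down"))) return("peak")
  if (identical(d, c("down", "up"))) return("V-shape")
  "complex"
}

#' Fit trajectories for many genes in one structure
#'
#' Builds one [time_series()] per gene from the samples of `structure`
#' (time = stage rank by default, or per-stage medians with
#' `per_stage_median = TRUE`) and fits each with [fit_segmented()].
#'
#' @param m an `expr_matrix` on the log scale.
#' @param meta a `sample_metadata`.
#' @param structure the structure whose samples are used.
#' @param genes optional gene ids to fit (default: all rows).
#' @param per_stage_median collapse replicate samples to per-stage medians.
#' @param ... passed to [fit_segmented()].
#' @return named list of `trajectory_fit`s.
#' @export
fit_trajectories <- function(m, meta, structure, genes = NULL,
                             per_stage_median = FALSE, ...) {
  stopifnot(inherits(m, "expr_matrix"))
  idx <- match(colnames(m$values), meta$sample_id)
  ds_stopifnot(!anyNA(idx), "fit_trajectories: samples missing from metadata")
  meta <- meta[idx, , drop = FALSE]
  cols <- which(meta$structure == structure)
  ds_stopifnot(length(cols) > 0, "fit_trajectories: no samples for structure ",
               structure)
  times <- as.integer(meta$stage[cols])
  genes <- genes %||% rownames(m$values)
  genes <- intersect(genes, rownames(m$values))
  fits <- lapply(genes, function(g) {
    v <- m$values[g, cols]
    if (per_stage_median) {
      med <- tapply(v, times, median)
      ts <- time_series(as.numeric(names(med)), as.numeric(med), gene = g,
                        structure = structure)
    } else {
      ts <- time_series(times, v, gene = g, structure = structure)
    }
    fit_segmented(ts, ...)
  })
  names(fits) <- genes
  fits
}

#' Tabulate trajectory fits
#'
#' @param fits list of `trajectory_fit`s.
#' @return data frame: gene, structure, k, breakpoints, slopes, adj_r2,
#'   shape, rejection_reason.
#' @export
trajectory_table <- function(fits) {
  if (inherits(fits, "trajectory_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    if (isTRUE(f$rejected)) {
      data.frame(gene = f$gene, structure = f$structure, k = NA_integer_,
                 breakpoints = "", slopes = "", adj_r2 = NA_real_,
                 shape = NA_character_, rejection_reason = f$reason,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = f$gene, structure = f$structure, k = f$k,
                 breakpoints = paste(f$breakpoints, collapse = ","),
                 slopes = paste(signif(f$slopes, 6), collapse = ","),
                 adj_r2 = f$adj_r2, shape = f$shape,
                 rejection_reason = NA_character_, stringsAsFactors = FALSE)
    }
  }))
}
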