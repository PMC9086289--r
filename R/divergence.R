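# Transcriptomic divergence: PCA over a gene subset, JackStraw component
# significance, per-stage pairwise Euclidean distances between structures,
# Wilcoxon rank-sum tests with Bonferroni correction, and the per-structure
# "divergent" call (adjusted p < alpha against *every* other structure).

#' Principal component analysis of samples over genes
#'
#' Samples are observations, genes are variables. Genes are centered; unit
#' variance scaling is off by default (distances live on the log-expression
#' scale). Component signs are canonicalized so the largest-magnitude
#' loading of each component is positive.
#'
#' @param m an `expr_matrix` on the log scale with >= 2 samples.
#' @param scale. scale genes to unit variance before rotation.
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `loadings` (genes x components), `variance_fraction`, `center`.
#' @export
run_pca <- function(m, scale. = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  ds_stopifnot(m$scale == "log2", "run_pca: expected a log-scale matrix")
  x <- t(m$values)
  ds_stopifnot(nrow(x) >= 2, "run_pca: need >= 2 samples")
  ds_stopifnot(ncol(x) >= 1, "run_pca: need >= 1 gene")
  if (scale.) {
    keep <- apply(x, 2, sd) > 0
    x <- x[, keep, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = scale.)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    l <- pc$rotation[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
                 center = pc$center, scaled = scale.),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  vf <- round(100 * x$variance_fraction[seq_len(min(5, length(x$variance_fraction)))], 1)
  cat(sprintf("<pca_result> %d samples x %d components; var%%: %s ...\n",
              nrow(x$scores), ncol(x$scores), paste(vf, collapse = ", ")))
  invisible(x)
}

#' JackStraw significance of principal components
#'
#' Repeatedly permutes a random fraction of gene rows across samples,
#' recomputes the PCA, and collects squared loadings of the permuted genes
#' as the null association score. Per-gene empirical p-values against this
#' null are then tested per component for enrichment of small values below
#' `gene_cutoff` with a one-sided exact binomial test against the uniform
#' expectation.
#'
#' @param m an `expr_matrix` on the log scale.
#' @param n_perm number of permutation rounds (>= 10).
#' @param fraction fraction of genes permuted per round.
#' @param seed integer seed; results are reproducible from it.
#' @param n_components components to assess (default: all from the PCA).
#' @param gene_cutoff gene-level p cutoff used by the component-level
#'   enrichment test.
#' @return list of class `jackstraw_result`: `component_p`, `gene_p`
#'   (genes x components), `n_perm`, `fraction`, `seed`.
#' @export
jackstraw <- function(m, n_perm = 100, fraction = 0.1, seed = 1,
                      n_components = NULL, gene_cutoff = 0.05) {
  stopifnot(inherits(m, "expr_matrix"))
  ds_stopifnot(n_perm >= 10, "jackstraw: n_perm must be >= 10")
  g <- nrow(m$values)
  n_sel <- max(1L, round(fraction * g))
  ds_stopifnot(n_sel >= 1, "jackstraw: fraction too small for gene count")
  pca <- run_pca(m)
  k <- min(n_components %||% ncol(pca$loadings), ncol(pca$loadings))
  obs <- pca$loadings[, seq_len(k), drop = FALSE]^2
  set.seed(seed)
  null <- matrix(NA_real_, nrow = n_perm * n_sel, ncol = k)
  row <- 0L
  for (b in seq_len(n_perm)) {
    sel <- sample.int(g, n_sel)
    perm <- m$values
    for (i in sel) perm[i, ] <- perm[i, sample.int(ncol(perm))]
    pp <- prcomp(t(perm), center = TRUE, scale. = FALSE)
    null[row + seq_len(n_sel), ] <- pp$rotation[sel, seq_len(k), drop = FALSE]^2
    row <- row + n_sel
  }
  gene_p <- matrix(NA_real_, nrow = g, ncol = k,
                   dimnames = list(rownames(m$values), colnames(obs)))
  for (j in seq_len(k)) {
    nj <- null[, j]
    # empirical p of each observed squared loading against the pooled null
    gene_p[, j] <- (1 + vapply(obs[, j], function(o) sum(nj >= o),
                               numeric(1))) / (1 + length(nj))
  }
  component_p <- vapply(seq_len(k), function(j) {
    x <- sum(gene_p[, j] <= gene_cutoff)
    binom.test(x, g, p = gene_cutoff, alternative = "greater")$p.value
  }, numeric(1))
  names(component_p) <- colnames(obs)
  structure(list(component_p = component_p, gene_p = gene_p,
                 n_perm = n_perm, fraction = fraction, seed = seed),
            class = "jackstraw_result")
}

#' Select significant principal components
#'
#' Components with JackStraw p below `alpha`. Two overrides, both logged:
#' when fewer than `fallback_k` components pass, the first `fallback_k`
#' are returned instead; and for small gene subsets (fewer than
#' `small_subset` genes) the permutation null is too coarse to trust at
#' all, so the first `fallback_k` components are used regardless —
#' mirroring the handling of a 12-gene subset whose second component
#' misses significance by construction (with so few genes, squared
#' loadings of permuted genes are not smaller than those of real ones).
#'
#' @param pca a `pca_result`.
#' @param js a `jackstraw_result` for the same matrix.
#' @param alpha component-level significance threshold.
#' @param fallback_k minimum number of components to return.
#' @param small_subset gene-count threshold under which the JackStraw
#'   call is overridden entirely.
#' @return integer vector of component indices.
#' @export
select_components <- function(pca, js, alpha = 0.05, fallback_k = 2,
                              small_subset = 30) {
  n_genes <- nrow(js$gene_p)
  if (!is.null(n_genes) && n_genes < small_subset) {
    k <- min(fallback_k, ncol(pca$scores))
    ds_log("select_components",
           sprintf("subset of %d genes below the JackStraw reliability floor (%d); using first %d components",
                   n_genes, small_subset, k))
    return(seq_len(k))
  }
  sig <- which(js$component_p < alpha)
  if (length(sig) < fallback_k) {
    k <- min(fallback_k, ncol(pca$scores))
    ds_log("select_components",
           sprintf("only %d/%d components significant at %g; falling back to first %d",
                   length(sig), length(js$component_p), alpha, k))
    return(seq_len(k))
  }
  sig
}

#' Pairwise Euclidean distances between structures within each stage
#'
#' Within each developmental stage, the Euclidean distance in the selected
#' principal-component subspace between every pair of samples belonging to
#' different structures. Each distance is attributed to both endpoint
#' structures. Stages with fewer than two structures are skipped with a log
#' line.
#'
#' @param pca a `pca_result`.
#' @param comps integer component indices (e.g. from [select_components()]).
#' @param meta a `sample_metadata` covering the score rows.
#' @return data frame of class `distance_table`: `stage`, `sample_a`,
#'   `sample_b`, `structure_a`, `structure_b`, `distance`.
#' @export
pairwise_stage_distances <- function(pca, comps, meta) {
  sc <- pca$scores[, comps, drop = FALSE]
  idx <- match(rownames(sc), meta$sample_id)
  ds_stopifnot(!anyNA(idx), "pairwise_stage_distances: samples missing from metadata")
  meta <- meta[idx, , drop = FALSE]
  out <- list()
  for (sg in levels(meta$stage)) {
    rows <- which(as.character(meta$stage) == sg)
    if (length(rows) == 0) next
    if (length(unique(meta$structure[rows])) < 2) {
      ds_log("distances", sprintf("stage %s skipped: < 2 structures", sg))
      next
    }
    sub <- sc[rows, , drop = FALSE]
    st <- meta$structure[rows]
    ids <- meta$sample_id[rows]
    dm <- as.matrix(dist(sub))
    pr <- which(upper.tri(dm), arr.ind = TRUE)
    keep <- st[pr[, 1]] != st[pr[, 2]]
    pr <- pr[keep, , drop = FALSE]
    if (nrow(pr) == 0) next
    out[[length(out) + 1]] <- data.frame(
      stage = sg, sample_a = ids[pr[, 1]], sample_b = ids[pr[, 2]],
      structure_a = st[pr[, 1]], structure_b = st[pr[, 2]],
      distance = dm[pr], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(stage = character(), sample_a = character(),
               sample_b = character(), structure_a = character(),
               structure_b = character(), distance = numeric(),
               stringsAsFactors = FALSE)
  structure(res, class = c("distance_table", "data.frame"))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks for ties. Exact p by full enumeration of group assignments when
#' `choose(n, nx)` is small enough; exact via the tie-free rank-sum
#' distribution when there are no ties and both groups are at most
#' `exact_max`; otherwise the normal approximation with tie correction and
#' continuity correction. All values tied across both groups returns p = 1
#' by convention.
#'
#' @param x,y numeric vectors.
#' @param exact_max exact-path group-size bound.
#' @param enum_cap largest number of assignments enumerated exhaustively.
#' @return list with `statistic` (rank sum of `x`), `p`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 25, enum_cap = 100000) {
  nx <- length(x)
  ny <- length(y)
  ds_stopifnot(nx >= 1 && ny >= 1, "wilcoxon_rank_sum: empty group")
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1) {
    return(list(statistic = sum(rank(all_v)[seq_len(nx)]), p = 1,
                method = "degenerate"))
  }
  r <- rank(all_v)
  w <- sum(r[seq_len(nx)])
  n <- nx + ny
  has_ties <- anyDuplicated(all_v) > 0
  if (choose(n, nx) <= enum_cap) {
    idx <- combn(n, nx)
    ws <- colSums(matrix(r[idx], nrow = nx))
    mu <- nx * (n + 1) / 2
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-12)
    return(list(statistic = w, p = p, method = "exact_enumeration"))
  }
  if (!has_ties && nx <= exact_max && ny <= exact_max) {
    u <- w - nx * (nx + 1) / 2
    mu_u <- nx * ny / 2
    if (u > mu_u) {
      p <- 2 * (1 - pwilcox(u - 1, nx, ny))
    } else if (u < mu_u) {
      p <- 2 * pwilcox(u, nx, ny)
    } else {
      p <- 1
    }
    return(list(statistic = w, p = min(1, p), method = "exact_distribution"))
  }
  # normal approximation, tie-corrected variance, continuity correction
  mu <- nx * (n + 1) / 2
  ties <- table(all_v)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  list(statistic = w, p = min(1, 2 * (1 - pnorm(z))), method = "normal")
}

#' Divergence test: which structures stand apart at each stage
#'
#' Per stage, for every pair of structures (a, b), a two-sided Wilcoxon
#' rank-sum test compares the distance distribution attributed to a with
#' that attributed to b, Bonferroni-corrected over all pairs within the
#' stage (or across all stages with `family = "global"`). A structure is
#' flagged divergent at a stage iff *all* its pairwise adjusted p-values
#' are below `alpha`. The per-structure mean adjusted p (the line-plot
#' statistic) is also emitted.
#'
#' @param d a `distance_table` from [pairwise_stage_distances()].
#' @param alpha significance threshold for the divergent call.
#' @param family Bonferroni family: pairs within one stage (default) or all
#'   pairs across stages.
#' @return list of class `divergence_result`: `pairwise` (stage,
#'   structure_a, structure_b, n_a, n_b, statistic, raw_p, adj_p) and
#'   `structures` (stage, structure, mean_adj_p, divergent).
#' @export
divergence_test <- function(d, alpha = 0.01, family = c("stage", "global")) {
  family <- match.arg(family)
  pw <- list()
  for (sg in unique(d$stage)) {
    ds <- d[d$stage == sg, , drop = FALSE]
    sts <- sort(unique(c(ds$structure_a, ds$structure_b)))
    if (length(sts) < 2) next
    attributed <- lapply(sts, function(s) {
      ds$distance[ds$structure_a == s | ds$structure_b == s]
    })
    names(attributed) <- sts
    pairs <- combn(sts, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]
      b <- pairs[2, j]
      xa <- attributed[[a]]
      xb <- attributed[[b]]
      ds_stopifnot(length(xa) >= 2 && length(xb) >= 2,
                   "divergence_test: structure with < 2 attributed distances at stage ", sg)
      wt <- wilcoxon_rank_sum(xa, xb)
      pw[[length(pw) + 1]] <- data.frame(
        stage = sg, structure_a = a, structure_b = b,
        n_a = length(xa), n_b = length(xb),
        statistic = wt$statistic, raw_p = wt$p, adj_p = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  pw <- if (length(pw)) do.call(rbind, pw) else
    data.frame(stage = character(), structure_a = character(),
               structure_b = character(), n_a = integer(), n_b = integer(),
               statistic = numeric(), raw_p = numeric(), adj_p = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(pw)) {
    if (family == "global") {
      pw$adj_p <- bonferroni(pw$raw_p, nrow(pw))
    } else {
      for (sg in unique(pw$stage)) {
        i <- pw$stage == sg
        pw$adj_p[i] <- bonferroni(pw$raw_p[i], sum(i))
      }
    }
  }
  st_rows <- list()
  for (sg in unique(pw$stage)) {
    sub <- pw[pw$stage == sg, , drop = FALSE]
    for (s in sort(unique(c(sub$structure_a, sub$structure_b)))) {
      ps <- sub$adj_p[sub$structure_a == s | sub$structure_b == s]
      st_rows[[length(st_rows) + 1]] <- data.frame(
        stage = sg, structure = s, mean_adj_p = mean(ps),
        divergent = all(ps < alpha), stringsAsFactors = FALSE)
    }
  }
  structures <- if (length(st_rows)) do.call(rbind, st_rows) else
    data.frame(stage = character(), structure = character(),
               mean_adj_p = numeric(), divergent = logical(),
               stringsAsFactors = FALSE)
  structure(list(pairwise = pw, structures = structures, alpha = alpha,
                 family = family), class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  n_div <- sum(x$structures$divergent)
  cat(sprintf("<divergence_result> %d pairwise tests, %d stage(s); %d divergent (structure, stage) cell(s) at alpha = %g\n",
              nrow(x$pairwise), length(unique(x$pairwise$stage)), n_div,
              x$alpha))
  if (n_div) {
    d <- x$structures[x$structures$divergent, c("stage", "structure",
                                                "mean_adj_p")]
    print.data.frame(d, row.names = FALSE)
  }
  invisible(x)
}

#' End-to-end divergence analysis for one gene subset
#'
#' Convenience wrapper: PCA, JackStraw, component selection, per-stage
#' pairwise distances, divergence test.
#'
#' @param m an `expr_matrix` on the log scale (already subset to the genes
#'   of interest).
#' @param meta a `sample_metadata`.
#' @param alpha divergence threshold (default 0.01).
#' @param alpha_pcs JackStraw component threshold (default 0.05).
#' @param n_perm JackStraw permutations.
#' @param fallback_k minimum components kept for small subsets.
#' @param seed RNG seed for the JackStraw permutations.
#' @return a `divergence_result` with extra elements `pca`, `jackstraw`,
#'   `components`, `distances`.
#' @export
run_divergence <- function(m, meta, alpha = 0.01, alpha_pcs = 0.05,
                           n_perm = 100, fallback_k = 2, seed = 1) {
  pca <- run_pca(m)
  js <- jackstraw(m, n_perm = n_perm, seed = seed)
  comps <- select_components(pca, js, alpha = alpha_pcs,
                             fallback_k = fallback_k)
  d <- pairwise_stage_distances(pca, comps, meta)
  res <- divergence_test(d, alpha = alpha)
  res$pca <- pca
  res$jackstraw <- js
  res$components <- comps
  res$distances <- d
  res
}
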