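# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own code paths: brute-force loops, closed forms, base-R models.

options(desertscope.quiet = TRUE)

# --- tiny annotation / regions ------------------------------------------------

toy_annotation <- function() {
  annotation(gene_id = c("g1", "g2", "g3"),
             chrom = "chr1",
             start = c(0, 20, 28), end = c(10, 30, 60),
             biotype = c("protein_coding", "protein_coding", "lincRNA"))
}

write_bed <- function(df, path = tempfile(fileext = ".bed")) {
  writeLines(apply(df, 1, paste, collapse = "\t"), path)
  path
}

# --- brute-force interval oracles --------------------------------------------

# per-base membership oracle for intersection over small coordinates
oracle_intersect_bases <- function(a, b, max_base = 200) {
  bases <- list()
  for (ch in unique(c(a$chrom, b$chrom))) {
    in_a <- in_b <- rep(FALSE, max_base)
    for (i in seq_len(nrow(a))) {
      if (a$chrom[i] == ch) in_a[seq(a$start[i] + 1, a$end[i])] <- TRUE
    }
    for (i in seq_len(nrow(b))) {
      if (b$chrom[i] == ch) in_b[seq(b$start[i] + 1, b$end[i])] <- TRUE
    }
    bases[[ch]] <- which(in_a & in_b) - 1 # back to 0-based base indices
  }
  bases
}

region_set_bases <- function(rs, max_base = 200) {
  bases <- list()
  for (ch in unique(rs$chrom)) {
    v <- rep(FALSE, max_base)
    for (i in seq_len(nrow(rs))) {
      if (rs$chrom[i] == ch && rs$end[i] > rs$start[i]) {
        v[seq(rs$start[i] + 1, rs$end[i])] <- TRUE
      }
    }
    bases[[ch]] <- which(v) - 1
  }
  bases
}

# independent constraint checker for the matched sampler
oracle_check_replicate <- function(rep_rs, template, excluded, ann, cfg) {
  ok_len <- all(abs((rep_rs$end - rep_rs$start) -
                      (template$end - template$start)) <=
                  cfg$length_tolerance + 0.5)
  no_excl <- TRUE
  for (i in seq_len(nrow(rep_rs))) {
    for (j in seq_len(nrow(excluded))) {
      if (rep_rs$chrom[i] == excluded$chrom[j] &&
          rep_rs$start[i] < excluded$end[j] &&
          rep_rs$end[i] > excluded$start[j]) no_excl <- FALSE
    }
  }
  no_self <- TRUE
  if (nrow(rep_rs) > 1) {
    for (i in seq_len(nrow(rep_rs) - 1)) {
      for (j in (i + 1):nrow(rep_rs)) {
        if (rep_rs$chrom[i] == rep_rs$chrom[j] &&
            rep_rs$start[i] < rep_rs$end[j] &&
            rep_rs$end[i] > rep_rs$start[j]) no_self <- FALSE
      }
    }
  }
  genes <- ann
  if (!is.null(cfg$biotype)) genes <- genes[genes$biotype %in% cfg$biotype, ]
  n_genes <- 0L
  for (i in seq_len(nrow(rep_rs))) {
    n_genes <- n_genes + sum(genes$chrom == rep_rs$chrom[i] &
                               genes$start >= rep_rs$start[i] &
                               genes$end <= rep_rs$end[i])
  }
  ok_genes <- n_genes >= cfg$min_total_genes
  c(length = ok_len, exclusion = no_excl, no_self_overlap = no_self,
    gene_floor = ok_genes)
}

# --- statistical oracles ------------------------------------------------------

# exhaustive rank-permutation two-sided p for the rank-sum statistic
oracle_wilcoxon_exact <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)])
  mu <- length(x) * (n + 1) / 2
  sets <- combn(n, length(x))
  count <- 0L
  for (j in seq_len(ncol(sets))) {
    if (abs(sum(r[sets[, j]]) - mu) >= abs(w_obs - mu) - 1e-12) {
      count <- count + 1L
    }
  }
  count / ncol(sets)
}

# hand-computed Kruskal-Wallis H with tie correction
oracle_kruskal_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  h <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    h <- h + sum(idx) * (mean(r[idx]) - (n + 1) / 2)^2
  }
  h <- 12 / (n * (n + 1)) * h
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# textbook Grubbs statistic and one-sided p
oracle_grubbs <- function(x, side = "max") {
  n <- length(x)
  g <- if (side == "max") (max(x) - mean(x)) / sd(x) else
    (mean(x) - min(x)) / sd(x)
  tt <- sqrt(n * (n - 2) * g^2 / ((n - 1)^2 - n * g^2))
  list(g = g, p = min(1, n * stats::pt(tt, n - 2, lower.tail = FALSE)))
}

# --- expression fixture -------------------------------------------------------

small_log_matrix <- function(seed = 1, genes = 20, structures = c("CBC", "NCX", "STR"),
                             samples_per_cell = 3, shift = NULL) {
  set.seed(seed)
  stages <- stage_windows()$stage
  meta <- expand.grid(rep = seq_len(samples_per_cell), stage = stages,
                      structure = structures, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_%s_%d", meta$structure, meta$stage, meta$rep)
  vals <- matrix(rnorm(genes * nrow(meta), 5, 0.5), nrow = genes,
                 dimnames = list(sprintf("g%02d", seq_len(genes)),
                                 meta$sample_id))
  if (!is.null(shift)) {
    cols <- meta$structure == shift$structure &
      meta$stage %in% shift$stages
    vals[, cols] <- vals[, cols] + shift$delta
  }
  list(matrix = expression_matrix(vals, "log2"),
       meta = sample_metadata(meta$sample_id, meta$structure, meta$stage))
}
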