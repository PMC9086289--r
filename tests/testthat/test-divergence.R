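test_that("run_pca centers genes, canonicalizes signs, conserves distances", {
  fx <- small_log_matrix(seed = 1, genes = 15)
  pca <- run_pca(fx$matrix)
  expect_true(all(abs(colMeans(pca$scores)) < 1e-10))
  vf <- pca$variance_fraction
  expect_true(all(vf >= 0) && !is.unsorted(rev(vf)) && sum(vf) <= 1 + 1e-12)
  # canonical sign: largest-magnitude loading positive
  for (k in seq_len(ncol(pca$loadings))) {
    l <- pca$loadings[, k]
    expect_gte(l[which.max(abs(l))], 0)
  }
  # Parseval: distances over all components equal centered-gene-space distances
  centered <- t(scale(t(fx$matrix$values), center = TRUE, scale = FALSE))
  d_gene <- as.matrix(dist(t(centered)))
  d_pc <- as.matrix(dist(pca$scores))
  expect_lt(max(abs(d_gene - d_pc)), 1e-9)

  # two identical samples land on identical scores
  vals <- matrix(rnorm(20), 10,
                 dimnames = list(paste0("g", 1:10), c("s1", "s2")))
  vals[, 2] <- vals[, 1]
  vals <- cbind(vals, s3 = rnorm(10))
  twin <- run_pca(expression_matrix(vals, "log2"))
  expect_equal(twin$scores["s1", ], twin$scores["s2", ], tolerance = 1e-10)

  expect_error(run_pca(expression_matrix(matrix(1, 2, 1,
    dimnames = list(c("a", "b"), "s")), "log2")), ">= 2 samples")
})

test_that("jackstraw flags a planted factor, is seeded, rejects tiny n_perm", {
  set.seed(11)
  n <- 40
  g <- 80
  vals <- matrix(rnorm(g * n), g, dimnames = list(sprintf("g%02d", 1:g),
                                                  sprintf("s%02d", 1:n)))
  factor_samples <- 1:20
  vals[1:40, factor_samples] <- vals[1:40, factor_samples] + 2
  m <- expression_matrix(vals, "log2")
  js <- jackstraw(m, n_perm = 50, seed = 4, n_components = 5)
  expect_lt(js$component_p[1], 0.05)
  expect_true(all(js$component_p >= 0 & js$component_p <= 1))
  js2 <- jackstraw(m, n_perm = 50, seed = 4, n_components = 5)
  expect_identical(js$component_p, js2$component_p)

  expect_error(jackstraw(m, n_perm = 5), "n_perm")
})

test_that("select_components honours significance, fallback and the small-subset floor", {
  fx <- small_log_matrix(seed = 2, genes = 40)
  pca <- run_pca(fx$matrix)
  fake_js <- function(p) {
    structure(list(component_p = p,
                   gene_p = matrix(0.5, 40, length(p)),
                   n_perm = 50, fraction = 0.1, seed = 1),
              class = "jackstraw_result")
  }
  expect_equal(select_components(pca, fake_js(c(0.001, 0.02, 0.03))), 1:3)
  expect_equal(select_components(pca, fake_js(c(0.5, 0.9, 0.7))), 1:2)
  expect_equal(select_components(pca, fake_js(c(0.001, 0.5, 0.01))), c(1L, 3L))
  # 12-gene subset: JackStraw override, first two components regardless
  small <- structure(list(component_p = c(0.001, 0.5, 0.01),
                          gene_p = matrix(0.5, 12, 3)),
                     class = "jackstraw_result")
  expect_equal(select_components(pca, small), 1:2)
})

test_that("pairwise_stage_distances matches a brute-force double loop", {
  # 3-4-5 triangle
  vals <- matrix(c(0, 0, 3, 4, 1, 1), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("a1", "b1", "c1")))
  pca <- list(scores = t(vals))
  meta <- sample_metadata(c("a1", "b1", "c1"), c("A", "B", "C"),
                          rep("Fetal1", 3))
  d <- pairwise_stage_distances(pca, 1:2, meta)
  ab <- d$distance[(d$structure_a == "A" & d$structure_b == "B") |
                     (d$structure_a == "B" & d$structure_b == "A")]
  expect_equal(ab, 5)
  expect_equal(nrow(d), 3) # each unordered pair once

  fx <- small_log_matrix(seed = 6, genes = 10)
  pca <- run_pca(fx$matrix)
  comps <- 1:3
  d <- pairwise_stage_distances(pca, comps, fx$meta)
  # brute force re-computation
  sc <- pca$scores[, comps]
  meta <- fx$meta
  n_pairs <- 0
  for (i in seq_len(nrow(sc) - 1)) {
    for (j in (i + 1):nrow(sc)) {
      si <- meta[meta$sample_id == rownames(sc)[i], ]
      sj <- meta[meta$sample_id == rownames(sc)[j], ]
      if (as.character(si$stage) != as.character(sj$stage)) next
      if (si$structure == sj$structure) next
      n_pairs <- n_pairs + 1
      dd <- sqrt(sum((sc[i, ] - sc[j, ])^2))
      row <- d[(d$sample_a == rownames(sc)[i] & d$sample_b == rownames(sc)[j]) |
                 (d$sample_a == rownames(sc)[j] & d$sample_b == rownames(sc)[i]), ]
      expect_equal(nrow(row), 1)
      expect_equal(row$distance, dd, tolerance = 1e-12)
    }
  }
  expect_equal(nrow(d), n_pairs)
})

test_that("wilcoxon_rank_sum agrees with enumeration, handles ties and degenerate input", {
  set.seed(21)
  for (i in 1:8) {
    x <- round(rnorm(4, 5, 2), 1)
    y <- round(rnorm(4, 6, 2), 1)
    got <- wilcoxon_rank_sum(x, y)
    expect_equal(got$p, oracle_wilcoxon_exact(x, y), info = sprintf("case %d", i))
  }
  # forced ties
  x <- c(1, 2, 2, 3)
  y <- c(2, 3, 3, 4)
  expect_equal(wilcoxon_rank_sum(x, y)$p, oracle_wilcoxon_exact(x, y))
  # degenerate: everything tied
  expect_equal(wilcoxon_rank_sum(rep(1, 5), rep(1, 6))$p, 1)
  # large tie-free groups agree with stats::wilcox.test exact path
  set.seed(3)
  x <- rnorm(20)
  y <- rnorm(18, 0.5)
  ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
  expect_equal(wilcoxon_rank_sum(x, y)$p, ref$p.value, tolerance = 1e-12)
})

test_that("divergence_test flags only a planted outlier structure", {
  set.seed(31)
  mk_d <- function(shift_structure = NULL) {
    sts <- c("A", "B", "C", "D")
    rows <- list()
    for (a in 1:3) for (b in (a + 1):4) {
      n <- 8
      d <- abs(rnorm(n, 2, 0.3))
      if (!is.null(shift_structure) &&
          (sts[a] == shift_structure || sts[b] == shift_structure)) {
        d <- d + 10
      }
      rows[[length(rows) + 1]] <- data.frame(
        stage = "Adulthood", sample_a = paste0(sts[a], seq_len(n)),
        sample_b = paste0(sts[b], seq_len(n)),
        structure_a = sts[a], structure_b = sts[b], distance = d,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  null_res <- divergence_test(mk_d(), alpha = 0.01)
  expect_false(any(null_res$structures$divergent))

  hit <- divergence_test(mk_d("C"), alpha = 0.01)
  flagged <- hit$structures[hit$structures$divergent, ]
  expect_equal(flagged$structure, "C")

  # Bonferroni properties
  expect_true(all(hit$pairwise$adj_p >= hit$pairwise$raw_p - 1e-15))
  expect_true(all(hit$pairwise$adj_p <=
                    pmin(1, hit$pairwise$raw_p * nrow(hit$pairwise)) + 1e-15))
  # flags monotone in alpha
  looser <- divergence_test(mk_d("C"), alpha = 0.2)
  expect_true(all(hit$structures$divergent <= looser$structures$divergent))
})

test_that("divergence is invariant to adding a constant to every value", {
  fx <- small_log_matrix(seed = 9, genes = 14,
                         shift = list(structure = "CBC",
                                      stages = "Adulthood", delta = 2))
  r1 <- run_divergence(fx$matrix, fx$meta, n_perm = 20, seed = 2)
  shifted <- fx$matrix
  shifted$values <- shifted$values + 7
  r2 <- run_divergence(shifted, fx$meta, n_perm = 20, seed = 2)
  expect_equal(r1$pairwise$raw_p, r2$pairwise$raw_p, tolerance = 1e-9)
  expect_equal(r1$structures$divergent, r2$structures$divergent)
  expect_equal(r1$distances$distance, r2$distances$distance, tolerance = 1e-9)
})
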