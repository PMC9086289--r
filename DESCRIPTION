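Package: desertscope
Title: Brain-Region Expression Trajectories for Genes in Introgression
    Deserts and Selective Sweeps
Version: 0.1.0
Authors@R:
    person("desertscope", "maintainers", email = "maintainers@desertscope.dev",
           role = c("aut", "cre"))
Description: A tested pipeline for characterising developmental expression
    trajectories of gene sets defined by genomic intervals, built around the
    analysis of archaic-introgression deserts and positively-selected regions
    in the human brain transcriptome. Provides matched random-region sampling
    with permutation nulls, PCA-based transcriptomic divergence testing
    (JackStraw component selection, per-stage pairwise Euclidean distances,
    Wilcoxon rank-sum tests with Bonferroni correction), a cohort statistics
    battery (repeated-measures ANOVA, Grubbs, Kruskal-Wallis, nested model
    comparison, Tukey post-hocs), segmented-regression trajectory fitting,
    and a fully deterministic synthetic-data generator with a truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
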