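# Deterministic synthetic-data generator: toy genome + annotation with a
# gene-density gradient, desert/sweep region fixtures with known gene
# membership, and structure x stage RPKM matrices with planted effects.
# Every output is a pure function of the config; a truth manifest records
# everything needed to score downstream modules.

#' Synthetic-data configuration
#'
#' The default world is deliberately tiny (300 genes, 6 structures, 8
#' stages, 3 samples per cell) so the whole test suite runs in minutes.
#' There is no generic structure effect by default: with no planted
#' effects the generator is a true null for the divergence test. Noise is
#' additive Gaussian on the log2 scale (lognormal RPKM).
#'
#' @param seed integer master seed.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param n_genes total genes placed (without overlap).
#' @param prop_coding fraction of genes with biotype `protein_coding`.
#' @param density_gradient ratio of gene density at the left end of each
#'   chromosome to the right end (> 1 makes density matching non-trivial).
#' @param structures structure labels.
#' @param stages stage labels (default: the 8 canonical windows).
#' @param samples_per_cell samples per (structure, stage).
#' @param baseline_mean,baseline_sd per-gene baseline log2 expression.
#' @param stage_slope_sd SD of the per-gene linear stage drift (log2 per
#'   stage step).
#' @param structure_effect_sd SD of generic per-(gene, structure) offsets;
#'   0 keeps the null world null.
#' @param noise_sd within-cell (gene, sample) noise SD on the log2 scale;
#'   planted shifts are expressed in units of this SD.
#' @param n_deserts desert regions in the region fixture.
#' @param desert_length desert length in bp.
#' @param n_sweep_in,n_sweep_out sweep regions inside / outside deserts.
#' @param genes_per_sweep coding genes wrapped by each in-desert sweep
#'   (defaults give a 12-gene desert-and-sweep intersection).
#' @param planted_effects list of effects, each a list with `genes`
#'   (character vector, or `"desert_sweep"` / `"desert"` resolved against
#'   the region manifest), `structure`, `stages`, `shift` (in noise-SD
#'   units). `"default"` plants the study-like pattern: a cerebellum-like
#'   +2 SD shift on the desert-and-sweep genes at four postnatal stages
#'   and a thalamus-like +2 SD shift at the first fetal stage.
#' @param planted_trajectories list of lists with `gene`, `structure`,
#'   `start` (log2 level at the first stage), `breaks` (stage indices),
#'   `slopes` (log2 per stage step, one per segment).
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         chrom_lengths = c(chr1 = 60e6, chr2 = 60e6,
                                           chr3 = 60e6, chr4 = 60e6),
                         n_genes = 300, prop_coding = 0.8,
                         density_gradient = 3,
                         structures = structure_labels(),
                         stages = stage_levels(),
                         samples_per_cell = 3,
                         baseline_mean = 3, baseline_sd = 1.5,
                         stage_slope_sd = 0.25,
                         structure_effect_sd = 0,
                         noise_sd = 0.5,
                         n_deserts = 4, desert_length = 15e6,
                         n_sweep_in = 4, n_sweep_out = 4,
                         genes_per_sweep = 3,
                         planted_effects = "default",
                         planted_trajectories = list()) {
  ds_stopifnot(n_genes > 0 && samples_per_cell > 0 && length(structures) > 0,
               "synth_config: counts must be positive")
  ds_stopifnot(noise_sd >= 0 && baseline_sd >= 0,
               "synth_config: SDs must be non-negative")
  structure(as.list(environment()), class = "synth_config")
}

# deterministic sub-seeds so each generator stage is independently stable
sub_seed <- function(cfg, stage) {
  (cfg$seed * 1000 + stage) %% .Machine$integer.max
}

#' Generate a toy genome and gene annotation
#'
#' Genes are placed without overlap; placement density decreases linearly
#' along each chromosome by `density_gradient`, so gene-density matching
#' in the region sampler is non-trivial. Biotypes mix `protein_coding`
#' and `lincRNA`.
#'
#' @param cfg a [synth_config()].
#' @return list with `genome` (chrom/length data frame) and `annotation`.
#' @export
make_genome_and_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(sub_seed(cfg, 1))
  total <- sum(cfg$chrom_lengths)
  per_chrom <- round(cfg$n_genes * cfg$chrom_lengths / total)
  per_chrom[length(per_chrom)] <- cfg$n_genes - sum(per_chrom[-length(per_chrom)])
  rows <- list()
  gid <- 0L
  for (ci in seq_along(cfg$chrom_lengths)) {
    L <- cfg$chrom_lengths[ci]
    n <- per_chrom[ci]
    if (n == 0) next
    # gene bodies shrink on dense chromosomes so placement stays feasible
    gene_len <- min(20000, floor(L / (4 * n)))
    ds_stopifnot(gene_len >= 100,
                 "make_genome_and_annotation: density request infeasible on ",
                 names(cfg$chrom_lengths)[ci])
    # left-heavy density: inverse-CDF of a linearly decreasing density
    g <- cfg$density_gradient
    u <- sort(runif(n))
    pos <- if (g == 1) u else (g - sqrt(g^2 - u * (g^2 - 1))) / (g - 1)
    starts <- floor(pos * (L - gene_len))
    # enforce non-overlap by pushing genes right where needed
    for (i in seq_len(n)) {
      if (i > 1 && starts[i] < starts[i - 1] + gene_len) {
        starts[i] <- starts[i - 1] + gene_len
      }
    }
    ds_stopifnot(starts[n] + gene_len <= L,
                 "make_genome_and_annotation: density request infeasible on ",
                 names(cfg$chrom_lengths)[ci])
    ids <- sprintf("G%05d", gid + seq_len(n))
    gid <- gid + n
    rows[[ci]] <- data.frame(gene_id = ids, chrom = names(cfg$chrom_lengths)[ci],
                             start = starts, end = starts + gene_len,
                             stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  biotype <- rep("lincRNA", nrow(df))
  coding <- sample.int(nrow(df), round(cfg$prop_coding * nrow(df)))
  biotype[coding] <- "protein_coding"
  ann <- annotation(gene_id = df$gene_id, symbol = paste0("SYM_", df$gene_id),
                    chrom = df$chrom, start = df$start, end = df$end,
                    biotype = biotype)
  list(genome = data.frame(chrom = names(cfg$chrom_lengths),
                           length = as.numeric(cfg$chrom_lengths),
                           stringsAsFactors = FALSE),
       annotation = ann)
}

#' Generate desert and sweep region fixtures with known gene membership
#'
#' Places `n_deserts` desert regions (one per chromosome, recycled),
#' `n_sweep_in` sweep regions wrapped around known coding genes inside
#' deserts (so the desert-and-sweep intersection has a planted, recorded
#' gene membership) and `n_sweep_out` sweeps outside deserts.
#'
#' @param cfg a [synth_config()].
#' @param ann the annotation from [make_genome_and_annotation()].
#' @return list with `deserts`, `sweeps` (region sets) and `manifest`
#'   (desert gene ids, desert-and-sweep gene ids, counts).
#' @export
make_region_fixture <- function(cfg, ann) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(sub_seed(cfg, 2))
  chroms <- names(cfg$chrom_lengths)
  d_rows <- list()
  for (i in seq_len(cfg$n_deserts)) {
    ch <- chroms[(i - 1) %% length(chroms) + 1]
    L <- cfg$chrom_lengths[ch]
    len <- min(cfg$desert_length, L * 0.4)
    # deserts sit in the left (gene-dense) half so they hold many genes
    s <- floor(runif(1, 0, L * 0.5 - len))
    d_rows[[i]] <- data.frame(chrom = ch, start = s, end = s + len,
                              label = sprintf("desert_%d", i),
                              stringsAsFactors = FALSE)
  }
  deserts <- validate_region_set(new_region_set(do.call(rbind, d_rows),
                                                "deserts"))
  desert_genes <- genes_in_regions(ann, deserts, biotype = "protein_coding")
  s_rows <- list()
  sweep_genes <- character()
  if (cfg$n_sweep_in > 0) {
    ds_stopifnot(nrow(desert_genes) >= cfg$n_sweep_in * cfg$genes_per_sweep,
                 "make_region_fixture: not enough desert genes for sweeps")
    pool <- desert_genes
    for (i in seq_len(cfg$n_sweep_in)) {
      di <- (i - 1) %% nrow(deserts) + 1
      cand <- pool[pool$chrom == deserts$chrom[di] &
                     pool$start >= deserts$start[di] &
                     pool$end <= deserts$end[di], , drop = FALSE]
      if (nrow(cand) < cfg$genes_per_sweep) {
        cand <- pool # fall back to any remaining desert genes
      }
      cand <- cand[order(cand$chrom, cand$start), , drop = FALSE]
      take <- cand[seq_len(cfg$genes_per_sweep), , drop = FALSE]
      pool <- pool[!pool$gene_id %in% take$gene_id, , drop = FALSE]
      s_rows[[length(s_rows) + 1]] <- data.frame(
        chrom = take$chrom[1], start = min(take$start) - 1000,
        end = max(take$end) + 1000, label = sprintf("sweep_in_%d", i),
        stringsAsFactors = FALSE)
      sweep_genes <- c(sweep_genes, take$gene_id)
    }
  }
  if (cfg$n_sweep_out > 0) {
    for (i in seq_len(cfg$n_sweep_out)) {
      ch <- chroms[(i - 1) %% length(chroms) + 1]
      L <- cfg$chrom_lengths[ch]
      # right half of the chromosome, clear of the deserts
      s <- floor(runif(1, L * 0.55, L * 0.9))
      s_rows[[length(s_rows) + 1]] <- data.frame(
        chrom = ch, start = s, end = s + 2e5,
        label = sprintf("sweep_out_%d", i), stringsAsFactors = FALSE)
    }
  }
  sweeps <- validate_region_set(
    new_region_set(if (length(s_rows)) do.call(rbind, s_rows) else
      data.frame(), "sweeps"))
  manifest <- list(
    desert_genes = desert_genes$gene_id,
    desert_sweep_genes = sort(unique(sweep_genes)),
    n_desert_genes = nrow(desert_genes),
    n_desert_sweep_genes = length(unique(sweep_genes)))
  list(deserts = deserts, sweeps = sweeps, manifest = manifest)
}

default_planted_effects <- function(manifest) {
  list(
    list(genes = manifest$desert_sweep_genes, structure = "CBC",
         stages = c("Birth-Infancy", "Childhood", "Adolescence", "Adulthood"),
         shift = 2),
    list(genes = manifest$desert_sweep_genes, structure = "MD",
         stages = "Fetal1", shift = 2))
}

resolve_planted_effects <- function(cfg, manifest = NULL) {
  pe <- cfg$planted_effects
  if (identical(pe, "default")) {
    if (is.null(manifest)) return(list())
    return(default_planted_effects(manifest))
  }
  if (is.null(pe)) return(list())
  lapply(pe, function(e) {
    if (is.character(e$genes) && length(e$genes) == 1 &&
        e$genes %in% c("desert_sweep", "desert")) {
      ds_stopifnot(!is.null(manifest),
                   "planted effect references the region manifest, but none given")
      e$genes <- if (e$genes == "desert_sweep") manifest$desert_sweep_genes
      else manifest$desert_genes
    }
    e
  })
}

#' Generate a structure x stage RPKM expression matrix with planted truth
#'
#' Log2-scale means are `baseline + stage drift + structure offset +
#' planted shift`, optionally overridden per (gene, structure) by a planted
#' piecewise-linear trajectory; RPKM values are `2^(mean + noise) - 1`,
#' floored at 0. The returned manifest records every planted effect and
#' trajectory, sufficient to score downstream modules without re-deriving
#' anything.
#'
#' @param cfg a [synth_config()].
#' @param ann the annotation (rows define the genes simulated).
#' @param region_manifest optional manifest from [make_region_fixture()],
#'   used to resolve symbolic planted-effect gene sets.
#' @return list with `matrix` (raw-scale `expr_matrix`), `meta`
#'   (`sample_metadata`) and `manifest` (planted truth).
#' @export
make_expression <- function(cfg, ann, region_manifest = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(sub_seed(cfg, 3))
  genes <- ann$gene_id
  g <- length(genes)
  structures <- cfg$structures
  stages <- cfg$stages
  meta <- expand.grid(rep = seq_len(cfg$samples_per_cell),
                      stage = stages, structure = structures,
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_%s_r%d", meta$structure, meta$stage, meta$rep)
  meta$donor <- sprintf("D_%s_r%d", meta$stage, meta$rep)
  n <- nrow(meta)
  baseline <- rnorm(g, cfg$baseline_mean, cfg$baseline_sd)
  stage_slope <- rnorm(g, 0, cfg$stage_slope_sd)
  stage_idx <- match(meta$stage, stages)
  centered_stage <- stage_idx - mean(seq_along(stages))
  mu <- outer(baseline, rep(1, n)) +
    outer(stage_slope, centered_stage)
  if (cfg$structure_effect_sd > 0) {
    se <- matrix(rnorm(g * length(structures), 0, cfg$structure_effect_sd),
                 nrow = g, dimnames = list(genes, structures))
    mu <- mu + se[, meta$structure]
  }
  effects <- resolve_planted_effects(cfg, region_manifest)
  for (e in effects) {
    gi <- which(genes %in% e$genes)
    ci <- which(meta$structure == e$structure & meta$stage %in% e$stages)
    if (length(gi) && length(ci)) {
      mu[gi, ci] <- mu[gi, ci] + e$shift * cfg$noise_sd
    }
  }
  for (tr in cfg$planted_trajectories) {
    gi <- which(genes == tr$gene)
    if (!length(gi)) next
    ci <- which(meta$structure == tr$structure)
    lev <- piecewise_levels(seq_along(stages), tr$start, tr$breaks, tr$slopes)
    mu[gi, ci] <- lev[stage_idx[ci]]
  }
  noise <- matrix(rnorm(g * n, 0, cfg$noise_sd), nrow = g)
  vals <- pmax(2^(mu + noise) - 1, 0)
  dimnames(vals) <- list(genes, meta$sample_id)
  manifest <- list(
    planted_effects = lapply(effects, function(e) {
      list(genes = e$genes, structure = e$structure, stages = e$stages,
           shift = e$shift, shift_log2 = e$shift * cfg$noise_sd)
    }),
    planted_trajectories = cfg$planted_trajectories,
    noise_sd = cfg$noise_sd, seed = cfg$seed,
    structures = structures, stages = stages,
    samples_per_cell = cfg$samples_per_cell)
  list(matrix = expression_matrix(vals, "rpkm"),
       meta = sample_metadata(meta$sample_id, meta$structure, meta$stage,
                              meta$donor),
       manifest = manifest)
}

# level of a continuous piecewise-linear trajectory at integer times
piecewise_levels <- function(times, start, breaks, slopes) {
  ds_stopifnot(length(slopes) == length(breaks) + 1,
               "piecewise_levels: need one slope per segment")
  lev <- numeric(length(times))
  lev[1] <- start
  for (i in seq_along(times)[-1]) {
    seg <- findInterval(times[i] - 1, breaks) + 1
    lev[i] <- lev[i - 1] + slopes[seg] * (times[i] - times[i - 1])
  }
  lev
}

#' Write a complete synthetic fixture to disk
#'
#' Emits exactly the formats the pipeline reads: `chrom.sizes`,
#' `annotation.tsv`, `deserts.bed`, `sweeps.bed`, `matrix.tsv`,
#' `metadata.tsv`, plus `truth.json` (the combined manifest).
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `paths` (named written file paths) and
#'   the in-memory objects `genome`, `annotation`, `deserts`, `sweeps`,
#'   `expr`, `meta`, `manifest`.
#' @export
make_fixture <- function(cfg, dir) {
  ga <- make_genome_and_annotation(cfg)
  rf <- make_region_fixture(cfg, ga$annotation)
  ex <- make_expression(cfg, ga$annotation, rf$manifest)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    chrom_sizes = file.path(dir, "chrom.sizes"),
    annotation = file.path(dir, "annotation.tsv"),
    deserts = file.path(dir, "deserts.bed"),
    sweeps = file.path(dir, "sweeps.bed"),
    matrix = file.path(dir, "matrix.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.json"))
  write.table(ga$genome, paths$chrom_sizes, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_annotation(ga$annotation, paths$annotation)
  write_regions(rf$deserts, paths$deserts)
  write_regions(rf$sweeps, paths$sweeps)
  write_expression(ex$matrix, ex$meta, paths$matrix, paths$metadata)
  truth <- c(rf$manifest, ex$manifest)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, genome = ga$genome,
                 annotation = ga$annotation, deserts = rf$deserts,
                 sweeps = rf$sweeps, expr = ex$matrix, meta = ex$meta,
                 manifest = truth))
}
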