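# Orchestration: regions -> expression -> divergence (/ trajectories) with
# one config, structured logging and a deterministic report directory.

#' Construct a run configuration
#'
#' Thresholds default to the study's printed values: divergence alpha
#' 0.01, component alpha 0.05, adjusted R^2 gate 0.5, median filter 2.
#' The median filter applies only in `"global"` mode; gene subsets keep
#' their outliers.
#'
#' @param annotation path to the gene annotation TSV/GTF.
#' @param deserts,sweeps paths to region BED files (`sweeps` optional
#'   unless a sweep-based mode is requested).
#' @param matrix,metadata paths to the expression TSVs.
#' @param mode gene-subset mode: `"deserts"`, `"deserts_sweeps"`
#'   (intersection), `"sweeps_only"` (sweeps minus deserts), `"global"`,
#'   or `"per_chromosome"` (deserts split by chromosome).
#' @param alpha_divergence,alpha_pcs,r2_min,median_filter thresholds.
#' @param jackstraw_perms JackStraw permutation rounds.
#' @param fit_trajectories_for structures for which single-gene segmented
#'   fits are produced (character vector; empty skips the step).
#' @param seed master seed for every random step.
#' @return a `run_config` list.
#' @export
run_config <- function(annotation, deserts, matrix, metadata, sweeps = NULL,
                       mode = c("deserts", "deserts_sweeps", "sweeps_only",
                                "global", "per_chromosome"),
                       alpha_divergence = 0.01, alpha_pcs = 0.05,
                       r2_min = 0.5, median_filter = 2,
                       jackstraw_perms = 100,
                       fit_trajectories_for = character(), seed = 1) {
  mode <- match.arg(mode)
  for (a in c(alpha_divergence, alpha_pcs)) {
    ds_stopifnot(a > 0 && a < 1, "run_config: alpha out of (0,1)")
  }
  structure(list(annotation = annotation, deserts = deserts, sweeps = sweeps,
                 matrix = matrix, metadata = metadata, mode = mode,
                 alpha_divergence = alpha_divergence, alpha_pcs = alpha_pcs,
                 r2_min = r2_min, median_filter = median_filter,
                 jackstraw_perms = jackstraw_perms,
                 fit_trajectories_for = fit_trajectories_for,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with the fields of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, j)
}

select_mode_genes <- function(cfg, ann, deserts, sweeps) {
  switch(cfg$mode,
         deserts = list(all = genes_in_regions(ann, deserts,
                                               biotype = "protein_coding")),
         deserts_sweeps = {
           ds_stopifnot(!is.null(sweeps), "mode deserts_sweeps needs sweeps")
           inter <- intersect_region_sets(deserts, sweeps)
           list(all = genes_in_regions(ann, inter,
                                       biotype = "protein_coding"))
         },
         sweeps_only = {
           ds_stopifnot(!is.null(sweeps), "mode sweeps_only needs sweeps")
           sw <- genes_in_regions(ann, sweeps, biotype = "protein_coding")
           de <- genes_in_regions(ann, deserts, biotype = "protein_coding")
           list(all = sw[!sw$gene_id %in% de$gene_id, , drop = FALSE])
         },
         global = list(all = ann[ann$biotype == "protein_coding", ,
                                 drop = FALSE]),
         per_chromosome = {
           de <- genes_in_regions(ann, deserts, biotype = "protein_coding")
           split(de, de$chrom)
         })
}

#' Run the full analysis
#'
#' Gene assignment from the configured regions, subsetting, log2
#' transform, median filtering (global mode only), the divergence test,
#' and optional per-structure trajectory fits. All outputs (tidy TSVs and
#' a JSON summary embedding the config and seed) are written under
#' `out_dir`; two runs with an identical config are byte-identical.
#'
#' @param cfg a [run_config()] or path to its JSON form.
#' @param out_dir report directory (created).
#' @return invisibly, a list of per-subset results (`divergence`,
#'   `genes`, `trajectories`) plus `summary_path`.
#' @export
run_full_analysis <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  ann <- stage("annotation", read_annotation(cfg$annotation))
  deserts <- stage("regions", read_regions(cfg$deserts, "deserts"))
  sweeps <- if (!is.null(cfg$sweeps)) {
    stage("regions", read_regions(cfg$sweeps, "sweeps"))
  }
  ex <- stage("expression", read_expression(cfg$matrix, cfg$metadata))
  ds_log("pipeline", sprintf("loaded %d genes (annotation), %d x %d matrix",
                             nrow(ann), nrow(ex$matrix$values),
                             ncol(ex$matrix$values)))
  subsets <- stage("gene_assignment",
                   select_mode_genes(cfg, ann, deserts, sweeps))
  logm <- stage("log_transform", log_transform(ex$matrix))
  results <- list()
  for (sub_name in names(subsets)) {
    genes <- subsets[[sub_name]]
    ds_log("pipeline", sprintf("subset '%s': %d genes", sub_name, nrow(genes)))
    m <- stage("subset", subset_genes(logm, genes))
    if (cfg$mode == "global") {
      m <- stage("median_filter", median_filter(m, cfg$median_filter))
    }
    div <- stage("divergence",
                 run_divergence(m, ex$meta, alpha = cfg$alpha_divergence,
                                alpha_pcs = cfg$alpha_pcs,
                                n_perm = cfg$jackstraw_perms,
                                seed = cfg$seed))
    traj <- list()
    for (st in cfg$fit_trajectories_for) {
      fits <- stage("trajectory", fit_trajectories(m, ex$meta, st))
      traj[[st]] <- list(fits = fits,
                         retained = filter_fits(fits, cfg$r2_min))
    }
    prefix <- if (length(subsets) > 1) paste0(sub_name, "_") else ""
    write_tsv_ <- function(df, file) {
      write.table(df, file.path(out_dir, paste0(prefix, file)), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    write_tsv_(div$pairwise, "divergence_pairwise.tsv")
    write_tsv_(div$structures, "divergence_structures.tsv")
    write_tsv_(data.frame(stage = div$distances$stage,
                          structure_a = div$distances$structure_a,
                          structure_b = div$distances$structure_b,
                          distance = div$distances$distance),
               "distances.tsv")
    for (st in names(traj)) {
      write_tsv_(trajectory_table(traj[[st]]$fits),
                 sprintf("trajectories_%s.tsv", st))
    }
    results[[sub_name]] <- list(genes = genes, divergence = div,
                                trajectories = traj)
  }
  summary <- list(
    config = unclass(cfg),
    seed = cfg$seed,
    subsets = lapply(results, function(r) {
      div <- r$divergence
      flagged <- div$structures[div$structures$divergent, , drop = FALSE]
      list(n_genes = nrow(r$genes),
           components = div$components,
           divergent = if (nrow(flagged)) {
             lapply(seq_len(nrow(flagged)), function(i) {
               list(stage = flagged$stage[i], structure = flagged$structure[i],
                    mean_adj_p = flagged$mean_adj_p[i])
             })
           } else list(),
           retained_trajectories = lapply(r$trajectories, function(tr) {
             vapply(tr$retained, function(f) f$gene, character(1))
           }))
    }))
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(c(results, list(summary_path = summary_path)))
}
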