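# Expression matrix container and bookkeeping. Values are RPKM on the raw
# scale or log2(RPKM + 1) after log_transform(); the scale flag records which
# and transforms refuse to run twice.

#' Ordered developmental stage windows
#'
#' The eight stages used throughout, with their age windows: three fetal
#' windows (post-conception weeks), a perinatal window, and four postnatal
#' windows (years).
#'
#' @return data frame with columns `stage` (ordered factor levels) and
#'   `window` (human-readable age range).
#' @export
stage_windows <- function() {
  data.frame(
    stage = c("Fetal1", "Fetal2", "Fetal3", "Birth-Infancy", "Infancy-Child",
              "Childhood", "Adolescence", "Adulthood"),
    window = c("12-13 PCW", "16-18 PCW", "19-22 PCW",
               "35-37 PCW & 0-0.3 y", "0.5-2.5 y", "2.8-10.7 y",
               "13-19 y", "21-64 y"),
    stringsAsFactors = FALSE)
}

stage_levels <- function() stage_windows()$stage

#' Default brain structure labels
#'
#' The six collapsed structures: amygdala (AMY), cerebellar cortex (CBC),
#' hippocampus (HIP), mediodorsal thalamus (MD), neocortex (NCX),
#' striatum (STR).
#' @return character vector.
#' @export
structure_labels <- function() c("AMY", "CBC", "HIP", "MD", "NCX", "STR")

#' Neocortical area to structure collapse map
#'
#' Input metadata may carry 11 neocortical area labels; this map collapses
#' them (and passes the other five structures through) to the six-structure
#' vocabulary. User-editable: pass your own named vector to
#' [collapse_structures()].
#'
#' @return named character vector, `names` = input label, value = collapsed
#'   structure.
#' @export
ncx_collapse_map <- function() {
  areas <- c("A1C", "DFC", "IPC", "ITC", "M1C", "MFC", "OFC", "S1C", "STC",
             "V1C", "VFC")
  c(setNames(rep("NCX", length(areas)), areas),
    setNames(c("AMY", "CBC", "HIP", "MD", "STR"),
             c("AMY", "CBC", "HIP", "MD", "STR")))
}

#' Collapse structure labels in sample metadata
#' @param meta a `sample_metadata`.
#' @param map named character vector; unmapped labels pass through unchanged.
#' @return the metadata with `structure` relabeled.
#' @export
collapse_structures <- function(meta, map = ncx_collapse_map()) {
  hit <- meta$structure %in% names(map)
  meta$structure[hit] <- unname(map[meta$structure[hit]])
  meta
}

#' Construct an expression matrix
#'
#' @param values numeric genes x samples matrix with unique row and column
#'   names (gene ids / sample ids).
#' @param scale `"rpkm"` (raw, values >= 0) or `"log2"`.
#' @return an `expr_matrix`.
#' @export
expression_matrix <- function(values, scale = c("rpkm", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  ds_stopifnot(!is.null(rownames(values)) && !anyDuplicated(rownames(values)),
               "expression_matrix: need unique gene ids as rownames")
  ds_stopifnot(!is.null(colnames(values)) && !anyDuplicated(colnames(values)),
               "expression_matrix: need unique sample ids as colnames")
  if (scale == "rpkm") {
    ds_stopifnot(all(values >= 0), "expression_matrix: negative RPKM")
  }
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Construct sample metadata
#'
#' @param sample_id sample identifiers.
#' @param structure brain structure labels.
#' @param stage stage labels drawn from [stage_windows()].
#' @param donor optional donor ids.
#' @return data frame of class `sample_metadata`; `stage` is a factor with
#'   the canonical stage ordering.
#' @export
sample_metadata <- function(sample_id, structure, stage, donor = NA) {
  ds_stopifnot(all(stage %in% stage_levels()),
               "sample_metadata: unknown stage label(s): ",
               paste(setdiff(unique(stage), stage_levels()), collapse = ", "))
  df <- data.frame(sample_id = as.character(sample_id),
                   structure = as.character(structure),
                   stage = factor(stage, levels = stage_levels()),
                   donor = as.character(donor), stringsAsFactors = FALSE)
  ds_stopifnot(!anyDuplicated(df$sample_id),
               "sample_metadata: duplicate sample_id")
  structure(df, class = c("sample_metadata", "data.frame"))
}

#' Read an expression matrix and its sample metadata
#'
#' Matrix: TSV with genes as rows, a header of sample ids, and the gene id
#' in the first column. Metadata: TSV with columns `sample_id`,
#' `structure`, `stage` and optionally `donor`. Samples present in only one
#' of the two files are dropped with a warning that reports the count.
#'
#' @param matrix_path,metadata_path file paths.
#' @param scale scale flag of the stored values.
#' @return list with elements `matrix` (an `expr_matrix`) and `meta`
#'   (a `sample_metadata`).
#' @export
read_expression <- function(matrix_path, metadata_path,
                            scale = c("rpkm", "log2")) {
  scale <- match.arg(scale)
  vals <- read.table(matrix_path, sep = "\t", header = TRUE,
                     row.names = 1, check.names = FALSE,
                     stringsAsFactors = FALSE)
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  md <- read.table(metadata_path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  ds_stopifnot(all(c("sample_id", "structure", "stage") %in% names(md)),
               "read_expression: metadata needs sample_id, structure, stage")
  common <- intersect(colnames(m), md$sample_id)
  dropped <- length(union(colnames(m), md$sample_id)) - length(common)
  if (dropped > 0) {
    warning(sprintf("read_expression: dropped %d unmatched sample(s)", dropped))
  }
  ds_stopifnot(length(common) > 0, "read_expression: no samples in common")
  md <- md[match(common, md$sample_id), , drop = FALSE]
  meta <- sample_metadata(md$sample_id, md$structure, md$stage,
                          if ("donor" %in% names(md)) md$donor else NA)
  list(matrix = expression_matrix(m[, common, drop = FALSE], scale),
       meta = meta)
}

#' Write an expression matrix and metadata as TSV
#' @param m an `expr_matrix`.
#' @param meta a `sample_metadata`.
#' @param matrix_path,metadata_path output paths.
#' @return invisibly, the matrix path.
#' @export
write_expression <- function(m, meta, matrix_path, metadata_path) {
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- as.data.frame(meta)
  md$stage <- as.character(md$stage)
  write.table(md, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

#' Log-transform an RPKM matrix
#'
#' `value <- log2(value + 1)` (pseudocount and base configurable). Calling
#' this on an already log-scale matrix is an error, never a silent no-op.
#'
#' @param m an `expr_matrix` on the raw scale.
#' @param base logarithm base.
#' @param pseudocount added before taking the log.
#' @return an `expr_matrix` on the log2 scale.
#' @export
log_transform <- function(m, base = 2, pseudocount = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "rpkm") {
    stop("log_transform: matrix is already on the log scale", call. = FALSE)
  }
  out <- m
  out$values <- log(m$values + pseudocount, base = base)
  out$scale <- "log2"
  out
}

#' Filter genes by median expression
#'
#' Keeps genes whose per-gene median is strictly greater than `threshold`,
#' interpreted on the matrix's current scale. Subset analyses of
#' evolutionarily interesting gene sets skip this filter entirely (outliers
#' there are the point).
#'
#' @param m an `expr_matrix`.
#' @param threshold median cutoff (default 2).
#' @return the filtered `expr_matrix`; kept/dropped counts are logged.
#' @export
median_filter <- function(m, threshold = 2) {
  stopifnot(inherits(m, "expr_matrix"))
  med <- apply(m$values, 1, median)
  keep <- med > threshold
  ds_log("median_filter", sprintf("kept %d / dropped %d genes at median > %g [%s scale]",
                                  sum(keep), sum(!keep), threshold, m$scale))
  out <- m
  out$values <- m$values[keep, , drop = FALSE]
  out
}

#' Subset an expression matrix to a gene list
#'
#' Rows are restricted to the intersection of the requested and present
#' genes; requested-but-absent ids are reported in a warning. An empty
#' intersection is an error since downstream statistics are undefined.
#'
#' @param m an `expr_matrix`.
#' @param genes character vector of gene ids (or an `annotation`, whose
#'   `gene_id` column is used).
#' @return the subset `expr_matrix`, in the matrix's row order.
#' @export
subset_genes <- function(m, genes) {
  stopifnot(inherits(m, "expr_matrix"))
  if (inherits(genes, "annotation") || is.data.frame(genes)) {
    genes <- genes$gene_id
  }
  genes <- unique(as.character(genes))
  present <- rownames(m$values) %in% genes
  missing <- setdiff(genes, rownames(m$values))
  if (length(missing)) {
    warning(sprintf("subset_genes: %d requested gene(s) absent: %s",
                    length(missing), paste(missing, collapse = ", ")))
  }
  ds_stopifnot(any(present),
               "subset_genes: no requested genes present in the matrix")
  out <- m
  out$values <- m$values[present, , drop = FALSE]
  out
}

#' Structure x stage summary profile
#'
#' For each (structure, stage) cell with at least one sample, the median
#' and standard deviation over all (gene, sample) values of the cell.
#' Cells with a single value report SD = 0 and are flagged low-confidence.
#'
#' @param m an `expr_matrix`.
#' @param meta a `sample_metadata` covering the matrix's samples.
#' @return data frame with columns `structure`, `stage`, `median`, `sd`,
#'   `n_values`, `low_confidence`.
#' @export
summarize_expression <- function(m, meta) {
  stopifnot(inherits(m, "expr_matrix"))
  idx <- match(colnames(m$values), meta$sample_id)
  ds_stopifnot(!anyNA(idx), "summarize_expression: samples missing from metadata")
  meta <- meta[idx, , drop = FALSE]
  out <- list()
  for (st in sort(unique(meta$structure))) {
    for (sg in stage_levels()) {
      cols <- which(meta$structure == st & as.character(meta$stage) == sg)
      if (length(cols) == 0) next
      v <- as.vector(m$values[, cols, drop = FALSE])
      if (length(v) == 0) next
      out[[length(out) + 1]] <- data.frame(
        structure = st, stage = sg, median = median(v),
        sd = if (length(v) > 1) sd(v) else 0,
        n_values = length(v), low_confidence = length(v) < 2,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$stage <- factor(res$stage, levels = stage_levels())
  res
}
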