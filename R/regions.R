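# Interval data model. Coordinates are BED dialect throughout: 0-based,
# half-open [start, end). GenomicRanges (1-based, closed) backs the overlap
# machinery behind this API.

#' Named constants: desert gene counts reported in the source literature
#'
#' The deserts' protein-coding gene total is reported both as 265 (methods
#' text, and the floor used for gene-density matching of random regions) and
#' as 255 (figure caption). Both are surfaced here; neither is asserted
#' anywhere in the package.
#' @return named integer vector with elements `methods` and `figure`.
#' @export
desert_gene_counts <- function() c(methods = 265L, figure = 255L)

new_region_set <- function(df, name = "regions") {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0) {
    df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     label = character(), stringsAsFactors = FALSE)
  }
  df <- df[, c("chrom", "start", "end", "label")]
  rownames(df) <- NULL
  structure(df, class = c("region_set", "data.frame"), name = name)
}

#' Construct a region set
#'
#' A `region_set` is a data frame of labeled genomic intervals
#' (`chrom`, `start`, `end`, `label`) in 0-based half-open coordinates.
#'
#' @param chrom chromosome names.
#' @param start,end interval bounds, 0-based half-open; `end > start >= 0`.
#' @param label free-text label per interval (recycled).
#' @param name identifier for the whole set.
#' @return a `region_set`.
#' @export
region_set <- function(chrom = character(), start = numeric(), end = numeric(),
                       label = "", name = "regions") {
  n <- length(chrom)
  label <- rep_len(as.character(label), n)
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), label = label,
                   stringsAsFactors = FALSE)
  validate_region_set(new_region_set(df, name))
}

validate_region_set <- function(rs) {
  if (nrow(rs) == 0) return(rs)
  ds_stopifnot(all(nzchar(rs$chrom)), "region_set: empty chromosome name")
  ds_stopifnot(all(rs$start >= 0), "region_set: start must be >= 0")
  bad <- which(rs$end <= rs$start)
  if (length(bad)) {
    stop(sprintf("region_set: end <= start for region(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  rs
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set '%s'> %d region(s), %.3g Mb total\n",
              attr(x, "name") %||% "regions", nrow(x),
              sum(x$end - x$start) / 1e6))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

region_set_name <- function(rs) attr(rs, "name") %||% "regions"

#' Total length of a region set in base pairs
#' @param rs a `region_set`.
#' @return numeric scalar.
#' @export
total_length <- function(rs) sum(rs$end - rs$start)

# 0-based half-open -> GRanges (1-based closed)
as_granges <- function(rs) {
  GenomicRanges::GRanges(rs$chrom,
                         IRanges::IRanges(start = rs$start + 1, end = rs$end))
}

#' Read a BED file into a region set
#'
#' Accepts 3+ tab-separated columns; column 4, when present, becomes the
#' label. Coordinates are taken as 0-based half-open (BED standard); pass
#' `one_based = TRUE` for 1-based inclusive input.
#'
#' @param path BED file path.
#' @param name identifier for the set; defaults to the file name.
#' @param one_based treat input coordinates as 1-based inclusive.
#' @return a `region_set`.
#' @export
read_regions <- function(path, name = basename(path), one_based = FALSE) {
  ds_stopifnot(file.exists(path), "read_regions: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) return(new_region_set(data.frame(), name))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3 || is.na(suppressWarnings(as.numeric(f[2]))) ||
        is.na(suppressWarnings(as.numeric(f[3])))) {
      stop(sprintf("read_regions: malformed BED line %d in %s", i, path),
           call. = FALSE)
    }
  }
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1),
    start = as.numeric(vapply(fields, `[`, "", 2)),
    end   = as.numeric(vapply(fields, `[`, "", 3)),
    label = vapply(fields, function(f) if (length(f) >= 4) f[4] else "", ""),
    stringsAsFactors = FALSE)
  if (one_based) df$start <- df$start - 1
  validate_region_set(new_region_set(df, name))
}

#' Write a region set as BED
#' @param rs a `region_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(rs, path) {
  write.table(as.data.frame(rs), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chrom.sizes table
#'
#' Two tab-separated columns: chromosome name, length in bp.
#' @param path file path.
#' @return data frame with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  ds_stopifnot(ncol(df) >= 2, "read_chrom_sizes: need two columns")
  out <- data.frame(chrom = as.character(df[[1]]), length = as.numeric(df[[2]]),
                    stringsAsFactors = FALSE)
  ds_stopifnot(all(out$length > 0), "read_chrom_sizes: non-positive length")
  out
}

#' Construct a gene annotation
#'
#' @param gene_id unique stable identifiers.
#' @param symbol display names.
#' @param chrom,start,end gene body coordinates, 0-based half-open.
#' @param biotype category, e.g. `"protein_coding"`.
#' @return data frame of class `annotation`, ordered by `chrom`, `start`.
#' @export
annotation <- function(gene_id, symbol = gene_id, chrom, start, end,
                       biotype = "protein_coding") {
  df <- data.frame(gene_id = as.character(gene_id),
                   symbol = as.character(symbol),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   biotype = as.character(biotype), stringsAsFactors = FALSE)
  ds_stopifnot(!anyDuplicated(df$gene_id), "annotation: duplicate gene_id")
  ds_stopifnot(all(df$end > df$start), "annotation: end must be > start")
  df <- df[order(df$chrom, df$start), ]
  rownames(df) <- NULL
  structure(df, class = c("annotation", "data.frame"))
}

#' Read a gene annotation
#'
#' Accepts either a 6-column TSV (`gene_id`, `symbol`, `chrom`, `start`,
#' `end`, `biotype`; header optional, 0-based half-open) or a GTF from which
#' only `gene` features are used (GTF is 1-based inclusive and converted).
#'
#' @param path file path.
#' @param format `"tsv"` or `"gtf"`; guessed from the extension by default.
#' @return an `annotation`.
#' @export
read_annotation <- function(path, format = c("auto", "tsv", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "tsv"
  }
  if (format == "gtf") return(read_annotation_gtf(path))
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  ds_stopifnot(ncol(df) >= 6, "read_annotation: need 6 columns")
  if (identical(tolower(df[1, 1]), "gene_id")) df <- df[-1, , drop = FALSE]
  annotation(gene_id = df[[1]], symbol = df[[2]], chrom = df[[3]],
             start = as.numeric(df[[4]]), end = as.numeric(df[[5]]),
             biotype = df[[6]])
}

read_annotation_gtf <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#", quote = "")
  df <- df[df[[3]] == "gene", , drop = FALSE]
  ds_stopifnot(nrow(df) > 0, "read_annotation: no gene features in GTF")
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(sprintf('%s "[^"]*"', key), attrs))
    ifelse(lengths(regmatches(attrs, gregexpr(key, attrs))) > 0,
           sub(sprintf('%s "([^"]*)"', key), "\\1", m), NA_character_)
  }
  ids <- attr_field(df[[9]], "gene_id")
  sym <- attr_field(df[[9]], "gene_name")
  bt <- attr_field(df[[9]], "gene_biotype")
  annotation(gene_id = ids, symbol = ifelse(is.na(sym), ids, sym),
             chrom = df[[1]], start = as.numeric(df[[4]]) - 1,
             end = as.numeric(df[[5]]),
             biotype = ifelse(is.na(bt), "unknown", bt))
}

#' Write an annotation as 6-column TSV
#' @param ann an `annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Genes contained in a set of regions
#'
#' Returns the genes whose full gene body lies inside some region
#' (`mode = "within"`, the default containment rule) or that overlap a
#' region by at least one base (`mode = "any"`), optionally filtered by
#' biotype. Regions on chromosomes absent from the annotation are skipped
#' with a warning.
#'
#' @param ann an `annotation`.
#' @param regions a `region_set`.
#' @param biotype keep only genes of this biotype; `NULL` keeps all.
#' @param mode containment rule.
#' @return an `annotation` subset, ordered by `chrom`, `start`.
#' @export
genes_in_regions <- function(ann, regions, biotype = NULL,
                             mode = c("within", "any")) {
  mode <- match.arg(mode)
  ds_stopifnot(nrow(ann) > 0, "genes_in_regions: empty annotation")
  if (nrow(regions) == 0) return(ann[0, , drop = FALSE])
  unknown <- !(regions$chrom %in% unique(ann$chrom))
  if (any(unknown)) {
    warning(sprintf("genes_in_regions: skipping %d region(s) on chromosome(s) unknown to the annotation: %s",
                    sum(unknown), paste(unique(regions$chrom[unknown]), collapse = ", ")))
    regions <- regions[!unknown, , drop = FALSE]
    if (nrow(regions) == 0) return(ann[0, , drop = FALSE])
  }
  gr_genes <- GenomicRanges::GRanges(ann$chrom,
                                     IRanges::IRanges(ann$start + 1, ann$end))
  gr_reg <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1, regions$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_reg, type = mode)
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  out <- ann[keep, , drop = FALSE]
  if (!is.null(biotype)) out <- out[out$biotype %in% biotype, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-base intersection of two region sets
#'
#' Each output region is an overlap between one region of `a` and one of
#' `b`; its label concatenates both parent labels.
#'
#' @param a,b `region_set`s.
#' @return a `region_set` named `"<a> & <b>"`.
#' @export
intersect_region_sets <- function(a, b) {
  name <- paste(region_set_name(a), region_set_name(b), sep = " & ")
  if (nrow(a) == 0 || nrow(b) == 0) return(new_region_set(data.frame(), name))
  ga <- as_granges(a)
  gb <- as_granges(b)
  hits <- GenomicRanges::findOverlaps(ga, gb)
  if (length(hits) == 0) return(new_region_set(data.frame(), name))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::pintersect(ga[qi], gb[si])
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(ov)),
                   start = GenomicRanges::start(ov) - 1,
                   end = GenomicRanges::end(ov),
                   label = paste(a$label[qi], b$label[si], sep = " & "),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  validate_region_set(new_region_set(df, name))
}

#' Sampler configuration for matched random regions
#'
#' Defaults mirror the study design: 1,000 replicate sets, regions of
#' roughly 15 Mb (within 1 Mb of each template region's length), and a
#' gene-density floor of 265 contained genes per replicate set.
#'
#' @param n_replicates number of replicate region sets.
#' @param target_length nominal region length in bp (informational; the
#'   per-region length is matched to the template).
#' @param length_tolerance allowed deviation from each template region's
#'   length, in bp.
#' @param min_total_genes replicate-set floor on contained genes.
#' @param excluded `region_set` that replicates may not overlap; defaults to
#'   the template itself at sampling time.
#' @param seed integer RNG seed.
#' @param max_attempts rejection-sampling cap per replicate.
#' @param biotype count only genes of this biotype toward the floor
#'   (`NULL` counts all genes).
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(n_replicates = 1000, target_length = 15e6,
                           length_tolerance = 1e6, min_total_genes = 265,
                           excluded = NULL, seed = 1, max_attempts = 10000,
                           biotype = NULL) {
  ds_stopifnot(n_replicates >= 0, "sampler_config: n_replicates must be >= 0")
  ds_stopifnot(length_tolerance < target_length,
               "sampler_config: length_tolerance must be < target_length")
  ds_stopifnot(min_total_genes >= 0,
               "sampler_config: min_total_genes must be >= 0")
  structure(list(n_replicates = as.integer(n_replicates),
                 target_length = target_length,
                 length_tolerance = length_tolerance,
                 min_total_genes = as.integer(min_total_genes),
                 excluded = excluded, seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts), biotype = biotype),
            class = "sampler_config")
}

# fast containment count: genes fully inside [s, e) on one chromosome
count_contained <- function(index, chrom, s, e) {
  g <- index[[chrom]]
  if (is.null(g)) return(0L)
  sum(g$start >= s & g$end <= e)
}

build_gene_index <- function(ann, biotype = NULL) {
  if (!is.null(biotype)) ann <- ann[ann$biotype %in% biotype, , drop = FALSE]
  split(ann[, c("start", "end")], ann$chrom)
}

overlaps_any <- function(chrom, s, e, other) {
  if (length(other$chrom) == 0) return(FALSE)
  any(other$chrom == chrom & other$start < e & other$end > s)
}

#' Sample length- and gene-density-matched random region sets
#'
#' Rejection sampling: each replicate contains one region per template
#' region, drawn uniformly over the genome, with length within
#' `length_tolerance` of that template region's length, overlapping neither
#' the excluded regions nor another region of the same replicate, and with
#' the replicate's total contained-gene count at or above
#' `min_total_genes`. Reproducible from `cfg$seed`.
#'
#' @param genome data frame with columns `chrom`, `length`.
#' @param ann an `annotation` used for gene-density matching.
#' @param cfg a [sampler_config()].
#' @param template `region_set` to match (e.g. the introgression deserts).
#' @return list of `region_set`s of length `cfg$n_replicates`.
#' @export
sample_matched_regions <- function(genome, ann, cfg, template) {
  stopifnot(inherits(cfg, "sampler_config"))
  ds_stopifnot(nrow(template) > 0, "sample_matched_regions: empty template")
  if (cfg$n_replicates == 0) return(list())
  excluded <- cfg$excluded %||% template
  index <- build_gene_index(ann, cfg$biotype)
  set.seed(cfg$seed)
  tmpl_len <- template$end - template$start
  excl <- list(chrom = excluded$chrom, start = excluded$start,
               end = excluded$end)
  out <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    attempts <- 0L
    repeat {
      placed <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), label = character(),
                           stringsAsFactors = FALSE)
      ok <- TRUE
      for (j in seq_along(tmpl_len)) {
        hit <- FALSE
        while (attempts < cfg$max_attempts) {
          attempts <- attempts + 1L
          len <- round(runif(1, tmpl_len[j] - cfg$length_tolerance,
                             tmpl_len[j] + cfg$length_tolerance))
          eligible <- genome$length - len
          if (all(eligible <= 0)) break
          w <- pmax(eligible, 0)
          ci <- sample.int(nrow(genome), 1, prob = w / sum(w))
          s <- floor(runif(1, 0, eligible[ci] + 1))
          e <- s + len
          chrom <- genome$chrom[ci]
          if (overlaps_any(chrom, s, e, excl)) next
          if (overlaps_any(chrom, s, e,
                           list(chrom = placed$chrom, start = placed$start,
                                end = placed$end))) next
          placed <- rbind(placed, data.frame(
            chrom = chrom, start = s, end = e,
            label = sprintf("rep%d_%s", r, template$label[j]),
            stringsAsFactors = FALSE))
          hit <- TRUE
          break
        }
        if (!hit) { ok <- FALSE; break }
      }
      if (ok) {
        n_genes <- sum(vapply(seq_len(nrow(placed)), function(i) {
          count_contained(index, placed$chrom[i], placed$start[i],
                          placed$end[i])
        }, integer(1)))
        if (n_genes >= cfg$min_total_genes) {
          out[[r]] <- validate_region_set(
            new_region_set(placed, sprintf("replicate_%d", r)))
          break
        }
      }
      if (attempts >= cfg$max_attempts) {
        stop(sprintf(paste0("sample_matched_regions: replicate %d infeasible ",
                            "after %d attempts (constraints too strict for ",
                            "this genome)"), r, attempts), call. = FALSE)
      }
    }
  }
  out
}

#' Region-level permutation test
#'
#' Empirical p-value of an observed statistic against the distribution of
#' the same statistic over matched random region sets, with the add-one
#' correction `p = (1 + k) / (1 + n)` where `k` counts replicates at least
#' as extreme as the observation.
#'
#' @param observed_stat observed scalar statistic.
#' @param stat_fn function mapping a `region_set` to a scalar.
#' @param replicates list of `region_set`s (the null ensemble).
#' @param alternative `"two-sided"`, `"greater"` or `"less"`.
#' @return list with `p`, `null` (vector of replicate statistics),
#'   `observed` and `alternative`, of class `permutation_test`.
#' @export
region_permutation_test <- function(observed_stat, stat_fn, replicates,
                                    alternative = c("two-sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  ds_stopifnot(length(replicates) >= 1,
               "region_permutation_test: need >= 1 replicate")
  null <- vapply(seq_along(replicates), function(i) {
    tryCatch(as.numeric(stat_fn(replicates[[i]])), error = function(e) {
      stop(sprintf("region_permutation_test: stat_fn failed on replicate %d: %s",
                   i, conditionMessage(e)), call. = FALSE)
    })
  }, numeric(1))
  n <- length(null)
  p_greater <- (1 + sum(null >= observed_stat)) / (1 + n)
  p_less <- (1 + sum(null <= observed_stat)) / (1 + n)
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              `two-sided` = min(1, 2 * min(p_greater, p_less)))
  structure(list(p = p, null = null, observed = observed_stat,
                 alternative = alternative), class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> observed = %.4g, n = %d, %s p = %.4g\n",
              x$observed, length(x$null), x$alternative, x$p))
  invisible(x)
}
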