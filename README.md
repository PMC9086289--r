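# desertscope

Brain-region expression trajectories for genes inside large
archaic-introgression deserts and positively-selected regions.

## What it is for

Introgression deserts are genomic regions of the modern human genome
depleted of Neanderthal/Denisovan haplotypes; selective-sweep catalogues
mark windows under positive selection on our lineage. A recurring
question in human evolutionary genomics is whether the genes inside such
intervals show distinctive expression dynamics in the developing brain.
desertscope packages that analysis as a reusable, tested pipeline for
anyone with (a) interval coordinates (BED), (b) a gene annotation
(TSV/GTF) and (c) an RPKM expression matrix with structure × stage sample
metadata (the shape of the psychENCODE developmental resource: brain
structures AMY, CBC, HIP, MD, NCX, STR across eight stages from 12
post-conception weeks to adulthood).

## The statistics at its core

* **Matched random-region null** — `sample_matched_regions()` draws
  replicate sets of random regions matched to the deserts in length
  (±1 Mb) and gene density (≥ 265 contained genes by default), excluding
  the deserts themselves; `region_permutation_test()` converts any
  region-level statistic into an empirical p-value
  `p = (1 + k)/(1 + n)`.
* **Transcriptomic divergence** — `run_divergence()` performs PCA on the
  samples over a gene subset, keeps JackStraw-significant components
  (p < 0.05; first two components for small subsets), computes per-stage
  pairwise Euclidean distances between samples of different structures,
  and calls a structure **divergent** at a stage when its attributed
  distance distribution differs from *every* other structure's
  (two-sided Wilcoxon rank-sum, Bonferroni within stage, adjusted
  p < 0.01).
* **Cohort battery** — repeated-measures two-way ANOVA (structure as
  subject, datasource as repeated factor), per-structure post-hoc ANOVAs
  with Bonferroni, two-sided Grubbs outlier test, tie-corrected
  Kruskal-Wallis, nested linear-model F-tests, Tukey stage post-hocs on
  per-structure means.
* **Segmented trajectories** — `fit_segmented()` fits continuous
  piecewise-linear models with 0–3 breakpoints (≥ 2 points per segment),
  selected by stepwise extended BIC, gated at adjusted R² ≥ 0.5, and
  labels shapes (`monotone-up/-down`, `peak`, `V-shape`, `flat`,
  `complex`).
* **Synthetic data** — `synth_config()` / `make_fixture()` generate a
  deterministic toy genome, desert/sweep fixtures and RPKM matrices with
  planted effects plus a JSON truth manifest, so the entire pipeline is
  testable offline.

## Worked example

```r
library(desertscope)

# a fully synthetic world: genome, annotation, 4 deserts, sweeps,
# 6 structures x 8 stages x 3 samples, planted divergence effects
fx <- make_fixture(synth_config(seed = 42), "fixture")
fx$deserts
#> <region_set 'deserts'> 4 region(s), 60 Mb total
#>   chrom    start      end    label
#> 1  chr1  3902664 18902664 desert_1
#> 2  chr2  2324457 17324457 desert_2
#> 3  chr3 12728500 27728500 desert_3
#> 4  chr4 10339916 25339916 desert_4

# genes both inside deserts and under a sweep (12 by construction)
lg  <- log_transform(fx$expr)                      # log2(RPKM + 1)
sub <- subset_genes(lg, fx$manifest$desert_sweep_genes)

res <- run_divergence(sub, fx$meta, alpha = 0.01, n_perm = 100, seed = 42)
res
#> <divergence_result> 120 pairwise tests, 8 stage(s); 5 divergent (structure, stage) cell(s) at alpha = 0.01
#>          stage structure   mean_adj_p
#>         Fetal1        MD 1.359150e-09
#>  Birth-Infancy       CBC 5.013152e-09
#>      Childhood       CBC 5.653482e-09
#>    Adolescence       CBC 4.918757e-09
#>      Adulthood       CBC 2.785387e-08
```

The generator planted a +2-SD shift for the cerebellum-like structure
(CBC) at four postnatal stages and for the thalamus-like structure (MD)
at the first fetal stage on exactly these 12 genes — the divergence call
recovers precisely those five (structure, stage) cells: `mean_adj_p` is
the average Bonferroni-adjusted Wilcoxon p of the structure against all
five others at that stage, and a cell is listed only if *every* pairwise
comparison is below 0.01.

The same analysis runs end-to-end from files:

```r
cfg <- run_config(annotation = "fixture/annotation.tsv",
                  deserts    = "fixture/deserts.bed",
                  sweeps     = "fixture/sweeps.bed",
                  matrix     = "fixture/matrix.tsv",
                  metadata   = "fixture/metadata.tsv",
                  mode       = "deserts_sweeps", seed = 42)
run_full_analysis(cfg, "report")   # tidy TSVs + summary.json, byte-deterministic
```

A command-line entry point with `synth`, `run` and `sample` subcommands
is installed at `inst/cli/desertscope.R`
(`Rscript <path>/desertscope.R run --config run.json -o report/`).

## Vignette

`vignettes/desertscope-methods.Rmd` documents the model assumptions,
tunable parameters and their defaults, what the synthetic generator does
and does not emulate, and the numerical choices (extended-BIC breakpoint
selection, small-subset component override, tie handling).
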