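---
title: "desertscope: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{desertscope: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desertscope)
options(desertscope.quiet = TRUE)
```

# The scientific problem

Genomic regions depleted of archaic-hominin (Neanderthal/Denisovan)
haplotypes — introgression deserts — and regions carrying signals of
positive selection on the modern-human lineage are natural candidates for
harbouring genes whose regulation distinguishes our species. desertscope
implements a pipeline that asks: do the genes inside such intervals follow
brain-region expression trajectories across development that stand apart
from the rest of the transcriptome? The pipeline takes interval
coordinates, a gene annotation, and an RPKM expression matrix over brain
structures and developmental stages (the shape of the psychENCODE
developmental resource: up to sixteen structures, collapsible to six —
AMY, CBC, HIP, MD, NCX, STR — and eight stages from 12 post-conception
weeks to adulthood), and produces three families of results:

1. **Matched-control comparisons** (`genome_regions`, `cohort_stats`):
   random genomic regions matched to the intervals of interest in length
   and gene density serve as a permutation null for region-level
   statistics, and a battery of classical tests compares mean expression
   between gene cohorts.
2. **Transcriptomic divergence** (`divergence`): the headline statistic.
   Per developmental stage, a brain structure is called *divergent* when
   its distribution of PCA-subspace Euclidean distances to samples of
   other structures differs (Wilcoxon rank-sum, Bonferroni-adjusted
   p < 0.01) from that of *every* other structure.
3. **Single-gene trajectories** (`trajectory`): segmented
   (breakpoint) regression of one gene's expression against stage rank,
   with an adjusted-R² ≥ 0.5 reporting gate and shape labels
   (monotone, peak, V-shape).

Everything is exercisable offline through the `synthetic_data` module,
which generates a toy genome, annotation, desert/sweep fixtures and
expression matrices with *planted*, manifest-recorded effects.

# Coordinates and gene assignment

All intervals are BED-dialect internally: 0-based, half-open. Readers
accept 1-based inclusive input via a flag. "Genes within a region" means
**full gene-body containment** by default: deserts are ~15 Mb, so genes
straddling a boundary are rare, and containment is the stricter,
reproducible reading; any-overlap is available as `mode = "any"`.
Biotype filtering (default use case: `protein_coding`) is applied after
containment.

The literature reports the deserts' protein-coding gene count
inconsistently (265 in the methods text, 255 in a figure caption). Both
numbers are exposed by `desert_gene_counts()` and neither is asserted:
the count depends on the annotation release, which is an input here.

# The matched random-region null

`sample_matched_regions()` draws, for each replicate, one random region
per template region (so a replicate is a *set* matching the four deserts,
not a single interval — the gene-count floor plainly refers to the
deserts' total), with:

- length within ±1 Mb (default) of the corresponding template region;
- no overlap with the excluded set (default: the template itself) nor
  with other regions of the same replicate;
- the replicate's total contained-gene count at or above the floor
  (default 265) — a floor, not a band, mirroring "at least as many
  genes".

Sampling is rejection sampling with uniform starts over eligible
chromosome space and an explicit attempt cap (default 10,000 per
replicate); infeasibility raises an error rather than silently relaxing a
constraint. The empirical p-value of `region_permutation_test()` uses the
add-one formula `(1 + k)/(1 + n)`, so p is never 0 and lies in
`[1/(n+1), 1]`.

# The divergence procedure

**PCA.** Samples are observations, genes variables; genes are centered
but not variance-scaled (distances should live on the log2-expression
scale; unit-variance scaling is a flag). Component signs are
canonicalized (largest-magnitude loading positive) so results are
deterministic.

**JackStraw.** A random fraction of gene rows (default 10%, at least one
gene) is permuted across samples, the PCA recomputed, and squared
loadings of the permuted genes pooled as the null association score.
Gene-level empirical p-values are tested per component for enrichment
below 0.05 with a one-sided exact binomial test. Components with p < 0.05
are retained.

**Small subsets.** With very few genes (< 30) the JackStraw null is
structurally uninformative: squared loadings are normalized over genes, so
a permuted gene's loading on a component spread across ~12 genes is not
smaller than a real one's. This is exactly why a 12-gene subset's second
component fails significance even when it carries signal. For such
subsets `select_components()` overrides the call and uses the first two
components (logged); for larger matrices the significant set is used,
with a fallback to the first two when fewer than two pass.

**Distances and the divergence call.** Within each stage, Euclidean
distances in the selected-component subspace are computed between every
pair of samples from *different* structures; each distance is attributed
to both endpoint structures. For every structure pair the two attributed
distance distributions are compared with a two-sided Wilcoxon rank-sum
test: exact by full enumeration of group assignments (midranks, valid
under ties) when the assignment count is ≤ 100,000; exact via the
rank-sum distribution when tie-free and both groups ≤ 25; otherwise the
normal approximation with tie correction and continuity correction. An
all-tied comparison returns p = 1 by convention. Bonferroni correction is
applied over all pairs within one stage (the per-stage family matches
per-stage significance profiles; a global family is a flag). A structure
is divergent at a stage iff **all** its pairwise adjusted p-values are
below α = 0.01; the per-structure mean adjusted p is the line-plot
statistic.

Sample-level (not centroid) distances are used: distance boxplots per
structure and stage only make sense with a distribution of sample pairs.

# The cohort-statistics battery

- `rm_two_way_anova()`: repeated-measures ANOVA with structure as the
  subject identifier and datasource (control / deserts /
  deserts∩sweeps) as the repeated factor, on per-cell means. Effect
  sums-of-squares at numerical-noise level (≤ 1e-12 of the total squared
  values) are treated as zero, returning F = 0, p = 1 — `aov()`
  otherwise manufactures an F statistic from 1e-30-scale ratios.
- `posthoc_pairwise_anova()`: one ANOVA per structure over replicate
  values, Bonferroni family = number of structures.
- `grubbs_test()`: G = max|x − mean|/sd, both sides, with the classical
  t-distribution relation for the one-sided p. Assumes approximate
  normality of per-structure means.
- `kruskal_wallis()`: tie-corrected H (backed by `stats::kruskal.test`;
  the test suite checks it against a hand-computed rank formula). An
  all-identical input returns H = 0, p = 1.
- `nested_model_comparison()`: the "does the factor matter" question is
  answered by an F-test between nested fixed-effect linear models
  (`value ~ datasource` vs `value ~ datasource + factor`). The source
  workflow describes two-level mixed models but evaluates them by an
  ANOVA between fitted models; a true random-intercept fit (lme4) is a
  documented extension point, not part of the contract.
- `tukey_posthoc()`: stage contrasts on per-subject (structure) stage
  means — the repeated-measures correction — with studentized-range
  adjusted p-values.

# Segmented trajectories

`fit_segmented()` fits continuous piecewise-linear least squares with
breakpoints placed on the observed time grid (points at a breakpoint
belong to the left segment; an equivalent discrete parameterization of
between-point breakpoints). The search is exhaustive over placements for
k = 0..3 breakpoints with ≥ 2 points per segment.

**Model selection.** Plain BIC applied to the best-of-all-placements fit
overfits badly: on 12 pure-noise points the minimum-RSS 3-breakpoint fit
frequently halves the RSS, and the selected model reaches adjusted
R² ≥ 0.5 in roughly half of random series. This is the known failure of
unadjusted information criteria for changepoint models. desertscope
therefore uses forward-stepwise selection with an extended BIC: each
estimated breakpoint location counts as a parameter, the
`2·log(choose(C, k))` multiplicity of the placement search (C = candidate
positions) enters the penalty, and stepping stops at the first k that
fails to improve. Measured on 200 seeds: 96.5% of pure-noise series fall
below the R² gate while planted single-breakpoint series (slopes +1/−1,
noise SD 0.3, 12 points) are recovered within ±1 time unit in 200/200
runs.

Adjusted R² is reported with the effective model size (2k + 2) and is
used only for the ≥ 0.5 reporting gate (an exact 0.5 is retained and
logged as a boundary case), never for selection. Genes with mean
expression below 2 are rejected before fitting (`low_expression`), series
too short to segment are rejected as `too_short`. Segment directions come
from slope t-tests at p < 0.05 ("flat" when not significant), and the
direction sequence (flats removed, runs collapsed) maps to the shape
labels: `monotone-up`, `monotone-down`, `peak` (up→down), `V-shape`
(down→up), `flat`, `complex`. Replicate samples at a stage are kept as
repeated x-values by default; per-stage medians are a flag.

# The synthetic world

`synth_config()` states the world once:

- 6 structures × 8 stages × 3 samples per cell, 300 genes on four 60 Mb
  chromosomes (tiny, so the suite runs in minutes); 80% protein-coding;
  gene density decreasing 3:1 along each chromosome so density matching
  is non-trivial.
- log2 means: per-gene baseline ~ N(3, 1.5); per-gene linear stage drift
  with slope SD 0.25 (developmental change shared across structures); *no*
  generic structure effect, so the no-plant configuration is a true null
  for the divergence test; within-cell noise SD 0.5 on the log2 scale.
  RPKM = 2^(mean + noise) − 1, floored at 0 (lognormal noise — the
  pipeline analyses log-scale values, and the source data are RPKM, so
  count-level models are out of scope).
- planted defaults emulate the study's findings: a cerebellum-like
  structure (CBC) shifted +2 noise-SDs on the 12 desert∩sweep genes at
  four postnatal stages, and a thalamus-like structure (MD) shifted at
  the first fetal stage. Planted trajectories override a gene's stage
  profile with a piecewise-linear course.
- the region fixture wraps sweep intervals around known desert genes so
  the desert∩sweep intersection has exactly 12 recorded members.

Every output is a pure function of the config (deterministic sub-seeds
per generator stage), and the truth manifest records memberships, planted
shifts and trajectories — sufficient to score every downstream module
without re-deriving anything.

What a green test does *not* establish: the generator has no donor
structure, no missing cells, no heteroskedastic or count-level noise, no
correlated genes beyond the planted effects, and structure differences
are pure mean shifts. Results on real data depend on properties the
generator does not emulate.

# Orchestration and determinism

`run_full_analysis()` wires annotation → region gene assignment → log2
transform → (median > 2 filter, in global mode only — gene subsets keep
their outliers deliberately) → divergence, with optional per-structure
trajectory fits. Config files are JSON (the environment guarantees
jsonlite; YAML is not in the dependency contract). All thresholds default
to the study's printed values (divergence α = 0.01, component α = 0.05,
R² gate 0.5, median filter 2). Every random step derives from the single
config seed; two runs with the same config produce byte-identical
reports.

# Known limitations

- The Wilcoxon comparison of attributed distance distributions follows
  the figure-caption reading of the source analysis; the shared
  d(a, b) distances appear in both compared groups, which makes the test
  conservative for adjacent pairs.
- The paper's literal p-values are not reproducible without the real
  expression resource; only procedures and operating characteristics are
  tested.
- The JackStraw component test uses a pooled-null binomial enrichment
  test; with very few genes its resolution is coarse (hence the
  small-subset override).
- Liftover, live annotation queries and desert/sweep *detection* are out
  of scope: coordinates are inputs.
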