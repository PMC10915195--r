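# ssgwas

Single-step GBLUP SNP-window association and pathway enrichment for
repeated multi-trait records.

`ssgwas` is aimed at quantitative geneticists analysing traits recorded
repeatedly on the same animals — the motivating case is semen volume (VOL),
sperm number (NS) and motility (MOT) of dairy bulls — where only part of
the population is genotyped. It implements the full analysis chain as
tested, composable R functions:

* **Relationships**: pedigree `A` (tabular method), genomic
  `G22 = ZZ'/2Σp(1−p)` with allele-2 centring, mean-matching *scaling*
  against `A22` and *blending* `G* = 0.95 G + 0.05 A22`, and the single-step
  matrix `H⁻¹ = A⁻¹ + [0 0; 0 G*⁻¹ − A22⁻¹]`.
* **Variance components**: a 3-trait genomic-polygenic repeatability model
  `y = Xb + Z_a a + Z_p p + e` with `Var(a) = H ⊗ V_a`, fitted by EM-REML
  with safeguarded average-information acceleration.
* **Window GWAS post-processing**: SNP effects back-solved as
  `u = Z'G*⁻¹â/s`, per-SNP variances, and overlapping / non-overlapping
  windows of 1, 10, 30, 50 and 100 SNPs with per-size selection thresholds
  (0.001%, 0.01%, 0.03%, 0.05%, 0.1% of the additive variance).
* **Biology**: nearest-gene assignment with distance bins (inside, ≤2.5 kb,
  2.5–5 kb, 5–25 kb, >25 kb), two-sided hypergeometric pathway enrichment
  with step-down (Holm) correction, and pairwise comparison of window
  schemes by shared significant pathways (NP) and genes (NG).
* **Synthetic data**: pedigrees, gene-drop genotypes, planted QTL and
  repeated correlated records with the exact structure the model assumes,
  so everything is testable offline.

All tabular inputs and outputs are tibbles; results chain with the pipe,
fitted objects have `tidy()`/`glance()` methods and `autoplot()` figures.

## A worked example

Simulate a small population, run the whole pipeline, and look at the
results (all numbers below are what this code prints):

```r
library(ssgwas)
library(dplyr)

spec <- sim_spec(n_sires = 15, n_dams = 45, n_bulls = 80,
                 records_per_bull = 8, n_genotyped_bulls = 60,
                 n_genotyped_dams = 8, n_chromosomes = 3,
                 markers_per_chromosome = 100, seed = 42)
ped      <- simulate_pedigree(spec)
geno_all <- simulate_genotypes(spec, ped)
ann      <- simulate_annotation(geno_all$map, seed = 42)
pw       <- simulate_pathways(ann$gene_id, n_pathways = 40, seed = 42)

cfg <- run_config(window_sizes = c(1, 10, 30), seed = 42,
                  reml_max_iter = 30, reml_tol = 1e-6)
run <- run_pipeline(cfg, spec, annotation = ann, pathways = pw)
run
#> <ssgwas_run> 6 schemes, 294 markers after QC
#> <ssgwas_reml> converged after 11 iterations (logL -663.8156)
#> heritabilities: vol 0.160, ns 0.224, mot 0.341

heritability(run$fit)
#> # A tibble: 3 × 6
#>   trait sigma_a2 sigma_p2 sigma_e2    h2 repeatability
#>   <chr>    <dbl>    <dbl>    <dbl> <dbl>         <dbl>
#> 1 vol      0.163    0.340    0.515 0.160         0.495
#> 2 ns       0.299    0.551    0.484 0.224         0.637
#> 3 mot      0.402    0.272    0.505 0.341         0.571
```

`heritability()` reports each trait's variance components: the simulation
was generated at h² = 0.3 and repeatability 0.5, and the REML estimates
scatter around those values as expected at 80 bulls. Each of the six
(size × mode) schemes carries its window-variance table, selected SNPs,
gene assignments and enrichment results, e.g. the distance-bin table in
the classic layout:

```r
run$bin_counts |> filter(scheme == "sw10_overlapping")
#> # A tibble: 6 × 4
#>   scheme           bin             n_snp n_gene
#>   <chr>            <chr>           <int>  <int>
#> 1 sw10_overlapping inside            100     76
#> 2 sw10_overlapping d1_within_2500     16     16
#> 3 sw10_overlapping d2_2500_5000       22     21
#> 4 sw10_overlapping d3_5000_25000     135     91
#> 5 sw10_overlapping d4_beyond_25000    21     16
#> 6 sw10_overlapping total             294    120
```

`autoplot(run$schemes$sw10_overlapping$window_variance)` draws the
Manhattan-style window plot; `autoplot(run$comparison)` the NP heatmap;
`autoplot(run$fit)` the likelihood trace.

The designed simulation studies are packaged too. Planting a five-marker
QTL region and checking that it tops every window scheme:

```r
qtl <- experiment_planted_qtl(n_reps = 2, seed = 1)
all(qtl$top_contains_qtl)
#> [1] TRUE
```

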