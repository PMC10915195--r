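---
title: "Single-step GBLUP window GWAS: models, choices and limits"
author: "ssgwas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step GBLUP window GWAS: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Semen-production traits of dairy bulls — ejaculate volume, sperm number and
motility — are recorded repeatedly on the same animals, are genetically
correlated, and are influenced by both a polygenic background and
individual regions of larger effect. When only a subset of the animals is
genotyped, single-step genomic BLUP (ssGBLUP) combines the pedigree and the
marker panel in one relationship matrix so that every animal, genotyped or
not, contributes to the analysis. `ssgwas` implements the full chain from
raw tables to pathway-level biology:

1. relationship matrices (pedigree **A**, genomic **G**, combined **H**);
2. multi-trait repeatability-model REML for the variance components;
3. back-solution of genomic breeding values into per-SNP variances;
4. aggregation into overlapping and non-overlapping SNP windows of several
   sizes, with per-size selection thresholds;
5. SNP-to-gene assignment by distance bins, hypergeometric pathway
   enrichment with step-down correction, and a pairwise comparison of
   window schemes by shared pathways and genes.

A synthetic-data module generates pedigrees, gene-drop genotypes, and
repeated three-trait records with exactly the statistical structure the
model assumes, so the entire pipeline is testable without access to any
proprietary data.

## The model

For trait vector records $y$ of repeated measurements,

$$y = Xb + Z_a a + Z_p p + e,$$

with fixed effects $b$ (contemporary group = year-month of collection,
ejaculate order, bull age in months, ambient temperature in °C, and the
heterosis regression on expected breed heterozygosity), additive genetic
effects $a \sim N(0, H \otimes V_a)$, permanent-environment effects
$p \sim N(0, I \otimes V_p)$ and residuals with per-record covariance
$V_e$ (restricted to the observed traits of that record). $V_a$, $V_p$ and
$V_e$ are unstructured 3×3 matrices.

The heterozygosity covariate is
$f_H(\text{sire})\,f_O(\text{dam}) + f_O(\text{sire})\,f_H(\text{dam})$
with $f_O = 1 - f_H$: the expected fraction of loci carrying one Holstein
and one other-breed allele.

### Relationship matrices

**A** is Wright's numerator relationship matrix from the tabular method
(`build_A()`), so `diag(A) = 1 + F`. The genomic matrix among genotyped
animals is

$$G_{22} = \frac{ZZ'}{2\sum_j p_j (1-p_j)},$$

where $p_j$ is the frequency of allele 2 at marker $j$ among the genotyped
animals (the default; a base-population frequency vector can be supplied)
and $Z$ holds codes centred by $2p_j$. With observed frequencies the
centred columns sum to zero, so raw $G_{22}$ is always singular; it is
first *scaled* (a two-parameter linear map matching its mean diagonal and
mean off-diagonal to those of $A_{22}$) and then *blended*,
$G^* = \alpha\,G_{\text{scaled}} + \beta A_{22}$ with defaults
$\alpha = 0.95$, $\beta = 0.05$ (weights $\tau = \omega = 1$; $\gamma$ and
$\delta$ are accepted but inert). Scaling precedes blending, matching the
documented default sequence of the standard pre-processing tools. The
combined inverse is

$$H^{-1} = A^{-1} + \begin{pmatrix}0&0\\0&\tau G^{*-1} - \omega
A_{22}^{-1}\end{pmatrix},$$

and the dense four-block $H$ is also exposed (`build_H_dense()`); the two
are verified to be mutual inverses in the tests.

### REML

`reml_fit()` maximises the restricted likelihood with EM steps — each one
provably non-decreasing — accelerated in two safeguarded ways:

* an **average-information (AI) Newton step**; the full step frequently
  leaves the positive-definite cone, so it is halved until the proposal is
  PD and accepted only when its likelihood is at least the EM candidate's;
* in slow tails (when AI is rejected), a **second EM step plus a
  SQUAREM-style extrapolation** along the EM trajectory, again accepted
  only on likelihood improvement.

Convergence is declared when the largest relative parameter change falls
below `tol` (default 1e-8). Per-iteration PSD projection clips negative
eigenvalues at a small positive floor so the Kronecker solves stay valid.
Starting values split the per-trait sample variance equally over the three
components. With per-trait missing records the residual EM update uses
pairwise-complete sufficient statistics; it coincides with exact EM when
records are complete, which is the setting in which the monotonicity
invariant is asserted. The AI gradient was verified against a numerical
differentiation of the likelihood, and the likelihood itself against the
direct dense-covariance formula, in the test suite.

One consequence of per-trait missingness worth knowing: a fixed-effect
level with no observed record for some trait makes that trait's design
singular. `build_design()` checks rank per trait and names the offending
columns rather than producing an unusable system.

### From breeding values to windows

Per-SNP effects are back-solved from the genotyped animals' breeding
values, $u = Z' G^{*-1}\hat a / s$ with $s = 2\sum_j p_j(1-p_j)$. The
per-SNP variance is, by default, the sample variance across genotyped
animals of the marker's genotype score $z_{\cdot j} u_j$; the textbook
$2p_j(1-p_j)u_j^2$ alternative sits behind
`snp_variances(method = "freq_formula")`. The per-SNP variance definition
is the least standardised step of this class of analyses, which is why both
forms are provided and the default is stated prominently here.

Windows are runs of $w$ consecutive markers within a chromosome
(marker-index based, not bp): overlapping windows shift by one marker,
non-overlapping by $w$ with the final partial window kept, so they
partition the panel and conserve summed variance exactly. A chromosome
with fewer than $w$ markers has no overlapping window. A window's variance
is the sum of its members' per-SNP variances and is reported as a
percentage of the trait's additive variance $\sigma^2_a$ (the REML
estimate, *not* $\sum_j v_j$). Selection takes every marker belonging to
at least one window at or above the per-size threshold (inclusive, per
"at least"): 0.001% for 1-SNP windows, 0.01% (10), 0.03% (30), 0.05% (50),
0.1% (100) by default.

A practical subtlety: back-solved per-SNP variances are strongly shrunken,
so $\sum_j v_j$ is far below $\sigma^2_a$ (about 1.5% of it at the default
simulated population shape, where ~3000 markers meet only 72 genotyped
animals). The absolute default thresholds are tied to a 76,519-marker
panel; for other panels `scaled_threshold()` reproduces the same relative
stringency, and accepts the realized summed per-SNP percentage as its
anchor so thresholds refer to what the windows can actually attain.

### Genes and pathways

Each selected SNP maps to the smallest-span gene containing it, or
otherwise to the nearest gene on its chromosome by
$\min(|bp - \text{start}|, |bp - \text{end}|)$, ties broken by gene id.
This distance convention (not the interval-gap convention of
`GenomicRanges::distanceToNearest()`, which differs by one) drives the
distance bins: inside, (0, 2500], (2500, 5000], (5000, 25000], >25000 bp,
upper edges inclusive. SNPs on chromosomes without annotation report a
missing gene and the outermost bin.

Enrichment of each scheme's gene set uses a two-sided hypergeometric test
(tail doubling capped at one; the minimum-likelihood-sum alternative is
available) against a background that we recommend taking as every
annotation gene present in the pathway database — the universe choice is
results-sensitive and is therefore an explicit argument. Multiplicity is
handled by the sequentially rejective step-down (Holm) procedure via
`stats::p.adjust()`, with significance strictly below $\alpha = 0.05$.
Pathways with no background member are skipped and do not count towards the
correction.

`compare_schemes()` builds the pairwise matrices NP (shared significant
pathways) and NG (genes in those shared pathways). How the two schemes'
gene lists combine before restricting to shared-pathway members is not
canonical; intersection is the default and union is available, and outputs
label the mode. Traits are pooled by union before enrichment by default;
per-trait runs simply call the chain per trait.

## The synthetic-data generator

`sim_spec()` defaults describe the population the package is aimed at:
62 founder sires and 112 founder dams, 131 phenotyped bulls with 100
records each, 72 genotyped animals (61 bulls, 11 dams), ten chromosomes of
300 markers, founder Holstein fractions uniform on [0.625, 1] with
offspring at the parental mean. Breeding values follow the pedigree via
recursive Mendelian sampling (so inbreeding reduces the sampling variance
correctly) plus optional planted marker-QTL with effects sized by
`qtl_effect_for_share()`. Contemporary groups are year-month labels;
bulls enter the stud in different months so CG is not a function of the
record index alone — otherwise ejaculate order and the age trend would be
aliased with the CG dummies. Trait covariances default to heritability
0.3 and repeatability 0.5 on unit phenotypic variance with moderate
positive correlations; no published estimates exist for these traits in
the source population, so these values are deliberately generic and are
*not* to be read as estimates.

What the generator does **not** emulate: linkage disequilibrium beyond
cosegregation within families (markers are unlinked), selection and
assortative mating, genotyping error, and X-specific inheritance (the X is
simulated as an autosome, matching how the QC treats it). Passing tests
therefore demonstrate correctness of the machinery under the model's own
assumptions, not robustness to LD structure or selection in real data.

## Simulation experiments

Two designed studies double as the package's strongest end-to-end checks
(both are re-run by `scripts/acceptance.R`):

* **Planted-region recovery** (`experiment_planted_qtl()`): a five-marker
  region mid-chromosome 2 is given designed variance shares
  (7.5/7.5/25/7.5/7.5% of each trait's total additive variance) and the
  top-ranked window of every size and mode must contain it. The
  population — 300 genotyped bulls on a 330-marker panel, ten records —
  is sized so the back-solution can resolve the region: when markers far
  outnumber genotyped animals, $u = Z'G^{*-1}\hat a/s$ spreads any
  single-marker signal so thinly that rank-one recovery is impossible no
  matter how large the simulated effect. That dilution is a property of
  the method worth knowing before interpreting real window rankings.
* **Scheme trend** (`experiment_scheme_trend()`): six causal genes shared
  by all three traits, focal pathways drawn from the ±9-marker halo of the
  QTLs, and 300 off-panel decoy genes keeping the hypergeometric test away
  from saturation. Overlapping windows extend selection roughly $w-1$
  markers to both sides of a strong region while aligned blocks reach only
  part of that halo, so overlapping schemes recover more halo genes and at
  least as many significant pathways — the mechanism the comparison
  matrices quantify. With a small gene universe the effect inverts
  (saturated selections destroy significance), which is why the universe
  construction matters and is documented here.

## Numerical choices and degenerate inputs

* Exact ties at the QC thresholds are kept (strict `<` comparisons).
* Markers still missing after QC are mean-imputed ($2p_j$).
* Chromosome labels sort naturally (1, 2, ..., 10, not 1, 10, 2).
* BED input is 0-based half-open, GFF3 1-based inclusive; everything
  internal is 1-based inclusive.
* Monomorphic-only panels, empty marker maps, empty gene selections,
  cycles in pedigrees, and confounded fixed effects are all fatal with
  named offenders rather than silent propagation.
* All randomness flows from one seed; per-stage child seeds are fixed
  functions of it, so stage-level reruns and full reruns are
  byte-reproducible (`run_pipeline()` writes a manifest with the config
  and input checksums).

## Problem sizes used in the checks

The automated checks run the REML recovery study at 400 bulls × 5 records
× 10 replicates, the recovery and trend experiments at 300 genotyped bulls
× 330 markers × 10 replicates, and the pipeline demonstration at the full
default population shape (13,100 records, ~2,900 post-QC markers). These
sizes were chosen so each study estimates its quantity with useful
precision while a complete run stays comfortable on a single CPU.

## Known limitations

* The repeatability model assumes homogeneous residual covariance across
  contemporary groups and no dominance or maternal effects.
* EM/AI-REML near a variance boundary converges slowly; the fitter warns
  when `max_iter` is reached. Estimates at an interior optimum are
  unaffected.
* The per-SNP variance definition, the enrichment universe, and the NG
  combination rule are all analysis choices with no single canonical
  answer; each is an explicit argument with its default stated above.
* Window percentages inherit the back-solution's shrinkage; comparing
  percentages across panels of different density requires the scaled
  thresholds, not the absolute defaults.
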