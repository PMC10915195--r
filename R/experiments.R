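#' Selection threshold scaled to the marker panel
#'
#' The per-size selection thresholds of the standard configuration
#' (0.001% for 1-SNP windows up to 0.1% for 100-SNP windows) sit at about
#' 0.765 times the average window share of the additive variance on the
#' 76,519-marker panel they were defined for (a w-SNP window's average
#' share is w / M x the summed per-SNP percentage). For a different panel
#' this helper reproduces the same relative stringency:
#' threshold(w) = 0.765 x w x total_pct / M. Because the back-solved
#' per-SNP variances are shrunken, their sum over markers is well below
#' sigma_a2; passing the realized `total_pct` (e.g.
#' `sum(v_j)/sigma_a2 x 100`, averaged over traits) anchors the threshold
#' to what the windows can actually reach.
#'
#' @param w Window size in SNPs.
#' @param n_markers Total marker count M of the panel.
#' @param total_pct Summed per-SNP percentage of the additive variance
#'   (default 100, i.e. a nominal unshrunken panel).
#' @param stringency Multiple of the average window share a window must
#'   reach (default 0.765, the standard configuration's ratio; 1 selects
#'   windows above the average window).
#' @return Threshold in percent of the additive genetic variance.
#' @export
scaled_threshold <- function(w, n_markers, total_pct = 100,
                             stringency = 0.765) {
  stringency * w * total_pct / n_markers
}

#' Planted-QTL window-recovery experiment
#'
#' Repeatedly simulates a genotyped bull population carrying one
#' large-effect QTL region (five consecutive markers mid-chromosome 2 whose
#' designed variance shares sum to `sum(shares)` of each trait's total
#' additive variance, with most of it on the centre marker), runs the
#' single-step pipeline with the generator's true variance components (the
#' mixed-model solve, SNP back-solution and window aggregation), and
#' records, for every window size and overlap mode, whether the top-ranked
#' window (largest percentage of additive variance) contains a region
#' marker for every trait.
#'
#' The population is sized so the back-solution can actually resolve the
#' region: 300 genotyped bulls on a 330-marker panel with 10 records each.
#' With many more markers than genotyped animals the back-solution spreads
#' any single-marker signal too thinly for rank-one recovery, which is a
#' property of the method, not of the simulation.
#'
#' @param n_reps Number of seeded replicates.
#' @param seed Base seed.
#' @param shares Designed per-marker variance shares of the five region
#'   markers (fractions of the total additive variance per trait).
#' @param sizes Window sizes to score.
#' @param modes Overlap modes to score.
#' @return A tibble: `rep`, `w`, `mode`, `top_contains_qtl` (logical, all
#'   traits), plus attributes `per_trait` (trait-level detail) and
#'   `realized_share` (the back-solved percentage of sigma_a2 attributed to
#'   the region, per rep and trait).
#' @export
experiment_planted_qtl <- function(n_reps = 10, seed = 1,
                                   shares = c(0.075, 0.075, 0.25,
                                              0.075, 0.075),
                                   sizes = c(1, 10, 30, 50, 100),
                                   modes = c("overlapping",
                                             "non_overlapping")) {
  per_trait <- list()
  realized <- list()
  out <- list()
  for (r in seq_len(n_reps)) {
    rep_seed <- child_seed(seed, 100 + r)
    spec <- sim_spec(n_sires = 60, n_dams = 150, n_bulls = 300,
                     records_per_bull = 10, n_genotyped_bulls = 300,
                     n_genotyped_dams = 0, n_chromosomes = 3,
                     markers_per_chromosome = 110,
                     Va = default_trait_cov(0.3, 0.3),
                     Vp = default_trait_cov(0.2, 0.2),
                     Ve = default_trait_cov(0.5, 0.1), seed = rep_seed)
    ped <- simulate_pedigree(spec)
    geno_all <- simulate_genotypes(spec, ped)
    region_idx <- 53:57
    region_markers <- geno_all$map$marker[geno_all$map$chrom == "2"][region_idx]
    spec$qtl <- bind_rows(purrr::map(seq_along(region_idx), function(i) {
      beta <- vapply(diag(spec$Va), function(v)
        qtl_effect_for_share(geno_all, region_markers[i], shares[i], v),
        numeric(1))
      tibble(chrom = "2", marker_index = region_idx[i],
             eff_vol = beta[1], eff_ns = beta[2], eff_mot = beta[3])
    }))
    sim <- simulate_phenotypes(spec, ped, geno_all)
    geno <- geno_all
    geno$codes <- geno_all$codes[head(sim$truth$bulls,
                                      spec$n_genotyped_bulls), , drop = FALSE]
    geno <- qc_filter(geno)
    relset <- build_relationships(ped, geno)
    design <- build_design(sim$phenotypes, animals = rownames(relset$A),
                           traits = spec$traits)
    ## true components: the genomic model sees polygenic + QTL variance
    va_tot <- spec$Va / (1 - sum(shares))
    sol <- solve_mme(design, relset$H_inv,
                     list(Va = va_tot, Vp = spec$Vp, Ve = spec$Ve))
    sigma_a2 <- setNames(diag(va_tot), spec$traits)
    snp_tab <- snp_effect_table(sol, relset, sigma_a2, geno)
    realized[[r]] <- snp_tab |>
      filter(.data$marker %in% region_markers) |>
      group_by(.data$trait) |>
      summarise(region_pct = sum(.data$pct_sigma_a2), .groups = "drop") |>
      mutate(rep = r)
    for (w in sizes) for (mode in modes) {
      windows <- build_windows(geno$map, w, mode)
      wvt <- aggregate_windows(windows, snp_tab, sigma_a2)
      members <- ssgwas_window_members(windows, geno$map)
      hits <- vapply(spec$traits, function(tr) {
        sub <- wvt[wvt$trait == tr, ]
        top <- sub$window_id[which.max(sub$pct)]
        any(region_markers %in% members$marker[members$window_id == top])
      }, logical(1))
      per_trait[[length(per_trait) + 1]] <-
        tibble(rep = r, w = w, mode = mode, trait = spec$traits,
               hit = unname(hits))
      out[[length(out) + 1]] <- tibble(rep = r, w = w, mode = mode,
                                       top_contains_qtl = all(hits))
    }
  }
  res <- bind_rows(out)
  attr(res, "per_trait") <- bind_rows(per_trait)
  attr(res, "realized_share") <- bind_rows(realized)
  res
}

# exported-name-free accessor used by experiments (window membership)
ssgwas_window_members <- function(windows, map) window_members(windows, map)

#' Overlapping-vs-non-overlapping shared-pathway trend experiment
#'
#' Simulates populations where causal genes shared across the three traits
#' (each containing a QTL affecting all traits) sit in gene-dense
#' neighbourhoods, maps selected SNPs to a synthetic annotation, tests
#' pathway enrichment for every window scheme, and compares the number of
#' significant pathways found by overlapping versus non-overlapping windows
#' of each size. Focal pathways are drawn from the QTL neighbourhoods:
#' overlapping windows extend selection roughly w - 1 markers to either
#' side of a strong region (any window containing it passes), while
#' non-overlapping windows cover only the aligned block, so the overlapping
#' schemes recover more neighbourhood genes — the mechanism behind the
#' trend this experiment scores. Selection thresholds use
#' [scaled_threshold()] anchored to the realized summed per-SNP variance.
#'
#' @param n_reps Number of seeded replicates.
#' @param seed Base seed.
#' @param sizes Window sizes.
#' @return A tibble: `rep`, `w`, `np_overlapping`, `np_non_overlapping`,
#'   `overlap_ge` (logical).
#' @export
experiment_scheme_trend <- function(n_reps = 10, seed = 1,
                                    sizes = c(1, 10, 30, 50, 100)) {
  out <- list()
  qtl_share_each <- 0.09
  n_qtl_per_chrom <- 2
  for (r in seq_len(n_reps)) {
    rep_seed <- child_seed(seed, 200 + r)
    spec <- sim_spec(n_sires = 60, n_dams = 150, n_bulls = 300,
                     records_per_bull = 10, n_genotyped_bulls = 300,
                     n_genotyped_dams = 0, n_chromosomes = 3,
                     markers_per_chromosome = 110,
                     Va = default_trait_cov(0.3, 0.3),
                     Vp = default_trait_cov(0.2, 0.2),
                     Ve = default_trait_cov(0.5, 0.1), seed = rep_seed)
    ped <- simulate_pedigree(spec)
    geno_all <- simulate_genotypes(spec, ped)
    ann <- simulate_annotation(geno_all$map, genes_per_chrom = 60,
                               length_range = c(4e3, 2e4), seed = rep_seed)
    ## decoy genes on an unmarked chromosome: part of the gene universe but
    ## never reachable by the panel (like genome genes outside chip
    ## coverage); they keep the selection fraction of the background small
    set.seed(child_seed(rep_seed, 7))
    decoys <- tibble(gene_id = sprintf("gene_off_%03d", 1:300),
                     chrom = "Z", start_bp = seq(1e4, by = 5e4,
                                                 length.out = 300),
                     end_bp = seq(1e4, by = 5e4, length.out = 300) + 2e4,
                     strand = "+")
    decoys$start_bp <- as.integer(decoys$start_bp)
    decoys$end_bp <- as.integer(decoys$end_bp)
    ann_all <- bind_rows(ann, decoys)
    ## two causal markers per chromosome, inside genes where possible
    nearest <- assign_nearest_gene(geno_all$map, ann)
    qtl_pick <- bind_rows(purrr::map(unique(geno_all$map$chrom), function(cc) {
      sub <- nearest[nearest$chrom == cc, ]
      anchors <- round(nrow(sub) * c(0.3, 0.7))
      bind_rows(purrr::map(anchors, function(a) {
        cand <- sub[order(abs(seq_len(nrow(sub)) - a)), ]
        cand <- cand[cand$bin == "inside", ]
        cand[1, ]
      }))
    }))
    ## focal pathways: genes in the +-9-marker halo of the QTLs — the band
    ## overlapping windows (w >= 10) cover on both sides, while aligned
    ## non-overlapping blocks reach only part of it
    halo_genes <- unique(unlist(purrr::map(seq_len(nrow(qtl_pick)), function(i) {
      sub <- nearest[nearest$chrom == qtl_pick$chrom[i], ]
      at <- match(qtl_pick$marker[i], sub$marker)
      win <- sub[max(1, at - 9):min(nrow(sub), at + 9), ]
      unique(win$gene_id[!is.na(win$gene_id)])
    })))
    nulls <- simulate_pathways(ann_all$gene_id, n_pathways = 57,
                               size_range = c(8, 20), seed = rep_seed)
    focal <- bind_rows(purrr::map(1:3, function(i) {
      genes <- unique(c(sample(halo_genes,
                               min(14, max(2, length(halo_genes) - 2))),
                        sample(decoys$gene_id, 3)))
      tibble(pathway = sprintf("focal%02d", i),
             name = sprintf("focal neighbourhood pathway %02d", i),
             gene = genes)
    }))
    pw <- bind_rows(focal, nulls)
    idx_within <- vapply(seq_len(nrow(qtl_pick)), function(i)
      match(qtl_pick$marker[i],
            geno_all$map$marker[geno_all$map$chrom == qtl_pick$chrom[i]]),
      integer(1))
    beta <- purrr::map(qtl_pick$marker, function(mk)
      vapply(diag(spec$Va), function(v)
        qtl_effect_for_share(geno_all, mk, qtl_share_each, v), numeric(1)))
    spec$qtl <- tibble(chrom = qtl_pick$chrom, marker_index = idx_within,
                       eff_vol = vapply(beta, `[`, numeric(1), 1),
                       eff_ns = vapply(beta, `[`, numeric(1), 2),
                       eff_mot = vapply(beta, `[`, numeric(1), 3))
    total_share <- qtl_share_each * nrow(qtl_pick)
    sim <- simulate_phenotypes(spec, ped, geno_all)
    geno <- geno_all
    geno$codes <- geno_all$codes[head(sim$truth$bulls,
                                      spec$n_genotyped_bulls), , drop = FALSE]
    geno <- qc_filter(geno)
    relset <- build_relationships(ped, geno)
    design <- build_design(sim$phenotypes, animals = rownames(relset$A),
                           traits = spec$traits)
    va_tot <- spec$Va / (1 - total_share)
    sol <- solve_mme(design, relset$H_inv,
                     list(Va = va_tot, Vp = spec$Vp, Ve = spec$Ve))
    sigma_a2 <- setNames(diag(va_tot), spec$traits)
    snp_tab <- snp_effect_table(sol, relset, sigma_a2, geno)
    total_pct <- snp_tab |>
      group_by(.data$trait) |>
      summarise(tot = sum(.data$pct_sigma_a2), .groups = "drop")
    total_pct <- mean(total_pct$tot)
    background <- intersect(unique(ann_all$gene_id), unique(pw$gene))
    M <- nrow(geno$map)
    np <- list()
    for (w in sizes) for (mode in c("overlapping", "non_overlapping")) {
      windows <- build_windows(geno$map, w, mode)
      wvt <- aggregate_windows(windows, snp_tab, sigma_a2)
      sel <- select_snps(wvt, windows, geno$map,
                         threshold_pct = scaled_threshold(w, M, total_pct, stringency = 1))
      assigned <- assign_nearest_gene(sel, ann)
      genes <- unique(assigned$gene_id[!is.na(assigned$gene_id)])
      enr <- enrich_pathways(genes, pw, background)
      np[[paste(w, mode)]] <- sum(enr$significant)
    }
    for (w in sizes)
      out[[length(out) + 1]] <- tibble(
        rep = r, w = w,
        np_overlapping = np[[paste(w, "overlapping")]],
        np_non_overlapping = np[[paste(w, "non_overlapping")]],
        overlap_ge = np[[paste(w, "overlapping")]] >=
          np[[paste(w, "non_overlapping")]])
  }
  bind_rows(out)
}
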