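#' Simulation specification
#'
#' Describes the synthetic population the generator emulates: a multibreed
#' dairy pedigree whose phenotyped bulls carry repeated records for three
#' correlated semen traits (volume, number of sperm, motility) under the
#' repeatability model with contemporary-group, ejaculate-order, age,
#' temperature and heterozygosity fixed effects. Defaults mirror the study
#' population shape: 62 founder sires and 112 founder dams, 131 phenotyped
#' bulls with 100 records each, 72 genotyped animals (61 bulls + 11 dams),
#' several thousand markers, Holstein fractions in \\[0.625, 1\\].
#'
#' Trait covariance defaults use moderate heritability (0.3) and
#' repeatability (0.5) on a unit phenotypic variance; the study does not
#' report its estimated components, so these are deliberately generic.
#'
#' @param n_sires,n_dams Founder counts.
#' @param n_bulls Phenotyped bulls (final-generation males).
#' @param n_generations Number of offspring generations (0 = founders only;
#'   the last generation holds the phenotyped bulls).
#' @param records_per_bull Repeated records per bull.
#' @param n_genotyped_bulls,n_genotyped_dams Genotyped subset sizes.
#' @param n_chromosomes,markers_per_chromosome Genome shape.
#' @param maf_range Founder allele-2 frequency range (uniform draw).
#' @param Va,Vp,Ve 3x3 additive, permanent-environment and residual
#'   covariance matrices (PSD).
#' @param fixed_effect_magnitudes Named numeric vector with elements `cg`,
#'   `ejaculate`, `age`, `temp`, `het`: standard deviations (levels) or
#'   slopes (covariates) of the simulated fixed effects.
#' @param qtl Optional tibble with columns `chrom`, `marker_index` and one
#'   effect column per trait (`eff_<trait>`), the per-copy allele effects of
#'   planted QTL.
#' @param holstein_range Holstein-fraction range for founders.
#' @param missing_rate Per-trait probability that a record's trait value is
#'   missing (records never lose all traits).
#' @param traits Trait names.
#' @param seed Integer seed driving all stages.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_sires = 62, n_dams = 112, n_bulls = 131,
                     n_generations = 1, records_per_bull = 100,
                     n_genotyped_bulls = 61, n_genotyped_dams = 11,
                     n_chromosomes = 10, markers_per_chromosome = 300,
                     maf_range = c(0.05, 0.5),
                     Va = default_trait_cov(0.3, 0.30),
                     Vp = default_trait_cov(0.2, 0.20),
                     Ve = default_trait_cov(0.5, 0.10),
                     fixed_effect_magnitudes = c(cg = 0.3, ejaculate = 0.2,
                                                 age = 0.01, temp = 0.02,
                                                 het = 0.3),
                     qtl = NULL,
                     holstein_range = c(0.625, 1.0),
                     missing_rate = 0,
                     traits = c("vol", "ns", "mot"),
                     seed = 1L) {
  check_psd(Va); check_psd(Vp); check_psd(Ve)
  if (records_per_bull < 1) stop_ssgwas("records_per_bull must be >= 1")
  if (n_sires + n_dams < 2) stop_ssgwas("need at least 2 founders")
  if (n_generations >= 1 && (n_sires < 1 || n_dams < 1))
    stop_ssgwas("offspring generations need at least one sire and one dam")
  if (!is.null(qtl)) qtl <- as_tibble(qtl)
  structure(list(n_sires = n_sires, n_dams = n_dams, n_bulls = n_bulls,
                 n_generations = n_generations,
                 records_per_bull = records_per_bull,
                 n_genotyped_bulls = n_genotyped_bulls,
                 n_genotyped_dams = n_genotyped_dams,
                 n_chromosomes = n_chromosomes,
                 markers_per_chromosome = markers_per_chromosome,
                 maf_range = maf_range, Va = Va, Vp = Vp, Ve = Ve,
                 fixed_effect_magnitudes = fixed_effect_magnitudes,
                 qtl = qtl, holstein_range = holstein_range,
                 missing_rate = missing_rate, traits = traits,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Default trait covariance matrix
#'
#' Compound-symmetry 3x3 covariance: common variance `v` and correlation `r`.
#'
#' @param v Variance per trait.
#' @param r Common correlation.
#' @return A 3x3 matrix.
#' @export
default_trait_cov <- function(v, r) {
  m <- matrix(v * r, 3, 3)
  diag(m) <- v
  m
}

#' Expected breed heterozygosity of an offspring
#'
#' f_H(sire) (1 - f_H(dam)) + (1 - f_H(sire)) f_H(dam): the probability that
#' a random locus carries one Holstein and one other-breed allele given the
#' parents' expected Holstein fractions. This is the heterosis covariate of
#' the repeatability model.
#'
#' @param f_sire,f_dam Holstein fractions of sire and dam, in \\[0, 1\\]
#'   (vectorized).
#' @return Expected heterozygosity in \\[0, 1\\].
#' @export
compute_heterozygosity <- function(f_sire, f_dam) {
  if (any(f_sire < 0 | f_sire > 1 | f_dam < 0 | f_dam > 1, na.rm = TRUE))
    stop_ssgwas("breed fractions must lie in [0, 1]")
  f_sire * (1 - f_dam) + (1 - f_sire) * f_dam
}

#' Simulate a pedigree with breed composition
#'
#' Founders (unknown parents) receive Holstein fractions drawn uniformly in
#' `holstein_range`; each offspring's fraction is the mean of its parents'.
#' Intermediate generations are of mixed sex; the final generation consists
#' of the `n_bulls` phenotyped males.
#'
#' @param spec A [sim_spec()].
#' @return A pedigree tibble (`animal`, `sire`, `dam`, `sex`, `generation`,
#'   `holstein`, `other`), topologically ordered.
#' @export
simulate_pedigree <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(child_seed(spec$seed, 1))
  f_s <- runif(spec$n_sires, spec$holstein_range[1], spec$holstein_range[2])
  f_d <- runif(spec$n_dams, spec$holstein_range[1], spec$holstein_range[2])
  ped <- tibble(
    animal = c(sprintf("S%03d", seq_len(spec$n_sires)),
               sprintf("D%03d", seq_len(spec$n_dams))),
    sire = NA_character_, dam = NA_character_,
    sex = rep(c("M", "F"), c(spec$n_sires, spec$n_dams)),
    generation = 0L, holstein = c(f_s, f_d))
  if (spec$n_generations >= 1) {
    for (g in seq_len(spec$n_generations)) {
      last <- g == spec$n_generations
      n_off <- spec$n_bulls
      males <- ped$animal[ped$sex == "M"]
      females <- ped$animal[ped$sex == "F"]
      sire <- sample(males, n_off, replace = TRUE)
      dam <- sample(females, n_off, replace = TRUE)
      off <- tibble(
        animal = sprintf("G%d_%03d", g, seq_len(n_off)),
        sire = sire, dam = dam,
        sex = if (last) "M" else sample(c("M", "F"), n_off, replace = TRUE),
        generation = g,
        holstein = (ped$holstein[match(sire, ped$animal)] +
                    ped$holstein[match(dam, ped$animal)]) / 2)
      ped <- bind_rows(ped, off)
    }
  }
  ped$other <- 1 - ped$holstein
  validate_pedigree(ped)
}

#' Simulate genotypes by Mendelian gene drop
#'
#' Founder alleles are drawn per marker with an allele-2 frequency sampled
#' uniformly from `maf_range`; every non-founder inherits one allele per
#' parent, independently across markers (no linkage). Marker positions are
#' strictly increasing within each chromosome.
#'
#' @param spec A [sim_spec()].
#' @param ped Pedigree tibble (topologically ordered).
#' @return A [geno_mat()] covering every pedigree animal, with the founder
#'   allele-2 frequencies in attribute `founder_freq`.
#' @export
simulate_genotypes <- function(spec, ped) {
  stopifnot(inherits(spec, "sim_spec"))
  ped <- validate_pedigree(ped)
  set.seed(child_seed(spec$seed, 2))
  n <- nrow(ped)
  m_per <- spec$markers_per_chromosome
  M <- spec$n_chromosomes * m_per
  p <- runif(M, spec$maf_range[1], spec$maf_range[2])
  h1 <- matrix(NA_integer_, n, M)
  h2 <- matrix(NA_integer_, n, M)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      h1[i, ] <- rbinom(M, 1, p)
    } else {
      pick <- rbinom(M, 1, 0.5)
      h1[i, ] <- ifelse(pick == 1, h1[si[i], ], h2[si[i], ])
    }
    if (is.na(di[i])) {
      h2[i, ] <- rbinom(M, 1, p)
    } else {
      pick <- rbinom(M, 1, 0.5)
      h2[i, ] <- ifelse(pick == 1, h1[di[i], ], h2[di[i], ])
    }
  }
  codes <- h1 + h2
  rownames(codes) <- ped$animal
  map <- tibble(
    marker = sprintf("snp_c%d_%04d", rep(seq_len(spec$n_chromosomes), each = m_per),
                     rep(seq_len(m_per), spec$n_chromosomes)),
    chrom = as.character(rep(seq_len(spec$n_chromosomes), each = m_per)),
    pos_bp = as.integer(unlist(lapply(seq_len(spec$n_chromosomes), function(cc) {
      cumsum(sample(1000:50000, m_per, replace = TRUE))
    }))))
  colnames(codes) <- map$marker
  out <- geno_mat(codes, map)
  attr(out, "founder_freq") <- p[match(out$map$marker, map$marker)]
  out
}

#' Size a planted QTL effect for a target variance share
#'
#' Returns the per-copy allele effect beta such that the QTL's variance
#' contribution `var(code) * beta^2` (realized code variance across the given
#' animals) accounts for fraction `share` of the total additive variance
#' `polygenic_var / (1 - share)`.
#'
#' @param geno A [geno_mat()].
#' @param marker Marker id.
#' @param share Target share of total additive variance, in (0, 1).
#' @param polygenic_var Polygenic additive variance of the trait.
#' @param animals Optional animal subset over which to take the realized code
#'   variance (default all).
#' @return The scalar effect size.
#' @export
qtl_effect_for_share <- function(geno, marker, share, polygenic_var,
                                 animals = NULL) {
  stopifnot(share > 0, share < 1)
  codes <- geno$codes[, marker]
  if (!is.null(animals)) codes <- codes[animals]
  v <- var(codes)
  if (v <= 0) stop_ssgwas("marker is monomorphic in the chosen animals")
  sqrt(share / (1 - share) * polygenic_var / v)
}

#' Simulate repeated multi-trait phenotype records
#'
#' Breeding values follow the pedigree (MVN with covariance A (x) Va via the
#' recursive Mendelian-sampling decomposition) plus any planted marker-QTL
#' contributions; permanent-environment effects are i.i.d. MVN(Vp) per bull;
#' residuals i.i.d. MVN(Ve) per record. Fixed effects: contemporary-group
#' (records cycle over simulated year-month labels, effects drawn once per
#' level), ejaculate order (alternating 1/2), bull age in months (increasing
#' over records), a seasonal ambient temperature, and the heterozygosity
#' regression from the parents' Holstein fractions.
#'
#' @param spec A [sim_spec()].
#' @param ped Pedigree tibble.
#' @param geno A [geno_mat()] covering the pedigree animals (only needed when
#'   `spec$qtl` is non-NULL).
#' @return A list with `phenotypes` (record tibble) and `truth` (breeding
#'   values, permanent-environment effects, fixed-effect coefficients, QTL
#'   table, and the variance components used).
#' @export
simulate_phenotypes <- function(spec, ped, geno = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  ped <- validate_pedigree(ped)
  set.seed(child_seed(spec$seed, 3))
  n <- nrow(ped)
  tr <- spec$traits
  nt <- length(tr)
  ## polygenic breeding values by recursive Mendelian sampling
  A <- build_A(ped)
  Fi <- diag(A) - 1
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  La <- t(chol(psd_project(spec$Va, quiet = TRUE)))
  u <- matrix(0, n, nt)
  for (i in seq_len(n)) {
    if (is.na(si[i]) && is.na(di[i])) {
      u[i, ] <- as.numeric(La %*% rnorm(nt))
    } else {
      par_mean <- numeric(nt)
      if (!is.na(si[i])) par_mean <- par_mean + 0.5 * u[si[i], ]
      if (!is.na(di[i])) par_mean <- par_mean + 0.5 * u[di[i], ]
      # Mendelian-sampling variance: 0.5 - 0.25 (F_s + F_d), +0.25 per
      # unknown parent (that parent contributes a full founder draw)
      ms <- 0.5 - 0.25 * ((if (is.na(si[i])) 0 else Fi[si[i]]) +
                          (if (is.na(di[i])) 0 else Fi[di[i]]))
      ms <- ms + (if (is.na(si[i])) 0.25 else 0) + (if (is.na(di[i])) 0.25 else 0)
      u[i, ] <- par_mean + sqrt(ms) * as.numeric(La %*% rnorm(nt))
    }
  }
  rownames(u) <- ped$animal
  ## planted QTL contributions (centered codes so means stay 0)
  qtl_truth <- NULL
  if (!is.null(spec$qtl) && nrow(spec$qtl)) {
    if (is.null(geno)) stop_ssgwas("spec has QTL but no genotypes supplied")
    eff_cols <- paste0("eff_", tr)
    if (!all(eff_cols %in% names(spec$qtl)))
      stop_ssgwas("qtl table needs columns ", paste(eff_cols, collapse = ", "))
    qtl_truth <- spec$qtl
    qtl_truth$marker <- purrr::map2_chr(
      as.character(spec$qtl$chrom), spec$qtl$marker_index,
      function(cc, ix) {
        mk <- geno$map$marker[geno$map$chrom == cc]
        if (ix < 1 || ix > length(mk))
          stop_ssgwas("QTL marker index out of range for chromosome ", cc)
        mk[ix]
      })
    zq <- geno$codes[ped$animal, qtl_truth$marker, drop = FALSE]
    zq <- sweep(zq, 2, colMeans(zq), "-")
    u <- u + zq %*% as.matrix(qtl_truth[, eff_cols])
  }
  ## permanent environment effects for recorded bulls
  bulls <- ped$animal[ped$sex == "M" & ped$generation == max(ped$generation)]
  bulls <- head(bulls, spec$n_bulls)
  if (!length(bulls)) stop_ssgwas("pedigree has no phenotyped bulls")
  Lp <- t(chol(psd_project(spec$Vp, quiet = TRUE)))
  pe <- t(Lp %*% matrix(rnorm(length(bulls) * nt), nt))
  rownames(pe) <- bulls
  ## fixed-effect structure
  nrec <- spec$records_per_bull
  fm <- spec$fixed_effect_magnitudes
  # bulls enter the stud in different months so contemporary group is not a
  # pure function of the record index (keeps ejaculate order and age
  # estimable next to the CG dummies)
  start_month <- setNames(sample(0:11, length(bulls), replace = TRUE), bulls)
  all_idx <- 0:(11 + nrec - 1)
  cg_levels <- unique(sprintf("%d-%02d", 2015 + all_idx %/% 12,
                              all_idx %% 12 + 1))
  cg_eff <- matrix(rnorm(length(cg_levels) * nt, 0, fm[["cg"]]), ncol = nt,
                   dimnames = list(cg_levels, tr))
  ej_eff <- matrix(c(rep(0, nt), rnorm(nt, 0, fm[["ejaculate"]])), 2, nt,
                   byrow = TRUE, dimnames = list(c("1", "2"), tr))
  b_age <- rnorm(nt, 0, fm[["age"]])
  b_temp <- rnorm(nt, 0, fm[["temp"]])
  b_het <- rnorm(nt, 0, fm[["het"]])
  f_par <- ped$holstein[match(ped$sire[match(bulls, ped$animal)], ped$animal)]
  m_par <- ped$holstein[match(ped$dam[match(bulls, ped$animal)], ped$animal)]
  het_bull <- compute_heterozygosity(f_par, m_par)
  names(het_bull) <- bulls
  age0 <- setNames(round(runif(length(bulls), 24, 48)), bulls)
  Le <- t(chol(psd_project(spec$Ve, quiet = TRUE)))
  rows <- purrr::map(bulls, function(b) {
    j <- seq_len(nrec)
    midx <- start_month[[b]] + j - 1
    months <- midx %% 12 + 1
    cg <- sprintf("%d-%02d", 2015 + midx %/% 12, months)
    age <- age0[[b]] + (j - 1)
    temp <- 25 + 5 * sin(2 * pi * months / 12) + rnorm(nrec, 0, 1.5)
    e <- t(Le %*% matrix(rnorm(nrec * nt), nt))
    yv <- matrix(rep(u[b, ] + pe[b, ], each = nrec), nrec) + e +
      cg_eff[cg, , drop = FALSE] +
      ej_eff[as.character(((j - 1) %% 2) + 1), , drop = FALSE] +
      outer(age, b_age) + outer(temp, b_temp) +
      outer(rep(het_bull[[b]], nrec), b_het)
    colnames(yv) <- tr
    tibble(animal = b, record = j, cg = cg,
           ejaculate = ((j - 1) %% 2) + 1, age = age, temp = temp,
           het = het_bull[[b]], as_tibble(as.data.frame(yv)))
  })
  phen <- bind_rows(rows)
  if (spec$missing_rate > 0) {
    for (t_ in tr)
      phen[[t_]][runif(nrow(phen)) < spec$missing_rate] <- NA_real_
    all_na <- rowSums(!is.na(as.matrix(phen[tr]))) == 0
    if (any(all_na))  # never lose a whole record
      phen[[tr[1]]][all_na] <- rnorm(sum(all_na))
  }
  truth <- list(bv = u, pe = pe,
                coefficients = list(cg = cg_eff, ejaculate = ej_eff,
                                    age = b_age, temp = b_temp, het = b_het),
                qtl = qtl_truth, Va = spec$Va, Vp = spec$Vp, Ve = spec$Ve,
                bulls = bulls)
  list(phenotypes = phen, truth = truth)
}

#' Simulate a gene annotation over a marker map
#'
#' Places non-overlapping genes along each chromosome of the map, with
#' lengths and intergenic gaps drawn uniformly, so that a configurable share
#' of SNPs falls inside genes and the rest at varying distances — the
#' structure the SNP-to-gene distance bins summarise.
#'
#' @param map Marker map tibble (`marker`, `chrom`, `pos_bp`).
#' @param genes_per_chrom Number of genes per chromosome.
#' @param length_range Gene length range in bp (uniform draw).
#' @param seed Integer seed.
#' @return An annotation tibble (`gene_id`, `chrom`, `start_bp`, `end_bp`,
#'   `strand`).
#' @export
simulate_annotation <- function(map, genes_per_chrom = 40,
                                length_range = c(5e3, 4e4), seed = 1L) {
  set.seed(child_seed(seed, 5))
  out <- purrr::map(unique(map$chrom), function(cc) {
    span <- range(map$pos_bp[map$chrom == cc])
    span[1] <- max(1, span[1] - 2e4)
    span[2] <- span[2] + 2e4
    n <- genes_per_chrom
    len <- round(runif(n, length_range[1], length_range[2]))
    slot <- (span[2] - span[1]) / n
    start <- round(span[1] + (seq_len(n) - 1) * slot +
                     runif(n, 0, pmax(1, slot - len)))
    end <- pmin(start + len - 1, span[1] + seq_len(n) * slot - 1)
    tibble(gene_id = sprintf("gene_c%s_%03d", cc, seq_len(n)),
           chrom = as.character(cc), start_bp = as.integer(start),
           end_bp = as.integer(pmax(end, start)),
           strand = sample(c("+", "-"), n, replace = TRUE))
  })
  bind_rows(out)
}

#' Simulate a pathway database (GMT-shaped)
#'
#' Draws random gene sets from the annotation's genes; optionally a number
#' of "focal" pathways are guaranteed to contain the supplied focal genes
#' (e.g. genes harbouring planted QTL), giving downstream enrichment a true
#' signal to find.
#'
#' @param gene_ids Character vector: the gene universe.
#' @param n_pathways Number of pathways.
#' @param size_range Pathway size range (uniform integer draw).
#' @param focal_genes Genes to plant into the first `n_focal` pathways.
#' @param n_focal How many pathways receive the focal genes.
#' @param seed Integer seed.
#' @return A long tibble (`pathway`, `name`, `gene`).
#' @export
simulate_pathways <- function(gene_ids, n_pathways = 40,
                              size_range = c(5, 25), focal_genes = NULL,
                              n_focal = 3, seed = 1L) {
  set.seed(child_seed(seed, 6))
  gene_ids <- unique(gene_ids)
  out <- purrr::map(seq_len(n_pathways), function(i) {
    sz <- sample(size_range[1]:size_range[2], 1)
    genes <- sample(gene_ids, min(sz, length(gene_ids)))
    if (!is.null(focal_genes) && i <= n_focal)
      genes <- unique(c(focal_genes, genes))
    tibble(pathway = sprintf("pw%03d", i),
           name = sprintf("synthetic pathway %03d", i), gene = genes)
  })
  bind_rows(out)
}

#' Simulate a complete analysis-ready dataset
#'
#' Runs [simulate_pedigree()], [simulate_genotypes()] and
#' [simulate_phenotypes()] and extracts the genotyped subset
#' (`n_genotyped_bulls` phenotyped bulls plus `n_genotyped_dams` dams).
#'
#' @param spec A [sim_spec()].
#' @return A list with `ped`, `geno_all` (all animals), `geno` (genotyped
#'   subset), `phenotypes`, `truth`.
#' @export
simulate_dataset <- function(spec) {
  ped <- simulate_pedigree(spec)
  geno_all <- simulate_genotypes(spec, ped)
  sim <- simulate_phenotypes(spec, ped, geno_all)
  set.seed(child_seed(spec$seed, 4))
  bulls <- sim$truth$bulls
  dams <- ped$animal[ped$sex == "F" & is.na(ped$sire)]
  g_ids <- c(head(bulls, spec$n_genotyped_bulls),
             head(sample(dams), min(spec$n_genotyped_dams, length(dams))))
  geno <- geno_all
  geno$codes <- geno_all$codes[intersect(ped$animal, g_ids), , drop = FALSE]
  list(ped = ped, geno_all = geno_all, geno = geno,
       phenotypes = sim$phenotypes, truth = sim$truth)
}
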