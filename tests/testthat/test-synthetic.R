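test_that("expected heterozygosity follows the cross-breed formula", {
  expect_equal(compute_heterozygosity(1, 0), 1)
  expect_equal(compute_heterozygosity(1, 1), 0)
  expect_equal(compute_heterozygosity(0.5, 0.5), 0.5)
  expect_equal(compute_heterozygosity(c(1, 0.625), c(0.625, 1)),
               c(0.375, 0.375))
  expect_error(compute_heterozygosity(1.2, 0.5), "\\[0, 1\\]")
})

test_that("simulated pedigrees respect founder structure and the midpoint rule", {
  spec0 <- sim_spec(n_sires = 5, n_dams = 7, n_generations = 0, seed = 3)
  ped0 <- simulate_pedigree(spec0)
  expect_equal(nrow(ped0), 12)
  expect_true(all(is.na(ped0$sire)))
  expect_true(all(ped0$holstein >= 0.625 & ped0$holstein <= 1))

  spec <- small_sim(seed = 11)
  ped <- simulate_pedigree(spec)
  off <- ped[!is.na(ped$sire), ]
  fs <- ped$holstein[match(off$sire, ped$animal)]
  fd <- ped$holstein[match(off$dam, ped$animal)]
  expect_equal(off$holstein, (fs + fd) / 2)
  ## phenotyped bulls stay inside the Holstein range
  bulls <- ped[ped$generation == max(ped$generation), ]
  expect_true(all(bulls$holstein >= 0.625 & bulls$holstein <= 1))
  ## determinism
  expect_identical(ped, simulate_pedigree(small_sim(seed = 11)))
})

test_that("gene-drop founder allele frequency matches the binomial draw", {
  spec <- sim_spec(n_sires = 150, n_dams = 150, n_generations = 0,
                   n_chromosomes = 1, markers_per_chromosome = 60,
                   maf_range = c(0.5, 0.5), seed = 7)
  ped <- simulate_pedigree(spec)
  g <- simulate_genotypes(spec, ped)
  freq <- colMeans(g$codes) / 2
  n_alleles <- 2 * nrow(g$codes)
  se <- sqrt(0.5 * 0.5 / n_alleles)
  expect_true(all(abs(freq - 0.5) < 4 * se))
  ## map positions strictly increasing within the chromosome
  expect_true(all(diff(g$map$pos_bp) > 0))
})

test_that("gene drop is Mendelian-consistent for every offspring", {
  spec <- small_sim(seed = 5)
  ped <- simulate_pedigree(spec)
  g <- simulate_genotypes(spec, ped)
  codes <- g$codes[ped$animal, ]
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  for (i in which(!is.na(si) & !is.na(di))) {
    cs <- codes[si[i], ]; cd <- codes[di[i], ]; co <- codes[i, ]
    lower <- (cs == 2) + (cd == 2)
    upper <- 2 - (cs == 0) - (cd == 0)
    expect_true(all(co >= lower & co <= upper))
  }
})

test_that("parent-offspring genotype-code correlation is about one half", {
  spec <- sim_spec(n_sires = 400, n_dams = 400, n_bulls = 400,
                   n_generations = 1, n_chromosomes = 1,
                   markers_per_chromosome = 1, maf_range = c(0.3, 0.3),
                   seed = 13)
  ped <- simulate_pedigree(spec)
  g <- simulate_genotypes(spec, ped)
  off <- ped[!is.na(ped$sire), ]
  r <- cor(g$codes[off$sire, 1], g$codes[off$animal, 1])
  expect_lt(abs(r - 0.5), 3 / sqrt(nrow(off)))
})

test_that("pure-noise phenotypes are standard normal", {
  spec <- sim_spec(n_sires = 10, n_dams = 20, n_bulls = 100,
                   records_per_bull = 100, n_chromosomes = 1,
                   markers_per_chromosome = 5,
                   Va = diag(0, 3), Vp = diag(0, 3), Ve = diag(3),
                   fixed_effect_magnitudes = c(cg = 0, ejaculate = 0,
                                               age = 0, temp = 0, het = 0),
                   seed = 21)
  ped <- simulate_pedigree(spec)
  sim <- simulate_phenotypes(spec, ped)
  y <- c(sim$phenotypes$vol, sim$phenotypes$ns, sim$phenotypes$mot)
  expect_gt(stats::ks.test(y, "pnorm")$p.value, 1e-4)
  expect_lt(abs(var(sim$phenotypes$vol) - 1), 0.05)
})

test_that("founder breeding values have the specified covariance", {
  Va <- default_trait_cov(0.4, 0.5)
  spec <- sim_spec(n_sires = 1000, n_dams = 1000, n_generations = 0,
                   n_chromosomes = 1, markers_per_chromosome = 2,
                   Va = Va, seed = 17)
  ped <- simulate_pedigree(spec)
  sim <- simulate_phenotypes(spec, ped)
  bv <- sim$truth$bv
  n <- nrow(bv)
  se_var <- sqrt(2 / n) * 0.4        # approximate SE of a sample variance
  expect_true(all(abs(apply(bv, 2, var) - 0.4) < 3 * se_var))
  expect_lt(abs(cor(bv[, 1], bv[, 2]) - 0.5), 3 / sqrt(n))
})

test_that("phenotype simulation is byte-deterministic in the seed", {
  s1 <- simulate_dataset(small_sim(seed = 99))
  s2 <- simulate_dataset(small_sim(seed = 99))
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$geno$codes, s2$geno$codes)
  s3 <- simulate_dataset(small_sim(seed = 100))
  expect_false(identical(s1$phenotypes$vol, s3$phenotypes$vol))
})

test_that("planted QTL effects are sized to the requested variance share", {
  spec <- small_sim(seed = 31)
  ped <- simulate_pedigree(spec)
  g <- simulate_genotypes(spec, ped)
  mk <- g$map$marker[10]
  beta <- qtl_effect_for_share(g, mk, share = 0.25, polygenic_var = 0.3)
  v_qtl <- var(g$codes[, mk]) * beta^2
  expect_equal(v_qtl / (v_qtl + 0.3), 0.25, tolerance = 1e-10)
})

test_that("synthetic annotation and pathways are well-formed", {
  g <- random_geno(10, 30, seed = 2)
  ann <- simulate_annotation(g$map, genes_per_chrom = 10, seed = 2)
  expect_equal(nrow(ann), 10)
  expect_true(all(ann$start_bp <= ann$end_bp))
  ## genes do not overlap within a chromosome
  expect_true(all(ann$start_bp[-1] > ann$end_bp[-nrow(ann)]))
  pw <- simulate_pathways(ann$gene_id, n_pathways = 8,
                          focal_genes = ann$gene_id[1:2], n_focal = 2,
                          seed = 2)
  expect_equal(dplyr::n_distinct(pw$pathway), 8)
  expect_true(all(table(pw$pathway) >= 1))
  expect_true(all(ann$gene_id[1:2] %in% pw$gene[pw$pathway == "pw001"]))
})
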