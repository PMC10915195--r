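test_that("pedigree reading handles founders, trios and unknown parents", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(animal = c("x", "y", "z"),
                                  sire = c("0", "0", "0"),
                                  dam = c("", "", "")), f)
  ped <- read_pedigree(f)
  expect_equal(nrow(ped), 3)
  expect_true(all(is.na(ped$sire)) && all(is.na(ped$dam)))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(animal = c("o", "s", "d"),
                                  sire = c("s", NA, NA),
                                  dam = c("d", NA, NA)), f2)
  ped2 <- read_pedigree(f2)
  expect_equal(ped2$animal, c("s", "d", "o"))  # topological order
})

test_that("pedigree cycles and bad breed fractions are fatal", {
  expect_error(validate_pedigree(tibble::tibble(
    animal = "a", sire = "a", dam = NA)), "cycle.*a")
  expect_error(validate_pedigree(tibble::tibble(
    animal = c("a", "b"), sire = c(NA, "a"), dam = c(NA, "a"),
    holstein = c(0.7, 0.8), other = c(0.2, 0.2))), "fractions")
  ok <- validate_pedigree(tibble::tibble(
    animal = c("a", "b"), sire = c(NA, "a"), dam = c(NA, NA),
    holstein = c(0.8, 0.9), other = c(0.2, 0.1)))
  expect_equal(ok$animal, c("a", "b"))
})

test_that("genotype reading enforces codes and sorts the map", {
  gm <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(animal = c("a1", "a2"),
                                  m1 = c(0, 2), m2 = c(2, 0)), gm)
  ## deliberately unsorted map (chrom 10 vs 2 exercises natural order too)
  readr::write_tsv(tibble::tibble(marker = c("m2", "m1"),
                                  chrom = c("10", "2"),
                                  pos_bp = c(50L, 100L)), mp)
  g <- read_genotypes(gm, mp)
  expect_equal(g$map$marker, c("m1", "m2"))     # chrom 2 before chrom 10
  expect_equal(colnames(g$codes), c("m1", "m2"))
  expect_equal(dim(g), c(2L, 2L))

  readr::write_tsv(tibble::tibble(animal = c("a1", "a2"),
                                  m1 = c(0, 3), m2 = c(2, 0)), gm)
  expect_error(read_genotypes(gm, mp), "a2.*m1")
})

test_that("QC removes by call rate and strict MAF, then mean-imputes", {
  set.seed(1)
  n <- 10
  codes <- cbind(lowcall = c(rep(0, 4), rep(1, 4), NA, NA),   # call rate 0.8
                 lowmaf = c(1, rep(0, 9)),                    # maf 0.05 kept
                 rare = c(rep(0, 10)),                        # maf 0 removed
                 good = rep(c(0, 1, 2), length.out = 10))
  codes[1, "good"] <- NA                                      # call rate 0.9 kept
  rownames(codes) <- sprintf("a%02d", 1:n)
  g <- geno_mat(codes, tibble::tibble(marker = colnames(codes), chrom = "1",
                                      pos_bp = c(10L, 20L, 30L, 40L)))
  out <- qc_filter(g, min_call_rate = 0.90, min_maf = 0.05)
  rep_ <- qc_report(out)
  expect_setequal(out$map$marker, c("lowmaf", "good"))
  expect_equal(rep_$reason[rep_$marker == "lowcall"], "call_rate")
  expect_equal(rep_$reason[rep_$marker == "rare"], "maf")
  expect_false(anyNA(out$codes))
  ## imputed value is the marker mean of observed codes
  expect_equal(out$codes["a01", "good"],
               mean(codes[-1, "good"]))
  ## idempotence: a clean matrix passes through unchanged
  again <- qc_filter(out, 0.90, 0.05)
  expect_equal(again$codes, out$codes)
  ## marker with MAF 0.04 strictly below threshold is removed
  codes2 <- cbind(m = c(rep(1, 2), rep(0, 23)))  # maf 0.04
  rownames(codes2) <- sprintf("b%02d", 1:25)
  g2 <- geno_mat(codes2, tibble::tibble(marker = "m", chrom = "1", pos_bp = 1L))
  expect_error(qc_filter(g2), "every marker")
})

test_that("no-op QC leaves a clean matrix untouched", {
  g <- random_geno(10, 8, seed = 3)
  out <- qc_filter(g, 0.9, 0.05)
  expect_equal(out$codes, g$codes)
  expect_false(any(qc_report(out)$removed))
})

test_that("BED is converted to 1-based inclusive and GFF3 validated", {
  skip_if_not_installed("rtracklayer")
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tgeneA\t0\t+", bed)
  ann <- read_annotation(bed)
  expect_equal(ann$chrom, "1")
  expect_equal(ann$start_bp, 1000L)
  expect_equal(ann$end_bp, 2000L)
  expect_equal(ann$gene_id, "geneA")

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t500\t400\t.\t+\t.\tID=bad"), gff)
  expect_error(read_annotation(gff), "line 2")
})

test_that("annotation BED round-trips through write_annotation_bed", {
  skip_if_not_installed("rtracklayer")
  ann <- tibble::tibble(gene_id = c("g1", "g2"), chrom = c("1", "2"),
                        start_bp = c(100L, 5000L), end_bp = c(900L, 9000L),
                        strand = c("+", "-"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_annotation_bed(ann, f)
  back <- read_annotation(f)
  expect_equal(back, ann)
})

test_that("GMT parsing keeps descriptions, rejects empty sets, round-trips", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pw1\tfirst pathway\tg1\tg2\tg3",
               "pw2\tsecond pathway\tg2"), f)
  pw <- read_gmt(f)
  expect_equal(unique(pw$pathway), c("pw1", "pw2"))
  expect_equal(pw$gene[pw$pathway == "pw1"], c("g1", "g2", "g3"))
  expect_equal(unique(pw$name[pw$pathway == "pw2"]), "second pathway")

  writeLines(c("pw1\tfirst\tg1", "pw2\tno genes here"), f)
  expect_error(read_gmt(f), "line 2")

  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(pw, f2)
  expect_equal(read_gmt(f2), pw)
})

test_that("tabular and genotype writers round-trip", {
  df <- tibble::tibble(a = c(1.5, 2.25), b = c("x", "y"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_table(df, f)
  expect_equal(read_table_tsv(f), df)

  g <- random_geno(6, 5, seed = 9)
  gm <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, gm, mp)
  back <- read_genotypes(gm, mp)
  expect_equal(back$codes, g$codes)
  expect_equal(back$map, g$map)
})

test_that("run configuration defaults, threshold checks and YAML reading", {
  cfg <- run_config()
  expect_equal(cfg$window_sizes, c(1L, 10L, 30L, 50L, 100L))
  expect_equal(unname(cfg$thresholds[c("1", "100")]), c(0.001, 0.1))
  expect_error(run_config(window_sizes = c(1, 7)), "threshold.*7")

  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("window_sizes: [1, 10]",
               "overlap_modes: [overlapping]",
               "seed: 99",
               "qc:",
               "  min_maf: 0.10",
               "reml:",
               "  max_iter: 50"), y)
  cfg2 <- read_run_config(y)
  expect_equal(cfg2$window_sizes, c(1L, 10L))
  expect_equal(cfg2$min_maf, 0.10)
  expect_equal(cfg2$seed, 99L)
  expect_equal(cfg2$reml_max_iter, 50L)
})

test_that("phenotype reading rejects records with every trait missing", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(animal = c("a", "b"), vol = c(1, NA),
                                  ns = c(2, NA), mot = c(3, NA)), f)
  expect_error(read_phenotypes(f), "all traits missing")
})
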