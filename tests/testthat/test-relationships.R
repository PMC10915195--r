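test_that("A matrix matches textbook closed forms", {
  ped <- tibble::tibble(animal = c("f1", "f2", "f3"),
                        sire = NA_character_, dam = NA_character_)
  expect_equal(build_A(ped), diag(3), ignore_attr = "dimnames")

  A <- build_A(trio_pedigree())
  expect_equal(A["o", "s"], 0.5)
  expect_equal(A["o", "d"], 0.5)
  expect_equal(A["o", "o"], 1.0)

  ## offspring of a full-sib mating: F = 0.25, a_zz = 1.25
  ped_fs <- tibble::tibble(
    animal = c("s", "d", "b1", "b2", "z"),
    sire = c(NA, NA, "s", "s", "b1"),
    dam = c(NA, NA, "d", "d", "b2"))
  expect_equal(build_A(ped_fs)["z", "z"], 1.25)
})

test_that("tabular A equals the recursive-definition oracle on random pedigrees", {
  set.seed(2024)
  for (i in 1:25) {
    ped <- random_pedigree(sample(5:25, 1))
    A_tab <- build_A(ped)[ped$animal, ped$animal]   # undo topological resort
    expect_equal(A_tab, recursive_A(ped), tolerance = 1e-12)
  }
})

test_that("G22 follows the allele-2 centering and divisor", {
  gg <- build_G22(tiny_geno())
  expect_equal(gg$p, c(m1 = 0.5, m2 = 0.5))
  expect_equal(gg$s, 1)
  expect_equal(gg$Z, matrix(c(-1, 1, 1, -1), 2, 2,
                            dimnames = dimnames(tiny_geno()$codes)))
  expect_equal(unname(gg$G), matrix(c(2, -2, -2, 2), 2))

  ## all-heterozygous marker at p = 0.5 contributes a zero column
  codes <- cbind(het = c(1, 1, 1), seg = c(0, 1, 2))
  rownames(codes) <- c("x", "y", "z")
  g <- geno_mat(codes, tibble::tibble(marker = colnames(codes), chrom = "1",
                                      pos_bp = c(1L, 2L)))
  expect_equal(unname(build_G22(g)$Z[, "het"]), c(0, 0, 0))

  ## symmetry and non-negative trace on random data
  G <- build_G22(random_geno(15, 40, seed = 4))$G
  expect_equal(G, t(G))
  expect_gte(sum(diag(G)), 0)

  mono <- geno_mat(cbind(m = c(2, 2, 2)) |> `rownames<-`(c("a", "b", "c")),
                   tibble::tibble(marker = "m", chrom = "1", pos_bp = 1L))
  expect_error(build_G22(mono), "monomorphic")
})

test_that("G22 is equivariant under animal permutation", {
  g <- random_geno(10, 25, seed = 6)
  G1 <- build_G22(g)$G
  perm <- sample(nrow(g$codes))
  g2 <- g
  g2$codes <- g$codes[perm, ]
  G2 <- build_G22(g2)$G
  expect_equal(G2, G1[perm, perm])
})

test_that("scaling matches A22 means and blending preserves the fixed point", {
  g <- random_geno(8, 30, seed = 5)
  G <- build_G22(g)$G
  set.seed(8)
  ped <- random_pedigree(8, p_unknown = 0.4)
  A22 <- build_A(ped)
  G_star <- blend_and_scale(G, A22)
  ## independent 2x2 solve for the scaling coefficients
  a <- (mean(diag(A22)) - offdiag_mean_test(A22)) /
    (mean(diag(G)) - offdiag_mean_test(G))
  b <- mean(diag(A22)) - a * mean(diag(G))
  G_scaled <- a * G + b
  expect_equal(mean(diag(G_scaled)), mean(diag(A22)), tolerance = 1e-10)
  expect_equal(offdiag_mean_test(G_scaled), offdiag_mean_test(A22),
               tolerance = 1e-10)
  expect_equal(G_star, 0.95 * G_scaled + 0.05 * A22, ignore_attr = TRUE)

  ## G == A22 is a fixed point
  expect_equal(blend_and_scale(A22, A22), A22, ignore_attr = TRUE)

  ## alpha = 1, beta = 0 with an already mean-matched G returns it unchanged
  expect_equal(blend_and_scale(G_scaled, A22,
                               blend_params(alpha = 1, beta = 0)),
               G_scaled, ignore_attr = TRUE)

  ## blending with beta > 0 gives a positive-definite G*
  ev <- eigen(G_star, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("H inverse degenerates correctly and inverts dense H", {
  set.seed(12)
  ped <- random_pedigree(12, p_unknown = 0.3)
  A <- build_A(ped)

  ## no genotyped animals: H == A
  expect_equal(build_H_dense(A, NULL, character(0)), A)
  expect_equal(build_H_inverse(A, NULL, character(0)),
               chol2inv(chol(A)), ignore_attr = TRUE, tolerance = 1e-10)

  ## all animals genotyped with G* := A22 collapses to A
  Hinv <- build_H_inverse(A, A, rownames(A))
  expect_equal(Hinv, chol2inv(chol(A)), ignore_attr = TRUE,
               tolerance = 1e-8)

  ## random case, 5 genotyped: dense H and correction-formula H^-1 are
  ## mutual inverses
  gset <- sample(rownames(A), 5)
  g <- random_geno(5, 40, seed = 12)
  rownames(g$codes) <- gset
  G_star <- blend_and_scale(build_G22(g)$G, A[gset, gset])
  H <- build_H_dense(A, G_star, gset)
  Hinv2 <- build_H_inverse(A, G_star, gset)
  expect_equal(H %*% Hinv2, diag(nrow(A)), ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("build_relationships wires the pieces together", {
  dat <- simulate_dataset(small_sim(seed = 77))
  geno <- qc_filter(dat$geno)
  rel <- build_relationships(dat$ped, geno)
  expect_s3_class(rel, "relationship_set")
  expect_equal(rownames(rel$A), dat$ped$animal)
  expect_equal(length(rel$genotyped), nrow(geno$codes))
  expect_equal(rel$H %*% rel$H_inv, diag(nrow(rel$A)),
               ignore_attr = TRUE, tolerance = 1e-6)
  ## genotyped block of H is exactly G*
  expect_equal(rel$H[rel$genotyped, rel$genotyped], rel$G_star,
               ignore_attr = TRUE)
})
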