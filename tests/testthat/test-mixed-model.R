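make_phen <- function(n_bulls = 4, n_rec = 3, traits = c("vol", "ns", "mot"),
                      cg_levels = 2, seed = 1) {
  set.seed(seed)
  bulls <- sprintf("b%02d", seq_len(n_bulls))
  out <- tidyr::expand_grid(animal = bulls, record = seq_len(n_rec))
  out$cg <- sprintf("cg%d", ((seq_len(nrow(out)) - 1) %% cg_levels) + 1)
  out$ejaculate <- rep_len(1:2, nrow(out))
  out$age <- 24 + out$record + round(runif(nrow(out)), 2)
  out$temp <- round(25 + rnorm(nrow(out)), 2)
  out$het <- rep(round(runif(n_bulls), 2), each = n_rec)
  for (tr in traits) out[[tr]] <- round(rnorm(nrow(out)), 3)
  out
}

test_that("design expansion: reference coding, single-level collapse, Za map", {
  phen <- make_phen(n_bulls = 1, n_rec = 2, cg_levels = 1)
  des <- build_design(phen, animals = "b01", fixed = "cg")
  expect_equal(colnames(des$X0), "(Intercept)")
  expect_equal(nrow(des$obs), 6)           # 2 records x 3 traits
  expect_equal(unique(des$record_animal), "b01")

  phen2 <- make_phen(n_bulls = 2, n_rec = 2, cg_levels = 2)
  des2 <- build_design(phen2, animals = c("b01", "b02"), fixed = "cg")
  expect_equal(ncol(des2$X0), 2)           # intercept + one CG dummy
})

test_that("aliased fixed-effect columns are fatal and named", {
  phen <- make_phen(n_bulls = 3, n_rec = 3)
  phen$age2 <- phen$age                    # exact copy => aliased
  expect_error(
    build_design(phen, animals = unique(phen$animal),
                 fixed = c("age", "age2")),
    "rank deficient.*age2")
})

test_that("missing traits produce per-trait rows and a per-trait rank check", {
  phen <- make_phen(n_bulls = 3, n_rec = 4)
  phen$vol[c(1, 5)] <- NA
  des <- build_design(phen, animals = unique(phen$animal), fixed = "age")
  expect_equal(nrow(des$obs), 3 * 12 - 2)
  ## a fixed effect observed for no record of one trait is caught
  phen2 <- make_phen(n_bulls = 2, n_rec = 3, cg_levels = 3)
  phen2$ns[phen2$cg == "cg2"] <- NA
  expect_error(build_design(phen2, animals = unique(phen2$animal),
                            fixed = "cg"), "trait 'ns'")
})

test_that("MME solutions match a dense GLS/BLUP oracle", {
  spec <- sim_spec(n_sires = 3, n_dams = 4, n_bulls = 6,
                   records_per_bull = 3, n_chromosomes = 1,
                   markers_per_chromosome = 10, seed = 15)
  ped <- simulate_pedigree(spec)
  sim <- simulate_phenotypes(spec, ped)
  A <- build_A(ped)
  A_inv <- chol2inv(chol(A))
  des <- build_design(sim$phenotypes, animals = rownames(A),
                      fixed = c("ejaculate", "age"))
  vc <- list(Va = default_trait_cov(0.3, 0.2),
             Vp = default_trait_cov(0.2, 0.1),
             Ve = default_trait_cov(0.5, 0.15))
  sol <- solve_mme(des, A_inv, vc)
  oracle <- gls_blup_oracle(des, A, vc)
  expect_equal(sol$fixed$estimate, oracle$b, tolerance = 1e-8)
  expect_equal(sol$gebv$gebv, oracle$u, tolerance = 1e-8)
  expect_equal(sol$pe$pe, oracle$pe, tolerance = 1e-8)
})

test_that("breeding values shrink to zero as Va vanishes", {
  phen <- make_phen(n_bulls = 4, n_rec = 3)
  des <- build_design(phen, animals = unique(phen$animal), fixed = "age")
  vc <- list(Va = diag(1e-12, 3), Vp = default_trait_cov(0.2, 0),
             Ve = diag(3))
  sol <- solve_mme(des, diag(4), vc)
  expect_lt(max(abs(sol$gebv$gebv)), 1e-6)
})

test_that("duplicated records with doubled Ve carry the same information", {
  ## two independent copies of a record with residual covariance 2 Ve are
  ## exactly as informative as one copy at Ve, so every estimate is
  ## unchanged; this is the residual-weighting identity of the model
  phen <- make_phen(n_bulls = 5, n_rec = 3, seed = 7)
  animals <- unique(phen$animal)
  vc <- list(Va = default_trait_cov(0.3, 0.2),
             Vp = default_trait_cov(0.2, 0.1),
             Ve = default_trait_cov(0.5, 0.1))
  des1 <- build_design(phen, animals = animals, fixed = c("age", "temp"))
  sol1 <- solve_mme(des1, diag(length(animals)), vc)
  phen2 <- dplyr::bind_rows(phen, phen)
  des2 <- build_design(phen2, animals = animals, fixed = c("age", "temp"))
  vc2 <- vc; vc2$Ve <- vc$Ve * 2
  sol2 <- solve_mme(des2, diag(length(animals)), vc2)
  expect_equal(sol1$fixed$estimate, sol2$fixed$estimate, tolerance = 1e-8)
  expect_equal(sol1$gebv$gebv, sol2$gebv$gebv, tolerance = 1e-8)
})

test_that("MME-based restricted likelihood equals the dense-V formula", {
  spec <- sim_spec(n_sires = 3, n_dams = 4, n_bulls = 6, records_per_bull = 3,
                   n_chromosomes = 1, markers_per_chromosome = 8, seed = 23,
                   missing_rate = 0.1)
  ped <- simulate_pedigree(spec)
  sim <- simulate_phenotypes(spec, ped)
  A <- build_A(ped)
  des <- build_design(sim$phenotypes, animals = rownames(A),
                      fixed = c("age", "het"))
  vc <- list(Va = default_trait_cov(0.35, 0.25),
             Vp = default_trait_cov(0.15, 0.05),
             Ve = default_trait_cov(0.45, 0.1))
  sol <- solve_mme(des, chol2inv(chol(A)), vc)
  expect_equal(sol$logL, dense_reml_logl(des, A, vc), tolerance = 1e-8)
})

test_that("REML matches an independent optimiser of the dense likelihood", {
  ## single trait so the independent search stays cheap
  spec <- sim_spec(n_sires = 5, n_dams = 10, n_bulls = 30,
                   records_per_bull = 3, n_chromosomes = 1,
                   markers_per_chromosome = 5, seed = 41)
  ped <- simulate_pedigree(spec)
  sim <- simulate_phenotypes(spec, ped)
  A <- build_A(ped)
  des <- build_design(sim$phenotypes, animals = rownames(A),
                      traits = "vol", fixed = "age")
  suppressWarnings(
    fit <- reml_fit(des, chol2inv(chol(A)), max_iter = 300, tol = 1e-10))
  ## independent route: optimise the dense-V restricted likelihood
  obj <- function(lt) {
    vc <- list(Va = matrix(exp(lt[1])), Vp = matrix(exp(lt[2])),
               Ve = matrix(exp(lt[3])))
    -dense_reml_logl(des, A, vc)
  }
  opt <- stats::optim(log(c(0.3, 0.3, 0.5)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  expect_equal(fit$logL, -opt$value, tolerance = 1e-4)
  expect_equal(unname(c(fit$Va, fit$Vp, fit$Ve)), unname(exp(opt$par)),
               tolerance = 0.02)
})

test_that("restricted likelihood never decreases across iterations", {
  dat <- simulate_dataset(small_sim(seed = 52))
  geno <- qc_filter(dat$geno)
  rel <- build_relationships(dat$ped, geno)
  des <- build_design(dat$phenotypes, animals = rownames(rel$A))
  suppressWarnings(
    fit <- reml_fit(des, rel$H_inv, max_iter = 25, tol = 1e-6))
  expect_true(all(diff(fit$trace$logL) >= -1e-8))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 18)
  expect_true(all(c("logLik", "converged") %in% names(glance(fit))))
})

test_that("pure-noise data drives genetic and permanent variance to the floor", {
  for (seed in c(61, 62)) {
    spec <- sim_spec(n_sires = 10, n_dams = 30, n_bulls = 80,
                     records_per_bull = 4, n_chromosomes = 1,
                     markers_per_chromosome = 5,
                     Va = diag(1e-4, 3), Vp = diag(1e-4, 3), Ve = diag(3),
                     seed = seed)
    ped <- simulate_pedigree(spec)
    sim <- simulate_phenotypes(spec, ped)
    A <- build_A(ped)
    des <- build_design(sim$phenotypes, animals = rownames(A),
                        fixed = c("age", "temp"))
    suppressWarnings(
    fit <- reml_fit(des, chol2inv(chol(A)), max_iter = 40, tol = 1e-6))
    expect_true(all(diag(fit$Va) < 0.1 * diag(fit$Ve)))
    expect_true(all(diag(fit$Vp) < 0.1 * diag(fit$Ve)))
  }
})

test_that("estimates are invariant to record order", {
  dat <- simulate_dataset(small_sim(seed = 71))
  rel <- build_relationships(dat$ped, qc_filter(dat$geno))
  des1 <- build_design(dat$phenotypes, animals = rownames(rel$A))
  suppressWarnings(
    fit1 <- reml_fit(des1, rel$H_inv, max_iter = 10, tol = 1e-8, use_ai = FALSE))
  set.seed(1)
  shuffled <- dat$phenotypes[sample(nrow(dat$phenotypes)), ]
  des2 <- build_design(shuffled, animals = rownames(rel$A))
  suppressWarnings(
    fit2 <- reml_fit(des2, rel$H_inv, max_iter = 10, tol = 1e-8, use_ai = FALSE))
  expect_equal(fit1$Va, fit2$Va, tolerance = 1e-6)
  expect_equal(fit1$Ve, fit2$Ve, tolerance = 1e-6)
})
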