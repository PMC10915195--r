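#' Back-solve SNP effects from genomic breeding values
#'
#' Standard ssGWAS back-solution u = Z' G*^-1 a_hat / s, where Z is the
#' 2p-centered genotype matrix of the genotyped animals, G* the blended
#' genomic relationship matrix, a_hat the genotyped animals' (G)EBVs and
#' s = 2 sum_j p_j (1 - p_j). When G is the unblended Z Z'/s and square
#' invertible, Z u reproduces a_hat exactly.
#'
#' @param gebv Numeric vector (or matrix, one column per trait) of breeding
#'   values for the genotyped animals, in the row order of `Z`.
#' @param Z Centered genotype matrix (animals x markers).
#' @param G_star Genomic relationship matrix used in the evaluation.
#' @param s Divisor 2 sum p(1-p).
#' @return Matrix of marker effects (markers x traits).
#' @export
backsolve_effects <- function(gebv, Z, G_star, s) {
  gebv <- as.matrix(gebv)
  if (nrow(gebv) != nrow(Z))
    stop_ssgwas("gebv length does not match the genotyped animals")
  if (!all(dim(G_star) == nrow(Z)))
    stop_ssgwas("G_star dimension does not match Z")
  if (s <= 0) stop_ssgwas("divisor s must be positive")
  Ginv_a <- solve(G_star, gebv)
  u <- crossprod(Z, Ginv_a) / s
  rownames(u) <- colnames(Z)
  u
}

#' Per-SNP additive variance contributions
#'
#' The default (`method = "score_variance"`) takes, for each marker, the
#' sample variance (n-1 denominator) over genotyped animals of the marker's
#' genotype-score contribution z_.j u_j. The alternative
#' `method = "freq_formula"` uses 2 p_j (1 - p_j) u_j^2.
#'
#' @param u Marker-effect matrix from [backsolve_effects()].
#' @param Z Centered genotype matrix (animals x markers).
#' @param p Allele-2 frequencies (needed for `freq_formula`).
#' @param method Variance definition (see above).
#' @return Matrix of per-SNP variances (markers x traits), all >= 0.
#' @export
snp_variances <- function(u, Z, p = NULL,
                          method = c("score_variance", "freq_formula")) {
  method <- match.arg(method)
  u <- as.matrix(u)
  if (nrow(u) != ncol(Z)) stop_ssgwas("length(u) != marker count")
  if (method == "score_variance") {
    if (nrow(Z) < 2) stop_ssgwas("need >= 2 genotyped animals")
    colvar <- matrixStats_colVars(Z)
    v <- colvar * u^2
  } else {
    if (is.null(p)) stop_ssgwas("freq_formula needs allele frequencies p")
    v <- (2 * p * (1 - p)) * u^2
  }
  rownames(v) <- colnames(Z)
  v
}

# column sample variances without an extra dependency
matrixStats_colVars <- function(m) {
  mu <- colMeans(m)
  (colSums(m^2) - nrow(m) * mu^2) / (nrow(m) - 1)
}

#' Per-SNP effects and variances as a tidy table
#'
#' Runs the back-solution and variance computation for every trait and
#' attaches marker-map coordinates and the percentage of the trait's total
#' additive variance.
#'
#' @param solution An `mme_solution` (or `ssgwas_reml`) holding GEBVs.
#' @param relset A `relationship_set` from [build_relationships()].
#' @param sigma_a2 Named numeric vector of total additive variances per
#'   trait (the REML estimates diag(Va)).
#' @param geno The post-QC [geno_mat()] (for the marker map).
#' @param method Passed to [snp_variances()].
#' @return A tibble: `marker`, `chrom`, `pos_bp`, `trait`, `effect`,
#'   `variance`, `pct_sigma_a2`.
#' @export
snp_effect_table <- function(solution, relset, sigma_a2, geno,
                             method = "score_variance") {
  if (inherits(solution, "ssgwas_reml")) solution <- solution$solutions
  gebv <- solution$gebv
  traits <- unique(gebv$trait)
  if (is.null(names(sigma_a2))) names(sigma_a2) <- traits
  if (any(sigma_a2[traits] <= 0))
    stop_ssgwas("sigma_a2 must be positive for every trait")
  gmat <- tidyr::pivot_wider(gebv, names_from = "trait",
                             values_from = "gebv")
  idx <- match(relset$genotyped, gmat$animal)
  if (anyNA(idx)) stop_ssgwas("genotyped animals missing from the solutions")
  a_hat <- as.matrix(gmat[idx, traits, drop = FALSE])
  u <- backsolve_effects(a_hat, relset$Z, relset$G_star, relset$s)
  v <- snp_variances(u, relset$Z, p = relset$p, method = method)
  map <- geno$map
  out <- purrr::map(seq_along(traits), function(k) {
    tibble(marker = map$marker, chrom = map$chrom, pos_bp = map$pos_bp,
           trait = traits[k],
           effect = u[map$marker, k], variance = v[map$marker, k],
           pct_sigma_a2 = v[map$marker, k] / sigma_a2[[traits[k]]] * 100)
  })
  bind_rows(out)
}
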