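#' Wright's numerator relationship matrix (tabular method)
#'
#' Builds the pedigree-based additive relationship matrix A with the tabular
#' method: processing animals in topological order,
#' a_ij = 0.5 (a_i,sire(j) + a_i,dam(j)) for i earlier than j and
#' a_jj = 1 + 0.5 a_sire(j),dam(j), so diag(A) = 1 + F (inbreeding).
#'
#' @param ped A pedigree tibble as returned by [read_pedigree()] /
#'   [validate_pedigree()].
#' @return A dense symmetric matrix with animal ids as dimnames, ordered as
#'   the (topologically sorted) pedigree.
#' @export
build_A <- function(ped) {
  ped <- validate_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$animal
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1) {
      prev <- seq_len(j - 1)
      rel <- numeric(j - 1)
      if (!is.na(s)) rel <- rel + 0.5 * A[prev, s]
      if (!is.na(d)) rel <- rel + 0.5 * A[prev, d]
      A[prev, j] <- rel
      A[j, prev] <- rel
    }
    A[j, j] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Blending parameters for the genomic relationship matrix
#'
#' Weight factors used when combining the genomic matrix G22 with the pedigree
#' block A22 and when forming the single-step inverse: G* = alpha G_scaled +
#' beta A22, and H^-1 adds tau G*^-1 - omega A22^-1 on the genotyped block.
#' `gamma` and `delta` are accepted for interface compatibility but inert
#' (reserved). Defaults are tau = 1, alpha = 0.95, beta = 0.05, gamma = 0,
#' delta = 0, omega = 1.
#'
#' @param tau,alpha,beta,gamma,delta,omega Real weights.
#' @return A list of class `blend_params`.
#' @export
blend_params <- function(tau = 1, alpha = 0.95, beta = 0.05,
                         gamma = 0, delta = 0, omega = 1) {
  if (alpha + beta > 1 + 1e-9)
    stop_ssgwas("alpha + beta must not exceed 1")
  structure(list(tau = tau, alpha = alpha, beta = beta, gamma = gamma,
                 delta = delta, omega = omega), class = "blend_params")
}

#' Genomic relationship matrix among genotyped animals
#'
#' G22 = Z Z' / (2 sum_j p_j (1 - p_j)), where p_j is the observed frequency
#' of allele 2 at marker j among the genotyped animals and Z holds the codes
#' centered by 2 p_j (code 0 -> -2p, 1 -> 1-2p, 2 -> 2-2p).
#'
#' @param geno A [geno_mat()] (codes must be complete; run [qc_filter()]
#'   first if they are not).
#' @param freqs Optional externally supplied allele-2 frequencies; default is
#'   the observed frequencies.
#' @return A list with `G` (genomic matrix), `Z` (centered codes), `p`
#'   (allele frequencies) and `s` (the divisor 2 sum p(1-p)).
#' @export
build_G22 <- function(geno, freqs = NULL) {
  stopifnot(inherits(geno, "geno_mat"))
  codes <- geno$codes
  if (nrow(codes) < 2) stop_ssgwas("need at least 2 genotyped animals")
  if (anyNA(codes)) stop_ssgwas("missing codes: run qc_filter() first")
  p <- freqs %||% (colMeans(codes) / 2)
  if (length(p) != ncol(codes)) stop_ssgwas("length(freqs) != marker count")
  s <- 2 * sum(p * (1 - p))
  if (s <= 0) stop_ssgwas("all markers are monomorphic (zero divisor)")
  Z <- sweep(codes, 2, 2 * p, "-")
  G <- tcrossprod(Z) / s
  list(G = (G + t(G)) / 2, Z = Z, p = p, s = s)
}

#' Scale and blend a genomic relationship matrix
#'
#' First applies the two-parameter linear adjustment G_scaled = a G + b J
#' solved so that the mean diagonal and the mean off-diagonal of G_scaled
#' equal those of A22; then blends G* = alpha G_scaled + beta A22.
#'
#' @param G Raw genomic matrix (square, same order as `A22`).
#' @param A22 Pedigree relationship block for the genotyped animals.
#' @param params A [blend_params()] object.
#' @return G*, with attributes `scale_a`, `scale_b`.
#' @export
blend_and_scale <- function(G, A22, params = blend_params()) {
  check_square(G); check_square(A22)
  if (!all(dim(G) == dim(A22))) stop_ssgwas("G and A22 dimensions differ")
  md_G <- mean(diag(G)); mo_G <- offdiag_mean(G)
  md_A <- mean(diag(A22)); mo_A <- offdiag_mean(A22)
  if (nrow(G) >= 2) {
    if (abs(md_G - mo_G) < 1e-12)
      stop_ssgwas("cannot scale: G has equal diagonal and off-diagonal means")
    a <- (md_A - mo_A) / (md_G - mo_G)
    b <- md_A - a * md_G
  } else {
    a <- md_A / md_G; b <- 0
  }
  G_scaled <- a * G + b
  G_star <- params$alpha * G_scaled + params$beta * A22
  G_star <- (G_star + t(G_star)) / 2
  attr(G_star, "scale_a") <- a
  attr(G_star, "scale_b") <- b
  G_star
}

#' Single-step H inverse (and dense H)
#'
#' H^-1 = A^-1 + \[0 0; 0 tau G*^-1 - omega A22^-1\] on the genotyped block.
#' `build_H_dense()` gives the four-block H itself
#' (A11 + A12 A22^-1 (G - A22) A22^-1 A21 in the non-genotyped block, etc.),
#' used for validation; the two coincide (as mutual inverses) at the default
#' tau = omega = 1.
#'
#' @param A Full pedigree relationship matrix (dimnames = animal ids).
#' @param G_star Blended genomic matrix for the genotyped animals.
#' @param genotyped Character vector of genotyped animal ids (must be rows of
#'   `A`).
#' @param params A [blend_params()].
#' @return `build_H_inverse()`: dense H^-1 in the order of `A`;
#'   `build_H_dense()`: dense H in the same order.
#' @export
build_H_inverse <- function(A, G_star, genotyped, params = blend_params()) {
  check_square(A)
  idx <- match(genotyped, rownames(A))
  if (anyNA(idx)) stop_ssgwas("genotyped ids missing from A")
  A_inv <- tryCatch(chol2inv(chol(A)), error = function(e)
    stop_ssgwas("A is not invertible: ", conditionMessage(e)))
  dimnames(A_inv) <- dimnames(A)
  if (!length(idx)) return(A_inv)
  A22 <- A[idx, idx, drop = FALSE]
  if (!all(dim(G_star) == length(idx)))
    stop_ssgwas("G_star dimension does not match the genotyped set")
  G_inv <- tryCatch(chol2inv(chol(G_star)), error = function(e)
    stop_ssgwas(sprintf(
      "G* is not invertible (reciprocal condition number %.3e): %s",
      rcond(G_star), conditionMessage(e))))
  A22_inv <- tryCatch(chol2inv(chol(A22)), error = function(e)
    stop_ssgwas(sprintf(
      "A22 is not invertible (reciprocal condition number %.3e): %s",
      rcond(A22), conditionMessage(e))))
  H_inv <- A_inv
  H_inv[idx, idx] <- H_inv[idx, idx] + params$tau * G_inv -
    params$omega * A22_inv
  (H_inv + t(H_inv)) / 2
}

#' @rdname build_H_inverse
#' @export
build_H_dense <- function(A, G_star, genotyped) {
  check_square(A)
  idx <- match(genotyped, rownames(A))
  if (anyNA(idx)) stop_ssgwas("genotyped ids missing from A")
  if (!length(idx)) return(A)
  nidx <- setdiff(seq_len(nrow(A)), idx)
  A22 <- A[idx, idx, drop = FALSE]
  A22_inv <- chol2inv(chol(A22))
  H <- A
  if (length(nidx)) {
    A12 <- A[nidx, idx, drop = FALSE]
    T12 <- A12 %*% A22_inv
    H[nidx, nidx] <- A[nidx, nidx] + T12 %*% (G_star - A22) %*% t(T12)
    H[nidx, idx] <- T12 %*% G_star
    H[idx, nidx] <- t(H[nidx, idx])
  }
  H[idx, idx] <- G_star
  (H + t(H)) / 2
}

#' Build the full relationship set for a single-step analysis
#'
#' Convenience wrapper: A from the pedigree, G22 from the genotypes, scaling
#' and blending against A22, and H^-1 (plus dense H). The genotyped set is the
#' intersection of the genotype matrix's animals with the pedigree.
#'
#' @param ped Pedigree tibble.
#' @param geno A complete (post-QC) [geno_mat()], or `NULL` for a
#'   pedigree-only set (H = A).
#' @param params A [blend_params()].
#' @return A list of class `relationship_set` with elements `A`, `A22`,
#'   `G22_raw`, `G_star`, `H_inv`, `H`, `genotyped`, `p`, `s`, `Z`, `params`.
#' @export
build_relationships <- function(ped, geno = NULL, params = blend_params()) {
  A <- build_A(ped)
  if (is.null(geno)) {
    out <- list(A = A, A22 = NULL, G22_raw = NULL, G_star = NULL,
                H_inv = chol2inv(chol(A)), H = A, genotyped = character(0),
                p = NULL, s = NULL, Z = NULL, params = params)
    dimnames(out$H_inv) <- dimnames(A)
    return(structure(out, class = "relationship_set"))
  }
  stopifnot(inherits(geno, "geno_mat"))
  genotyped <- intersect(rownames(A), rownames(geno$codes))
  if (length(genotyped) < 2)
    stop_ssgwas("fewer than 2 genotyped animals appear in the pedigree")
  gsub_geno <- geno
  gsub_geno$codes <- geno$codes[genotyped, , drop = FALSE]
  g22 <- build_G22(gsub_geno)
  A22 <- A[genotyped, genotyped, drop = FALSE]
  G_star <- blend_and_scale(g22$G, A22, params)
  H_inv <- build_H_inverse(A, G_star, genotyped, params)
  H <- build_H_dense(A, G_star, genotyped)
  structure(list(A = A, A22 = A22, G22_raw = g22$G, G_star = G_star,
                 H_inv = H_inv, H = H, genotyped = genotyped, p = g22$p,
                 s = g22$s, Z = g22$Z, params = params),
            class = "relationship_set")
}

#' @export
print.relationship_set <- function(x, ...) {
  cat(sprintf("<relationship_set> %d animals, %d genotyped\n",
              nrow(x$A), length(x$genotyped)))
  invisible(x)
}
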