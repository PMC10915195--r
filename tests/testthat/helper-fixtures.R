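# shared fixture builders; everything is generated in code at test time

trio_pedigree <- function() {
  tibble::tibble(animal = c("s", "d", "o"),
                 sire = c(NA, NA, "s"), dam = c(NA, NA, "d"))
}

# random valid pedigree: founders first, each later animal picks parents
# among earlier ones (or unknown)
random_pedigree <- function(n, p_unknown = 0.2) {
  ids <- sprintf("a%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && runif(1) > p_unknown) sire[i] <- sample(ids[seq_len(i - 1)], 1)
    if (i >= 3 && runif(1) > p_unknown) dam[i] <- sample(ids[seq_len(i - 1)], 1)
  }
  tibble::tibble(animal = ids, sire = sire, dam = dam)
}

# brute-force numerator relationship matrix straight from the recursive
# definition: a_ij = 0.5 (a_i,sire(j) + a_i,dam(j)),
# a_jj = 1 + 0.5 a_sire(j),dam(j); memoised, independent of the tabular code
recursive_A <- function(ped) {
  ids <- ped$animal
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  memo <- new.env(parent = emptyenv())
  rel <- function(i, j) {
    if (i > j) return(rel(j, i))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      1 + if (!is.na(si[i]) && !is.na(di[i])) 0.5 * rel(si[i], di[i]) else 0
    } else {
      # j is later in topological order than i
      out <- 0
      if (!is.na(si[j])) out <- out + 0.5 * rel(i, si[j])
      if (!is.na(di[j])) out <- out + 0.5 * rel(i, di[j])
      out
    }
    memo[[key]] <- val
    val
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- rel(i, j)
  A
}

tiny_geno <- function() {
  geno_mat(matrix(c(0, 2, 2, 0), 2, 2,
                  dimnames = list(c("a1", "a2"), c("m1", "m2"))),
           tibble::tibble(marker = c("m1", "m2"), chrom = "1",
                          pos_bp = c(100L, 200L)))
}

# small but well-conditioned genotype set: n animals, m markers
random_geno <- function(n = 12, m = 20, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.2, 0.8)
  codes <- sapply(p, function(pp) rbinom(n, 2, pp))
  dimnames(codes) <- list(sprintf("an%02d", 1:n), sprintf("mk%02d", 1:m))
  geno_mat(codes, tibble::tibble(marker = colnames(codes), chrom = "1",
                                 pos_bp = as.integer(seq(1e4, by = 1e4,
                                                         length.out = m))))
}

small_sim <- function(seed = 42, ...) {
  sim_spec(n_sires = 8, n_dams = 16, n_bulls = 30, records_per_bull = 4,
           n_genotyped_bulls = 20, n_genotyped_dams = 4,
           n_chromosomes = 2, markers_per_chromosome = 40, seed = seed, ...)
}

# dense GLS/BLUP oracle for the multi-trait repeatability model, built from
# the observation-level covariance V = Z_a (K x Va) Z_a' + Z_p (I x Vp) Z_p'
# + R; independent of the package's MME solver
gls_blup_oracle <- function(design, K, vc) {
  nt <- design$nt
  obs <- design$obs
  n <- nrow(obs)
  q <- length(design$animals)
  qp <- length(design$pe_animals)
  a_of_rec <- match(design$record_animal, design$animals)
  p_of_rec <- match(design$record_animal, design$pe_animals)
  Za <- matrix(0, n, q * nt)
  Zp <- matrix(0, n, qp * nt)
  X <- matrix(0, n, ncol(design$X0) * nt)
  for (r in seq_len(n)) {
    rec <- obs$record[r]; k <- obs$trait[r]
    Za[r, (a_of_rec[rec] - 1) * nt + k] <- 1
    Zp[r, (p_of_rec[rec] - 1) * nt + k] <- 1
    X[r, (seq_len(ncol(design$X0)) - 1) * nt + k] <- design$X0[rec, ]
  }
  Ga <- kronecker(K, vc$Va)
  Gp <- kronecker(diag(qp), vc$Vp)
  R <- matrix(0, n, n)
  for (rec in unique(obs$record)) {
    rows <- obs$row[obs$record == rec]
    O <- obs$trait[obs$record == rec]
    R[rows, rows] <- vc$Ve[O, O]
  }
  V <- Za %*% Ga %*% t(Za) + Zp %*% Gp %*% t(Zp) + R
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% obs$y)
  resid <- obs$y - X %*% b
  u <- Ga %*% t(Za) %*% Vi %*% resid
  pe <- Gp %*% t(Zp) %*% Vi %*% resid
  list(b = as.numeric(b), u = as.numeric(u), pe = as.numeric(pe))
}

# restricted log-likelihood from the observation-level covariance matrix
# (direct formula, independent of the MME-based evaluation)
dense_reml_logl <- function(design, K, vc) {
  nt <- design$nt
  obs <- design$obs
  n <- nrow(obs)
  q <- length(design$animals)
  qp <- length(design$pe_animals)
  a_of_rec <- match(design$record_animal, design$animals)
  p_of_rec <- match(design$record_animal, design$pe_animals)
  Za <- matrix(0, n, q * nt); Zp <- matrix(0, n, qp * nt)
  X <- matrix(0, n, ncol(design$X0) * nt)
  for (r in seq_len(n)) {
    rec <- obs$record[r]; k <- obs$trait[r]
    Za[r, (a_of_rec[rec] - 1) * nt + k] <- 1
    Zp[r, (p_of_rec[rec] - 1) * nt + k] <- 1
    X[r, (seq_len(ncol(design$X0)) - 1) * nt + k] <- design$X0[rec, ]
  }
  R <- matrix(0, n, n)
  for (rec in unique(obs$record)) {
    rows <- obs$row[obs$record == rec]
    O <- obs$trait[obs$record == rec]
    R[rows, rows] <- vc$Ve[O, O]
  }
  V <- Za %*% kronecker(K, vc$Va) %*% t(Za) +
    Zp %*% kronecker(diag(qp), vc$Vp) %*% t(Zp) + R
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  as.numeric(-0.5 * (determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       t(obs$y) %*% P %*% obs$y))
}

offdiag_mean_test <- function(m) {
  (sum(m) - sum(diag(m))) / (nrow(m) * (nrow(m) - 1))
}
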