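#' Build the multi-trait mixed-model design
#'
#' Expands a phenotype table of repeated records into the observation-level
#' design of the repeatability model y = X b + Z_a a + Z_p p + e: one row per
#' record per non-missing trait. Categorical fixed effects are dummy-coded
#' with a dropped reference level (single-level factors collapse into the
#' intercept); numeric columns enter untransformed as covariates. A rank
#' check on the record-level design matrix names aliased columns.
#'
#' @param phen Phenotype tibble (see [read_phenotypes()]).
#' @param animals Character vector of all animal ids in the order of the
#'   relationship matrix used for fitting; must contain every recorded
#'   animal. Breeding values are predicted for all of them.
#' @param traits Trait column names.
#' @param fixed Fixed-effect column names present in `phen`.
#' @return An object of class `mme_design`.
#' @export
build_design <- function(phen, animals,
                         traits = c("vol", "ns", "mot"),
                         fixed = intersect(c("cg", "ejaculate", "age",
                                             "temp", "het"), names(phen))) {
  phen <- as_tibble(phen)
  if (!nrow(phen)) stop_ssgwas("phenotype table is empty")
  miss <- setdiff(phen$animal, animals)
  if (length(miss))
    stop_ssgwas("recorded animals missing from the relationship order: ",
                paste(head(miss, 5), collapse = ", "))
  nt <- length(traits)
  Y <- as.matrix(phen[traits])
  if (any(rowSums(!is.na(Y)) == 0))
    stop_ssgwas("records with all traits missing must be dropped upstream")
  ## record-level fixed-effect matrix
  fdat <- as.data.frame(phen[fixed], stringsAsFactors = FALSE)
  for (cl in names(fdat)) {
    if (is.character(fdat[[cl]]) || is.factor(fdat[[cl]]) ||
        cl %in% c("cg", "ejaculate"))
      fdat[[cl]] <- factor(fdat[[cl]])
  }
  single <- vapply(fdat, function(x) is.factor(x) && nlevels(x) < 2, logical(1))
  if (any(single)) fdat <- fdat[, !single, drop = FALSE]
  X0 <- if (ncol(fdat)) model.matrix(~ ., data = fdat)
        else matrix(1, nrow(phen), 1, dimnames = list(NULL, "(Intercept)"))
  qrx <- qr(X0)
  if (qrx$rank < ncol(X0)) {
    aliased <- colnames(X0)[qrx$pivot[(qrx$rank + 1):ncol(X0)]]
    stop_ssgwas("fixed-effect design is rank deficient; aliased columns: ",
                paste(aliased, collapse = ", "))
  }
  ## with per-trait missingness each trait sees only a subset of records,
  ## so the per-trait design must be full rank too
  for (k in seq_len(nt)) {
    seen <- !is.na(Y[, k])
    qrk <- qr(X0[seen, , drop = FALSE])
    if (qrk$rank < ncol(X0)) {
      aliased <- colnames(X0)[qrk$pivot[(qrk$rank + 1):ncol(X0)]]
      stop_ssgwas(sprintf(
        "fixed-effect design is rank deficient for trait '%s' %s: %s",
        traits[k], "(no informative records for columns)",
        paste(aliased, collapse = ", ")))
    }
  }
  ## observation table: one row per record per observed trait
  obs_trait <- which(!is.na(t(Y)))            # column-major over t(Y): record-major
  rec_of <- (obs_trait - 1L) %/% nt + 1L
  tr_of <- (obs_trait - 1L) %% nt + 1L
  obs <- tibble(row = seq_along(rec_of), record = rec_of, trait = tr_of,
                y = Y[cbind(rec_of, tr_of)])
  rec_animals <- as.character(phen$animal)
  pe_animals <- unique(rec_animals)
  structure(list(obs = obs, X0 = X0, traits = traits, nt = nt,
                 animals = animals, pe_animals = pe_animals,
                 record_animal = rec_animals,
                 n_records = nrow(phen)),
            class = "mme_design")
}

#' @export
print.mme_design <- function(x, ...) {
  cat(sprintf(
    "<mme_design> %d records, %d trait-observations, %d traits, %d fixed columns\n",
    x$n_records, nrow(x$obs), x$nt, ncol(x$X0)))
  invisible(x)
}

# ---- internal machinery -----------------------------------------------------

# one-time structures shared by every REML iteration / MME solve
mme_prepare <- function(design, K_inv) {
  nt <- design$nt
  obs <- design$obs
  p0 <- ncol(design$X0)
  q <- length(design$animals)
  qp <- length(design$pe_animals)
  if (nrow(K_inv) != q) stop_ssgwas("K_inv dimension != number of animals")
  off_a <- p0 * nt
  off_p <- off_a + q * nt
  n_eff <- off_p + qp * nt
  a_idx <- match(design$record_animal, design$animals)
  p_idx <- match(design$record_animal, design$pe_animals)
  ## sparse W: fixed part via a record-to-nonzero join, then Za, Zp
  nz <- which(design$X0 != 0, arr.ind = TRUE)
  xtrip <- tibble(record = nz[, 1], col0 = nz[, 2],
                  val = design$X0[nz])
  xx <- inner_join(obs, xtrip, by = "record", relationship = "many-to-many")
  i_all <- c(xx$row, obs$row, obs$row)
  j_all <- c((xx$col0 - 1L) * nt + xx$trait,
             off_a + (a_idx[obs$record] - 1L) * nt + obs$trait,
             off_p + (p_idx[obs$record] - 1L) * nt + obs$trait)
  x_all <- c(xx$val, rep(1, nrow(obs)), rep(1, nrow(obs)))
  W <- Matrix::sparseMatrix(i = i_all, j = j_all, x = x_all,
                            dims = c(nrow(obs), n_eff))
  ## per-record observed-trait patterns
  pat_key <- vapply(split(obs$trait, obs$record),
                    function(v) paste(v, collapse = ","), character(1))
  rec_order <- as.integer(names(pat_key))
  pat_of_rec <- setNames(pat_key, rec_order)[as.character(seq_len(design$n_records))]
  patterns <- list()
  for (pk in unique(pat_of_rec)) {
    recs <- which(pat_of_rec == pk)
    tr_set <- as.integer(strsplit(pk, ",")[[1]])
    sel <- obs$record %in% recs
    rows_mat <- matrix(obs$row[sel][order(obs$record[sel], obs$trait[sel])],
                       ncol = length(tr_set), byrow = TRUE)
    patterns[[pk]] <- list(traits = tr_set, records = recs, rows = rows_mat)
  }
  ## per-record dense W rows for residual-block computations
  Wt <- Matrix::t(W)
  rec_rows <- split(obs$row, obs$record)
  rec_struct <- lapply(seq_len(design$n_records), function(r) {
    rr <- rec_rows[[as.character(r)]] %||% rec_rows[[r]]
    sub <- Wt[, rr, drop = FALSE]
    cols <- sort(unique(sub@i)) + 1L
    list(rows = rr, cols = cols,
         Wd = t(as.matrix(sub[cols, , drop = FALSE])))
  })
  prep <- list(W = W, obs = obs, patterns = patterns,
               rec_struct = rec_struct,
               p0 = p0, q = q, qp = qp, nt = nt, off_a = off_a,
               off_p = off_p, n_eff = n_eff, K_inv = K_inv,
               logdet_K = -2 * sum(log(diag(chol(K_inv)))),
               y = obs$y)
  ## precomputed pieces for fast C assembly:
  ## W' Rinv W = sum over patterns, trait pairs (k<=l) of
  ## Veinv_pat[k,l] * Msym(pattern, k, l) with fixed sparsity; the values
  ## of every Msym are stored aligned to one common sparsity template
  terms <- list()
  for (pk in names(patterns)) {
    pat <- patterns[[pk]]
    m <- length(pat$traits)
    for (kk in seq_len(m)) for (ll in kk:m) {
      Mkl <- Matrix::crossprod(W[pat$rows[, kk], , drop = FALSE],
                               W[pat$rows[, ll], , drop = FALSE])
      Msym <- if (kk == ll) Mkl else Mkl + Matrix::t(Mkl)
      terms[[length(terms) + 1]] <- list(pattern = pk, k = kk, l = ll,
                                         M = methods::as(Msym, "CsparseMatrix"))
    }
  }
  tmpl <- Reduce(`+`, lapply(terms, function(t_) {
    M <- t_$M; M@x[] <- 1; M
  }))
  tmpl <- methods::as(tmpl, "CsparseMatrix")
  ti <- tmpl@i + 1L
  tj <- rep(seq_len(ncol(tmpl)), diff(tmpl@p))
  prep$tmpl_lin <- (as.numeric(tj) - 1) * n_eff + ti
  prep$terms <- lapply(terms, function(t_) {
    M <- t_$M
    mi <- M@i + 1L
    mj <- rep(seq_len(ncol(M)), diff(M@p))
    pos <- match((as.numeric(mj) - 1) * n_eff + mi, prep$tmpl_lin)
    vals <- numeric(length(prep$tmpl_lin))
    vals[pos] <- M@x
    list(pattern = t_$pattern, k = t_$k, l = t_$l, vals = vals)
  })
  ## expansion of K_inv for the additive block and gather indices for Va_inv
  reps <- rep(seq_len(q), each = nt)
  prep$Kbig <- K_inv[reps, reps]
  tr_rep <- rep(seq_len(nt), q)
  prep$VaTileIdx <- matrix(tr_rep, q * nt, q * nt, byrow = FALSE) +
    nt * (matrix(tr_rep, q * nt, q * nt, byrow = TRUE) - 1L)
  ## linear indices of the nt x nt blocks on the permanent-environment
  ## diagonal, plus the matching entry of Vp_inv for each cell
  k_idx <- rep(seq_len(nt), times = nt)
  l_idx <- rep(seq_len(nt), each = nt)
  b_rep <- rep(0:(qp - 1), each = nt * nt)
  pe_i <- off_p + b_rep * nt + rep(k_idx, qp)
  pe_j <- off_p + b_rep * nt + rep(l_idx, qp)
  prep$pe_lin <- (as.numeric(pe_j) - 1) * n_eff + pe_i
  prep$pe_val_idx <- rep(k_idx + (l_idx - 1L) * nt, qp)
  prep
}

# apply the block-diagonal Rinv (per-record Ve[O,O]^-1) to a vector/matrix
apply_Rinv <- function(prep, Veinv_pat, V) {
  V <- as.matrix(V)
  out <- matrix(0, nrow(V), ncol(V))
  for (pk in names(prep$patterns)) {
    pat <- prep$patterns[[pk]]
    Vinv <- Veinv_pat[[pk]]
    m <- length(pat$traits)
    for (kk in seq_len(m)) {
      acc <- 0
      for (ll in seq_len(m))
        acc <- acc + Vinv[kk, ll] * V[pat$rows[, ll], , drop = FALSE]
      out[pat$rows[, kk], ] <- acc
    }
  }
  out
}

vech_pairs <- function(nt) {
  out <- list()
  for (s in seq_len(nt)) for (r in s:nt) out[[length(out) + 1]] <- c(r, s)
  out
}

# assemble C and rhs, factor, solve; optionally invert
mme_evaluate <- function(prep, vc, need_inverse = FALSE) {
  nt <- prep$nt
  Va_inv <- chol2inv(chol(vc$Va))
  Vp_inv <- chol2inv(chol(vc$Vp))
  Veinv_pat <- list()
  logdet_R <- 0
  for (pk in names(prep$patterns)) {
    O <- prep$patterns[[pk]]$traits
    VeO <- vc$Ve[O, O, drop = FALSE]
    chO <- chol(VeO)
    Veinv_pat[[pk]] <- chol2inv(chO)
    logdet_R <- logdet_R +
      nrow(prep$patterns[[pk]]$rows) * 2 * sum(log(diag(chO)))
  }
  ## dense C: data part from the sparsity template, then G-inverse blocks
  xvals <- 0
  for (t_ in prep$terms)
    xvals <- xvals + Veinv_pat[[t_$pattern]][t_$k, t_$l] * t_$vals
  C <- matrix(0, prep$n_eff, prep$n_eff)
  C[prep$tmpl_lin] <- xvals
  ia <- prep$off_a + seq_len(prep$q * nt)
  C[ia, ia] <- C[ia, ia] + prep$Kbig * Va_inv[prep$VaTileIdx]
  C[prep$pe_lin] <- C[prep$pe_lin] + Vp_inv[prep$pe_val_idx]
  Ry <- apply_Rinv(prep, Veinv_pat, prep$y)
  rhs <- as.numeric(Matrix::crossprod(prep$W, Ry))
  ch <- tryCatch(chol(C), error = function(e)
    stop_ssgwas("singular mixed-model coefficient matrix; check variance ",
                "components and design rank: ", conditionMessage(e)))
  sol <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
  yPy <- sum(prep$y * Ry) - sum(sol * rhs)
  logdet_G <- nt * prep$logdet_K + prep$q *
    determinant(vc$Va, logarithm = TRUE)$modulus +
    prep$qp * determinant(vc$Vp, logarithm = TRUE)$modulus
  logdet_C <- 2 * sum(log(diag(ch)))
  logL <- -0.5 * as.numeric(logdet_R + logdet_G + logdet_C + yPy)
  out <- list(vc = vc, ch = ch, sol = sol, rhs = rhs, logL = logL,
              Veinv_pat = Veinv_pat, Va_inv = Va_inv, Vp_inv = Vp_inv,
              resid = prep$y - as.numeric(prep$W %*% sol))
  if (need_inverse) out$Cinv <- chol2inv(ch)
  out
}

# EM sufficient statistics and score ingredients at the current evaluation
mme_statistics <- function(prep, ev) {
  nt <- prep$nt
  q <- prep$q; qp <- prep$qp
  sol <- ev$sol; Cinv <- ev$Cinv
  A_hat <- matrix(sol[prep$off_a + seq_len(q * nt)], ncol = nt, byrow = TRUE)
  P_hat <- matrix(sol[prep$off_p + seq_len(qp * nt)], ncol = nt, byrow = TRUE)
  Ta <- crossprod(A_hat, prep$K_inv %*% A_hat)
  Tp <- crossprod(P_hat)
  Sa <- matrix(0, nt, nt); Sp <- matrix(0, nt, nt)
  for (k in seq_len(nt)) for (l in k:nt) {
    rk <- prep$off_a + seq(k, q * nt, by = nt)
    rl <- prep$off_a + seq(l, q * nt, by = nt)
    Sa[k, l] <- Sa[l, k] <- sum(prep$K_inv * Cinv[rk, rl])
    pk <- prep$off_p + seq(k, qp * nt, by = nt)
    pl <- prep$off_p + seq(l, qp * nt, by = nt)
    Sp[k, l] <- Sp[l, k] <- sum(Cinv[cbind(pk, pl)])
  }
  ## residual accumulators (pairwise-complete)
  Eacc <- matrix(0, nt, nt); Bacc <- matrix(0, nt, nt)
  Dacc <- matrix(0, nt, nt); Qacc <- matrix(0, nt, nt)
  Racc <- matrix(0, nt, nt); Nacc <- matrix(0, nt, nt)
  Veinv_pat <- ev$Veinv_pat
  for (pk in names(prep$patterns)) {
    pat <- prep$patterns[[pk]]
    O <- pat$traits
    Vinv <- Veinv_pat[[pk]]
    E <- matrix(ev$resid[pat$rows], ncol = length(O))
    Eacc[O, O] <- Eacc[O, O] + crossprod(E)
    QO <- E %*% Vinv
    Qacc[O, O] <- Qacc[O, O] + crossprod(QO)
    Racc[O, O] <- Racc[O, O] + nrow(pat$rows) * Vinv
    Nacc[O, O] <- Nacc[O, O] + nrow(pat$rows)
  }
  pat_of_rec <- rep(NA_character_, length(prep$rec_struct))
  for (pk in names(prep$patterns))
    pat_of_rec[prep$patterns[[pk]]$records] <- pk
  for (r in seq_along(prep$rec_struct)) {
    st <- prep$rec_struct[[r]]
    O <- prep$obs$trait[st$rows]
    B <- st$Wd %*% Cinv[st$cols, st$cols, drop = FALSE] %*% t(st$Wd)
    Vinv <- Veinv_pat[[pat_of_rec[r]]]
    Bacc[O, O] <- Bacc[O, O] + B
    Dacc[O, O] <- Dacc[O, O] + Vinv %*% B %*% Vinv
  }
  list(A_hat = A_hat, P_hat = P_hat, Ta = Ta, Tp = Tp, Sa = Sa, Sp = Sp,
       Eacc = Eacc, Bacc = Bacc, Dacc = Dacc, Qacc = Qacc, Racc = Racc,
       Nacc = Nacc, Veinv_pat = Veinv_pat)
}

# EM-REML update: Va <- (Ta + Sa)/q, Vp <- (Tp + Sp)/qp,
# Ve (pairwise-complete) <- (Eacc + Bacc)/Nacc elementwise
em_update <- function(prep, st) {
  Va <- psd_project((st$Ta + st$Sa) / prep$q, quiet = TRUE)
  Vp <- psd_project((st$Tp + st$Sp) / prep$qp, quiet = TRUE)
  Ve <- psd_project((st$Eacc + st$Bacc) / pmax(st$Nacc, 1), quiet = TRUE)
  list(Va = Va, Vp = Vp, Ve = Ve)
}

# REML score vector in the vech parameterisation
reml_score <- function(prep, ev, st, pairs) {
  nt <- prep$nt
  Ma <- ev$Va_inv %*% (st$Ta + st$Sa - prep$q * ev$vc$Va) %*% ev$Va_inv
  Mp <- ev$Vp_inv %*% (st$Tp + st$Sp - prep$qp * ev$vc$Vp) %*% ev$Vp_inv
  Me <- st$Qacc + st$Dacc - st$Racc   # -(Racc - Dacc - Qacc)
  g <- numeric(0)
  for (pr in pairs) {
    r <- pr[1]; s <- pr[2]
    g <- c(g, if (r == s) 0.5 * Ma[r, r] else Ma[r, s])
  }
  for (pr in pairs) {
    r <- pr[1]; s <- pr[2]
    g <- c(g, if (r == s) 0.5 * Mp[r, r] else Mp[r, s])
  }
  for (pr in pairs) {
    r <- pr[1]; s <- pr[2]
    g <- c(g, if (r == s) 0.5 * Me[r, r] else Me[r, s])
  }
  g
}

# average-information matrix via the f-vector representation
ai_matrix <- function(prep, ev, st, pairs) {
  nt <- prep$nt
  obs <- prep$obs
  n_par <- 3 * length(pairs)
  Fm <- matrix(0, nrow(obs), n_par)
  ## map obs rows to animal / pe indices through the record
  col <- 0
  for (pr in pairs) {            # Va block
    r <- pr[1]; s <- pr[2]
    E <- matrix(0, nt, nt); E[r, s] <- E[r, s] + 1; E[s, r] <- E[s, r] + 1
    if (r == s) E[r, r] <- 1
    MaA <- st$A_hat %*% t(E %*% ev$Va_inv)       # q x nt, row i = M a_i
    col <- col + 1
    Fm[, col] <- MaA[cbind(attr(prep, "rec_a")[obs$record], obs$trait)]
  }
  for (pr in pairs) {            # Vp block
    r <- pr[1]; s <- pr[2]
    E <- matrix(0, nt, nt); E[r, s] <- E[r, s] + 1; E[s, r] <- E[s, r] + 1
    if (r == s) E[r, r] <- 1
    MpP <- st$P_hat %*% t(E %*% ev$Vp_inv)
    col <- col + 1
    Fm[, col] <- MpP[cbind(attr(prep, "rec_p")[obs$record], obs$trait)]
  }
  for (pr in pairs) {            # Ve block
    r <- pr[1]; s <- pr[2]
    E <- matrix(0, nt, nt); E[r, s] <- E[r, s] + 1; E[s, r] <- E[s, r] + 1
    if (r == s) E[r, r] <- 1
    col <- col + 1
    fcol <- numeric(nrow(obs))
    for (pk in names(prep$patterns)) {
      pat <- prep$patterns[[pk]]
      O <- pat$traits
      Emat <- matrix(ev$resid[pat$rows], ncol = length(O))
      fO <- Emat %*% st$Veinv_pat[[pk]] %*% E[O, O, drop = FALSE]
      fcol[pat$rows] <- fO
    }
    Fm[, col] <- fcol
  }
  RF <- apply_Rinv(prep, ev$Veinv_pat, Fm)
  S <- as.matrix(Matrix::crossprod(prep$W, RF))
  Tm <- backsolve(ev$ch, backsolve(ev$ch, S, transpose = TRUE))
  PF <- RF - apply_Rinv(prep, ev$Veinv_pat, as.matrix(prep$W %*% Tm))
  0.5 * crossprod(Fm, PF)
}

theta_to_vc <- function(theta, pairs, nt) {
  mk <- function(v) {
    m <- matrix(0, nt, nt)
    for (i in seq_along(pairs)) {
      r <- pairs[[i]][1]; s <- pairs[[i]][2]
      m[r, s] <- m[s, r] <- v[i]
    }
    m
  }
  np <- length(pairs)
  list(Va = mk(theta[seq_len(np)]),
       Vp = mk(theta[np + seq_len(np)]),
       Ve = mk(theta[2 * np + seq_len(np)]))
}

vc_to_theta <- function(vc, pairs) {
  grab <- function(m) vapply(pairs, function(pr) m[pr[1], pr[2]], numeric(1))
  c(grab(vc$Va), grab(vc$Vp), grab(vc$Ve))
}

all_pd <- function(vc) {
  ok <- function(m) inherits(tryCatch(chol(m), error = function(e) e), "matrix")
  ok(vc$Va) && ok(vc$Vp) && ok(vc$Ve)
}

# Jacobian d vech(L L') / d vech(L) for one lower-triangular factor;
# AI-Newton steps are taken on the Cholesky scale so every proposal stays
# in the PSD cone
chol_jacobian <- function(L, pairs) {
  np <- length(pairs)
  J <- matrix(0, np, np)
  for (p in seq_len(np)) {
    r <- pairs[[p]][1]; s <- pairs[[p]][2]
    for (q in seq_len(np)) {
      a <- pairs[[q]][1]; b <- pairs[[q]][2]
      J[p, q] <- (r == a) * L[s, b] + (s == a) * L[r, b]
    }
  }
  J
}

vc_to_chol_theta <- function(vc, pairs) {
  grab <- function(m) {
    L <- t(chol(m))
    vapply(pairs, function(pr) L[pr[1], pr[2]], numeric(1))
  }
  c(grab(vc$Va), grab(vc$Vp), grab(vc$Ve))
}

chol_theta_to_vc <- function(thc, pairs, nt) {
  mk <- function(v) {
    L <- matrix(0, nt, nt)
    for (i in seq_along(pairs)) L[pairs[[i]][1], pairs[[i]][2]] <- v[i]
    tcrossprod(L)
  }
  np <- length(pairs)
  list(Va = mk(thc[seq_len(np)]), Vp = mk(thc[np + seq_len(np)]),
       Ve = mk(thc[2 * np + seq_len(np)]))
}

#' Fit the multi-trait repeatability model by REML
#'
#' Estimates the additive-genetic (Va), permanent-environment (Vp) and
#' residual (Ve) covariance matrices of the genomic-polygenic repeatability
#' model by restricted maximum likelihood. Iterations are EM steps (which
#' never decrease the restricted likelihood) accelerated by
#' average-information (AI) proposals; an AI proposal is accepted only when
#' it keeps all three matrices positive definite and does not fall below the
#' EM candidate's likelihood. Convergence is declared when the largest
#' absolute relative parameter change drops below `tol`.
#'
#' @param design An [build_design()] object.
#' @param K_inv Inverse relationship matrix for the additive effect (H^-1
#'   for single-step, A^-1 for pedigree-only), ordered like
#'   `design$animals`.
#' @param start Optional starting `list(Va, Vp, Ve)`; the default splits the
#'   per-trait sample variance equally across the three components.
#' @param max_iter,tol Iteration controls (defaults 200 and 1e-8).
#' @param use_ai Logical: attempt AI acceleration (default TRUE).
#' @param verbose Print per-iteration progress.
#' @return An object of class `ssgwas_reml` with elements `Va`, `Vp`, `Ve`,
#'   `logL`, `trace` (per-iteration tibble), `converged`, `iterations`, and
#'   `solutions` (the [solve_mme()] output at the final estimates).
#' @export
reml_fit <- function(design, K_inv, start = NULL, max_iter = 200L,
                     tol = 1e-8, use_ai = TRUE, verbose = FALSE) {
  stopifnot(inherits(design, "mme_design"))
  nt <- design$nt
  prep <- mme_prepare(design, K_inv)
  attr(prep, "rec_a") <- match(design$record_animal, design$animals)
  attr(prep, "rec_p") <- match(design$record_animal, design$pe_animals)
  pairs <- vech_pairs(nt)
  if (is.null(start)) {
    sv <- vapply(seq_len(nt), function(k)
      var(design$obs$y[design$obs$trait == k]), numeric(1))
    sv[!is.finite(sv) | sv <= 0] <- 1
    start <- list(Va = diag(sv / 3, nt), Vp = diag(sv / 3, nt),
                  Ve = diag(sv / 3, nt))
  }
  check_psd(start$Va); check_psd(start$Vp); check_psd(start$Ve)
  vc <- start
  ev <- mme_evaluate(prep, vc, need_inverse = TRUE)
  if (!is.finite(ev$logL)) stop_ssgwas("non-finite restricted likelihood at start")
  trace <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    st <- mme_statistics(prep, ev)
    cand_em <- em_update(prep, st)
    ev_em <- mme_evaluate(prep, cand_em)
    best <- list(vc = cand_em, ev = ev_em, kind = "em")
    if (use_ai && it > 1) {
      g <- reml_score(prep, ev, st, pairs)
      AI <- ai_matrix(prep, ev, st, pairs)
      theta <- vc_to_theta(vc, pairs)
      dtheta <- tryCatch(
        solve(AI + diag(1e-8 * max(diag(AI)), nrow(AI)), g),
        error = function(e) NULL)
      if (!is.null(dtheta)) {
        ## halve the Newton step until the proposal is PD; evaluate that
        ## single candidate and keep it only when it beats the EM step, so
        ## likelihood ascent is preserved
        steps <- 1 / 2^(0:7)
        pd_at <- which(vapply(steps, function(s)
          all_pd(theta_to_vc(theta + s * dtheta, pairs, nt)), logical(1)))
        if (length(pd_at)) {
          cand <- theta_to_vc(theta + steps[pd_at[1]] * dtheta, pairs, nt)
          ev_ai <- tryCatch(mme_evaluate(prep, cand), error = function(e) NULL)
          if (!is.null(ev_ai) && is.finite(ev_ai$logL) &&
              ev_ai$logL > best$ev$logL)
            best <- list(vc = cand, ev = ev_ai, kind = "ai")
        }
      }
    }
    if (best$kind == "em" && it >= 3) {
      ## slow-tail acceleration: take a second EM step and attempt a
      ## SQUAREM-style extrapolation along the EM trajectory; both
      ## candidates are safeguarded by the likelihood comparison
      ev_em_full <- best$ev
      ev_em_full$Cinv <- chol2inv(ev_em_full$ch)
      st2 <- mme_statistics(prep, ev_em_full)
      cand_em2 <- em_update(prep, st2)
      ev_em2 <- mme_evaluate(prep, cand_em2)
      if (is.finite(ev_em2$logL) && ev_em2$logL >= best$ev$logL)
        best <- list(vc = cand_em2, ev = ev_em2, kind = "em")
      t0 <- vc_to_theta(vc, pairs)
      t1 <- vc_to_theta(cand_em, pairs)
      t2 <- vc_to_theta(cand_em2, pairs)
      rr <- t1 - t0
      vv <- t2 - 2 * t1 + t0
      if (sum(vv^2) > 0) {
        alpha <- -sqrt(sum(rr^2) / sum(vv^2))
        cand_sq <- theta_to_vc(t0 - 2 * alpha * rr + alpha^2 * vv, pairs, nt)
        cand_sq <- list(Va = psd_project(cand_sq$Va, quiet = TRUE),
                        Vp = psd_project(cand_sq$Vp, quiet = TRUE),
                        Ve = psd_project(cand_sq$Ve, quiet = TRUE))
        if (all_pd(cand_sq)) {
          ev_sq <- tryCatch(mme_evaluate(prep, cand_sq),
                            error = function(e) NULL)
          if (!is.null(ev_sq) && is.finite(ev_sq$logL) &&
              ev_sq$logL > best$ev$logL)
            best <- list(vc = cand_sq, ev = ev_sq, kind = "em_accel")
        }
      }
    }
    theta_old <- vc_to_theta(vc, pairs)
    theta_new <- vc_to_theta(best$vc, pairs)
    scale <- max(abs(theta_new), .Machine$double.eps)
    delta <- max(abs(theta_new - theta_old) /
                   pmax(abs(theta_old), abs(theta_new), 1e-4 * scale))
    vc <- best$vc
    trace[[it]] <- tibble(iteration = it, logL = best$ev$logL,
                          step = best$kind, max_rel_change = delta)
    if (verbose)
      inform(sprintf("iter %3d  logL %.6f  step %s  delta %.3e",
                     it, best$ev$logL, best$kind, delta))
    ## reuse the accepted candidate's factorisation; only the inverse is new
    ev <- best$ev
    ev$Cinv <- chol2inv(ev$ch)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warn(sprintf("REML did not reach tol %.1e within %d iterations", tol,
                 max_iter))
  vc$Va <- psd_project(vc$Va); vc$Vp <- psd_project(vc$Vp)
  vc$Ve <- psd_project(vc$Ve)
  dimnames(vc$Va) <- dimnames(vc$Vp) <- dimnames(vc$Ve) <-
    list(design$traits, design$traits)
  sols <- extract_solutions(design, prep, ev)
  structure(list(Va = vc$Va, Vp = vc$Vp, Ve = vc$Ve, logL = ev$logL,
                 trace = bind_rows(trace), converged = converged,
                 iterations = length(trace), solutions = sols,
                 n_obs = nrow(design$obs), n_records = design$n_records,
                 traits = design$traits),
            class = "ssgwas_reml")
}

#' Solve the mixed-model equations at fixed variance components
#'
#' Henderson's MME for the multi-trait repeatability model with Kronecker
#' covariance structure (K (x) Va for the additive effect, I (x) Vp for the
#' permanent environment, record-wise Ve for the residual).
#'
#' @inheritParams reml_fit
#' @param vc List with PSD matrices `Va`, `Vp`, `Ve`.
#' @return An object of class `mme_solution`: tibbles `gebv` (animal, trait,
#'   gebv — all animals in `design$animals`), `fixed` (term, trait,
#'   estimate), `pe`, `residuals`, plus the restricted log-likelihood.
#' @export
solve_mme <- function(design, K_inv, vc) {
  stopifnot(inherits(design, "mme_design"))
  check_psd(vc$Va); check_psd(vc$Vp); check_psd(vc$Ve)
  prep <- mme_prepare(design, K_inv)
  ev <- mme_evaluate(prep, vc)
  extract_solutions(design, prep, ev)
}

extract_solutions <- function(design, prep, ev) {
  nt <- design$nt
  sol <- ev$sol
  p0 <- prep$p0
  fixed <- tibble(
    term = rep(colnames(design$X0), each = nt),
    trait = rep(design$traits, p0),
    estimate = sol[seq_len(p0 * nt)])
  gebv <- tibble(
    animal = rep(design$animals, each = nt),
    trait = rep(design$traits, prep$q),
    gebv = sol[prep$off_a + seq_len(prep$q * nt)])
  pe <- tibble(
    animal = rep(design$pe_animals, each = nt),
    trait = rep(design$traits, prep$qp),
    pe = sol[prep$off_p + seq_len(prep$qp * nt)])
  resid <- design$obs
  resid$fitted <- resid$y - ev$resid
  resid$residual <- ev$resid
  resid$trait <- design$traits[resid$trait]
  structure(list(fixed = fixed, gebv = gebv, pe = pe,
                 residuals = as_tibble(resid), logL = ev$logL),
            class = "mme_solution")
}

#' @export
print.mme_solution <- function(x, ...) {
  cat(sprintf("<mme_solution> %d breeding values, logL = %.4f\n",
              nrow(x$gebv), x$logL))
  invisible(x)
}

#' @export
print.ssgwas_reml <- function(x, ...) {
  cat(sprintf("<ssgwas_reml> %s after %d iterations (logL %.4f)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$logL))
  cat("heritabilities:",
      paste(sprintf("%s %.3f", x$traits, heritability(x)$h2), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-trait heritability and repeatability from a REML fit
#'
#' h2 = Va_tt / (Va_tt + Vp_tt + Ve_tt); repeatability adds Vp to the
#' numerator.
#'
#' @param fit An `ssgwas_reml` object.
#' @return A tibble with columns `trait`, `sigma_a2`, `sigma_p2`,
#'   `sigma_e2`, `h2`, `repeatability`.
#' @export
heritability <- function(fit) {
  va <- diag(fit$Va); vp <- diag(fit$Vp); ve <- diag(fit$Ve)
  tot <- va + vp + ve
  tibble(trait = fit$traits, sigma_a2 = va, sigma_p2 = vp, sigma_e2 = ve,
         h2 = va / tot, repeatability = (va + vp) / tot)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy ssgwas_reml
#' @rdname reml_fit
#' @param x An `ssgwas_reml` object.
#' @param ... Unused.
tidy.ssgwas_reml <- function(x, ...) {
  nt <- length(x$traits)
  comp <- function(m, name) {
    idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
    tibble(component = name, trait1 = x$traits[idx[, 1]],
           trait2 = x$traits[idx[, 2]], estimate = m[idx])
  }
  bind_rows(comp(x$Va, "additive"), comp(x$Vp, "permanent_env"),
            comp(x$Ve, "residual"))
}

#' @export
#' @method glance ssgwas_reml
#' @rdname reml_fit
glance.ssgwas_reml <- function(x, ...) {
  tibble(logLik = x$logL, iterations = x$iterations,
         converged = x$converged, n_obs = x$n_obs, n_records = x$n_records)
}

#' @export
#' @method tidy mme_solution
tidy.mme_solution <- function(x, ...) x$gebv

#' @export
#' @method glance mme_solution
glance.mme_solution <- function(x, ...) {
  tibble(logLik = x$logL, n_animals = length(unique(x$gebv$animal)),
         n_obs = nrow(x$residuals))
}
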