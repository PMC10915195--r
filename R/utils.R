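#' @importFrom rlang abort warn inform %||% .data .env
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows bind_cols distinct n rename relocate
#'   across pull
#' @importFrom stats var rnorm runif rbinom setNames model.matrix phyper
#'   p.adjust sd
#' @importFrom utils head tail
NULL

# natural ordering for chromosome labels: numeric labels first in numeric
# order (1,2,...,10 not 1,10,2), then non-numeric labels (X, MT, ...)
# alphabetically; stable for ties.
chrom_order <- function(chrom) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, chrom)
}

chrom_rank <- function(chrom) {
  lev <- unique(as.character(chrom))
  lev <- lev[chrom_order(lev)]
  match(as.character(chrom), lev)
}

stop_ssgwas <- function(msg, ...) {
  abort(paste0(msg, ...), class = "ssgwas_error")
}

check_square <- function(m, name = deparse(substitute(m))) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_ssgwas(sprintf("`%s` must be a square matrix", name))
  invisible(m)
}

# symmetric PSD check with a small tolerance relative to the largest eigenvalue
check_psd <- function(m, name = deparse(substitute(m)), tol = 1e-8) {
  check_square(m, name)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop_ssgwas(sprintf("`%s` must be symmetric", name))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev))))
    stop_ssgwas(sprintf("`%s` must be positive semi-definite", name))
  invisible(m)
}

# clip negative eigenvalues so a covariance matrix stays usable in solves;
# warns when a meaningful clip happened
psd_project <- function(m, floor_frac = 1e-10, quiet = FALSE) {
  m <- (m + t(m)) / 2
  es <- eigen(m, symmetric = TRUE)
  fl <- floor_frac * max(abs(es$values), .Machine$double.eps)
  if (min(es$values) < fl) {
    if (!quiet && min(es$values) < -1e-6 * max(abs(es$values)))
      warn("covariance matrix projected onto the PSD cone (negative eigenvalue clipped)")
    es$values <- pmax(es$values, fl)
    m <- es$vectors %*% (es$values * t(es$vectors))
    m <- (m + t(m)) / 2
  }
  m
}

offdiag_mean <- function(m) {
  n <- nrow(m)
  if (n < 2) return(NA_real_)
  (sum(m) - sum(diag(m))) / (n * (n - 1))
}

# split one RNG seed into reproducible per-stage child seeds (< 2^31)
child_seed <- function(seed, stage) {
  (as.numeric(seed) * 1000003 + stage * 7919) %% 2147483647
}
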