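# exhaustive two-sided hypergeometric by enumerating all C(N, n) draws
enum_two_sided <- function(k, K, n, N) {
  pool <- c(rep(1, K), rep(0, N - K))
  draws <- utils::combn(N, n)
  overlaps <- colSums(matrix(pool[draws], nrow = n))
  lower <- mean(overlaps <= k)
  upper <- mean(overlaps >= k)
  min(1, 2 * min(lower, upper))
}

# by-hand Holm procedure: sort, multiply by (m - i + 1), cummax, cap
holm_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}
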