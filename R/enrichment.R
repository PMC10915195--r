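#' Two-sided hypergeometric test
#'
#' For X ~ Hypergeometric(N, K, n) (a selection of n from a background of N
#' containing K pathway members, k of which were selected), the two-sided p
#' is min(1, 2 min(P\[X <= k\], P\[X >= k\])): tail doubling capped at one.
#' Tails are computed with `stats::phyper()`.
#'
#' @param k Selected genes in the pathway.
#' @param K Background genes in the pathway.
#' @param n Selected genes in the background.
#' @param N Background size.
#' @param alternative `"two_sided"` (default) doubles the smaller tail;
#'   `"min_lik_sum"` sums the probabilities of all outcomes no more likely
#'   than k (the minimum-likelihood alternative definition).
#' @return The p-value (vectorized over `k`, `K`, `n`).
#' @export
hypergeom_two_sided <- function(k, K, n, N,
                                alternative = c("two_sided", "min_lik_sum")) {
  alternative <- match.arg(alternative)
  args <- vapply(list(k = k, K = K, n = n, N = N), function(x)
    any(x < 0 | x != round(x)), logical(1))
  if (any(args)) stop_ssgwas("all arguments must be non-negative integers")
  if (any(K > N) || any(n > N)) stop_ssgwas("K and n must not exceed N")
  if (any(k > pmin(n, K)) || any(k < pmax(0, n + K - N)))
    stop_ssgwas("k outside the hypergeometric support")
  if (alternative == "two_sided") {
    lower <- phyper(k, K, N - K, n)
    upper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    pmin(1, 2 * pmin(lower, upper))
  } else {
    purrr::pmap_dbl(list(k, K, n, N), function(k1, K1, n1, N1) {
      supp <- max(0, n1 + K1 - N1):min(n1, K1)
      d <- stats::dhyper(supp, K1, N1 - K1, n1)
      min(1, sum(d[d <= d[supp == k1] * (1 + 1e-12)]))
    })
  }
}

#' Step-down multiple-testing correction (Holm)
#'
#' The sequentially rejective Bonferroni procedure: sort p ascending,
#' multiply the i-th by (m - i + 1), enforce monotonicity, cap at 1, return
#' in the input order. Delegates to `stats::p.adjust(method = "holm")`.
#'
#' @param p_raw Numeric vector of raw p-values in \\[0, 1\\].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_stepdown <- function(p_raw) {
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE))
    stop_ssgwas("p-values must lie in [0, 1]")
  p.adjust(p_raw, method = "holm")
}

#' Pathway enrichment of a selected gene set
#'
#' One two-sided hypergeometric test per pathway with at least one member in
#' the background, followed by the step-down correction across the tested
#' pathways. A pathway is `enriched` when the observed overlap exceeds its
#' expectation n K / N, `depleted` otherwise; it is significant when the
#' adjusted p is strictly below `alpha`.
#'
#' @param selected_genes Character vector of selected gene ids.
#' @param pathways Long tibble (`pathway`, `name`, `gene`) from
#'   [read_gmt()].
#' @param background Character vector: the gene universe. The recommended
#'   choice (used by [run_pipeline()]) is every annotation gene that appears
#'   in the pathway database.
#' @param alpha Significance level (strict `<`), default 0.05.
#' @param alternative Passed to [hypergeom_two_sided()].
#' @return A tibble: `pathway`, `name`, `k`, `K`, `n`, `N`, `p_raw`,
#'   `p_adj`, `direction`, `significant`.
#' @export
enrich_pathways <- function(selected_genes, pathways, background,
                            alpha = 0.05,
                            alternative = "two_sided") {
  background <- unique(background)
  if (!length(background)) stop_ssgwas("empty background gene universe")
  N <- length(background)
  selected <- unique(intersect(selected_genes, background))
  n <- length(selected)
  pw <- pathways |>
    filter(.data$gene %in% background) |>
    group_by(.data$pathway, .data$name) |>
    summarise(K = dplyr::n_distinct(.data$gene),
              k = dplyr::n_distinct(intersect(.data$gene, selected)),
              .groups = "drop")
  if (!nrow(pw))
    return(tibble(pathway = character(0), name = character(0),
                  k = integer(0), K = integer(0), n = integer(0),
                  N = integer(0), p_raw = numeric(0), p_adj = numeric(0),
                  direction = character(0), significant = logical(0)))
  p_raw <- hypergeom_two_sided(pw$k, pw$K, n, N, alternative = alternative)
  tibble(pathway = pw$pathway, name = pw$name, k = pw$k, K = pw$K,
         n = n, N = N, p_raw = p_raw, p_adj = holm_stepdown(p_raw),
         direction = ifelse(pw$k > n * pw$K / N, "enriched", "depleted"),
         significant = holm_stepdown(p_raw) < alpha) |>
    arrange(.data$p_adj, .data$pathway)
}
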