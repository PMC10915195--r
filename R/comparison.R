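#' Pairwise comparison of window schemes by shared pathways and genes
#'
#' For every pair of schemes, NP counts the significant pathways the two
#' schemes share, and NG counts the genes belonging to those shared
#' pathways among the genes the schemes identified. The gene lists of the
#' two schemes are combined by intersection (default) or union before
#' restricting to the shared pathways' members; diagonals hold each
#' scheme's own counts.
#'
#' @param enrichment Tibble of [enrich_pathways()] results for all schemes,
#'   with an extra `scheme` column (all computed against the same pathway
#'   database and background).
#' @param gene_sets Named list: scheme -> character vector of identified
#'   genes.
#' @param pathways Long pathway tibble (`pathway`, `gene`).
#' @param ng_mode `"intersection"` or `"union"` of the two schemes' gene
#'   lists.
#' @return An object of class `scheme_comparison`: integer matrices `NP`
#'   and `NG` (schemes x schemes), the scheme order, and `ng_mode`.
#' @export
compare_schemes <- function(enrichment, gene_sets, pathways,
                            ng_mode = c("intersection", "union")) {
  ng_mode <- match.arg(ng_mode)
  schemes <- names(gene_sets)
  if (is.null(schemes) || !length(schemes))
    stop_ssgwas("gene_sets must be a named list keyed by scheme")
  if (!all(unique(enrichment$scheme) %in% schemes))
    stop_ssgwas("enrichment contains schemes absent from gene_sets")
  if (length(unique(enrichment$N)) > 1)
    stop_ssgwas("schemes were tested against different backgrounds")
  sig <- purrr::map(setNames(schemes, schemes), function(s) {
    unique(enrichment$pathway[enrichment$scheme == s & enrichment$significant])
  })
  members <- split(pathways$gene, pathways$pathway)
  ns <- length(schemes)
  NP <- matrix(0L, ns, ns, dimnames = list(schemes, schemes))
  NG <- matrix(0L, ns, ns, dimnames = list(schemes, schemes))
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    shared <- intersect(sig[[i]], sig[[j]])
    NP[i, j] <- length(shared)
    genes_ij <- if (i == j) gene_sets[[i]]
                else if (ng_mode == "intersection")
                  intersect(gene_sets[[i]], gene_sets[[j]])
                else union(gene_sets[[i]], gene_sets[[j]])
    shared_members <- unique(unlist(members[shared], use.names = FALSE))
    NG[i, j] <- length(intersect(genes_ij, shared_members))
  }
  structure(list(schemes = schemes, NP = NP, NG = NG, ng_mode = ng_mode),
            class = "scheme_comparison")
}

#' @export
print.scheme_comparison <- function(x, ...) {
  cat(sprintf("<scheme_comparison> %d schemes (NG mode: %s)\n",
              length(x$schemes), x$ng_mode))
  cat("NP (shared significant pathways):\n")
  print(x$NP)
  cat("NG (genes in shared pathways):\n")
  print(x$NG)
  invisible(x)
}

#' @export
#' @method tidy scheme_comparison
#' @rdname compare_schemes
#' @param x A `scheme_comparison` object.
#' @param ... Unused.
tidy.scheme_comparison <- function(x, ...) {
  grid <- expand.grid(scheme1 = x$schemes, scheme2 = x$schemes,
                      stringsAsFactors = FALSE)
  tibble(scheme1 = grid$scheme1, scheme2 = grid$scheme2,
         np = as.integer(x$NP[cbind(grid$scheme1, grid$scheme2)]),
         ng = as.integer(x$NG[cbind(grid$scheme1, grid$scheme2)]))
}

#' Rank schemes and flag the dominant overlap mode
#'
#' Ranks schemes by their own significant-pathway and gene counts (the
#' diagonals) and, when scheme names carry an `overlapping` /
#' `non_overlapping` mode with matching sizes, reports which mode dominates
#' pairwise.
#'
#' @param cm A `scheme_comparison`.
#' @return A list with `ranking` (tibble) and `mode_dominance` (tibble or
#'   NULL).
#' @export
summarize_comparison <- function(cm) {
  stopifnot(inherits(cm, "scheme_comparison"))
  if (length(cm$schemes) < 2)
    stop_ssgwas("need at least two schemes to compare")
  ranking <- tibble(scheme = cm$schemes,
                    np = diag(cm$NP), ng = diag(cm$NG)) |>
    arrange(dplyr::desc(.data$np), dplyr::desc(.data$ng)) |>
    mutate(rank = dplyr::min_rank(dplyr::desc(.data$np)))
  mode_dom <- NULL
  m <- regmatches(cm$schemes,
                  regexec("^sw(\\d+)_(overlapping|non_overlapping)$",
                          cm$schemes))
  if (all(lengths(m) == 3)) {
    info <- tibble(scheme = cm$schemes,
                   w = as.integer(vapply(m, `[`, character(1), 2)),
                   mode = vapply(m, `[`, character(1), 3))
    wide <- info |>
      mutate(np = diag(cm$NP)[match(.data$scheme, cm$schemes)]) |>
      select("w", "mode", "np") |>
      tidyr::pivot_wider(names_from = "mode", values_from = "np")
    if (all(c("overlapping", "non_overlapping") %in% names(wide)))
      mode_dom <- mutate(wide, overlapping_dominates =
                           .data$overlapping >= .data$non_overlapping)
  }
  list(ranking = ranking, mode_dominance = mode_dom)
}
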