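#' Assign each SNP to its nearest gene and a distance bin
#'
#' A SNP inside one or more genes gets bin `"inside"` (distance 0) and the
#' smallest-span containing gene. Otherwise the nearest gene on the same
#' chromosome minimises min(|bp - start|, |bp - end|); ties are broken by
#' lexicographic gene id. Distance bins (upper edge inclusive):
#' `d1_within_2500` (0, 2500\], `d2_2500_5000` (2500, 5000\],
#' `d3_5000_25000` (5000, 25000\], `d4_beyond_25000` (25000, Inf). SNPs on a
#' chromosome with no annotated gene report gene `NA` and bin
#' `d4_beyond_25000`.
#'
#' @param snps Tibble with columns `marker`, `chrom`, `pos_bp` (extra
#'   columns such as `trait` are preserved).
#' @param ann Gene annotation tibble from [read_annotation()].
#' @return The input rows with `gene_id`, `distance_bp` and `bin` appended.
#' @export
assign_nearest_gene <- function(snps, ann) {
  snps <- as_tibble(snps)
  ann <- as_tibble(ann)
  if (!nrow(snps))
    return(mutate(snps, gene_id = character(0), distance_bp = numeric(0),
                  bin = character(0)))
  uniq <- distinct(snps, .data$marker, .data$chrom, .data$pos_bp)
  assign_one_chrom <- function(sub, genes) {
    if (!nrow(genes)) {
      return(mutate(sub, gene_id = NA_character_, distance_bp = NA_real_,
                    bin = "d4_beyond_25000"))
    }
    res <- purrr::pmap(list(sub$pos_bp), function(pos) {
      inside <- genes$start_bp <= pos & genes$end_bp >= pos
      if (any(inside)) {
        cand <- genes[inside, , drop = FALSE]
        span <- cand$end_bp - cand$start_bp
        cand <- cand[order(span, cand$gene_id), , drop = FALSE]
        tibble(gene_id = cand$gene_id[1], distance_bp = 0)
      } else {
        d <- pmin(abs(pos - genes$start_bp), abs(pos - genes$end_bp))
        cand <- genes[order(d, genes$gene_id), , drop = FALSE]
        tibble(gene_id = cand$gene_id[1], distance_bp = min(d))
      }
    })
    bind_cols(sub, bind_rows(res))
  }
  out <- uniq |>
    dplyr::group_split(.data$chrom) |>
    purrr::map(function(sub) {
      assign_one_chrom(sub, ann[ann$chrom == sub$chrom[1], , drop = FALSE])
    }) |>
    bind_rows() |>
    mutate(bin = dplyr::case_when(
      is.na(.data$distance_bp) ~ "d4_beyond_25000",
      .data$distance_bp == 0 ~ "inside",
      .data$distance_bp <= 2500 ~ "d1_within_2500",
      .data$distance_bp <= 5000 ~ "d2_2500_5000",
      .data$distance_bp <= 25000 ~ "d3_5000_25000",
      TRUE ~ "d4_beyond_25000"))
  left_join(snps, out, by = c("marker", "chrom", "pos_bp"))
}

#' Distance-bin count tables (per scheme)
#'
#' Counts SNPs and distinct genes in each distance bin per window scheme,
#' plus totals, mirroring the classic
#' "inside / 1-2500 / 2500-5000 / 5000-25000 / >25000" layout.
#'
#' @param assignments Tibble from [assign_nearest_gene()] with an extra
#'   `scheme` column (and optionally `trait`).
#' @return A tibble: `scheme`, `bin` (including `"total"`), `n_snp`,
#'   `n_gene`.
#' @export
tabulate_bins <- function(assignments) {
  bins <- c("inside", "d1_within_2500", "d2_2500_5000", "d3_5000_25000",
            "d4_beyond_25000")
  if (!"scheme" %in% names(assignments))
    assignments$scheme <- "all"
  per_bin <- assignments |>
    group_by(.data$scheme, .data$bin) |>
    summarise(n_snp = dplyr::n_distinct(.data$marker),
              n_gene = dplyr::n_distinct(.data$gene_id[!is.na(.data$gene_id)]),
              .groups = "drop")
  totals <- assignments |>
    group_by(.data$scheme) |>
    summarise(bin = "total", n_snp = dplyr::n_distinct(.data$marker),
              n_gene = dplyr::n_distinct(.data$gene_id[!is.na(.data$gene_id)]),
              .groups = "drop")
  grid <- tidyr::expand_grid(scheme = unique(assignments$scheme), bin = bins)
  per_bin <- left_join(grid, per_bin, by = c("scheme", "bin")) |>
    mutate(n_snp = tidyr::replace_na(.data$n_snp, 0L),
           n_gene = tidyr::replace_na(.data$n_gene, 0L))
  bind_rows(per_bin, totals) |>
    arrange(.data$scheme, match(.data$bin, c(bins, "total")))
}
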