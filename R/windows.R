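#' Default per-size selection threshold
#'
#' The minimum percentage of the additive genetic variance a window must
#' explain for its SNPs to be selected: 0.001% for 1-SNP windows, 0.01% for
#' 10, 0.03% for 30, 0.05% for 50 and 0.1% for 100-SNP windows. Other sizes
#' have no default and must be supplied explicitly.
#'
#' @param w Window size in SNPs.
#' @return The threshold in percent.
#' @export
default_threshold <- function(w) {
  thr <- c(`1` = 0.001, `10` = 0.01, `30` = 0.03, `50` = 0.05, `100` = 0.1)
  key <- as.character(as.integer(w))
  if (!key %in% names(thr))
    stop_ssgwas("no default selection threshold for window size ", w,
                "; supply one explicitly")
  unname(thr[key])
}

#' Build SNP windows over a marker map
#'
#' Windows are runs of `w` consecutive markers within a chromosome (marker
#' index, not bp span). Overlapping windows shift by one marker: (1..w),
#' (2..w+1), ...; a chromosome with fewer than `w` markers yields none.
#' Non-overlapping windows shift by `w` and the final partial window is
#' kept, so they partition the chromosome. With `w = 1` both modes coincide.
#'
#' @param map Marker map tibble (`marker`, `chrom`, `pos_bp`), sorted as in
#'   a [geno_mat()].
#' @param w Window size (SNPs).
#' @param mode `"overlapping"` or `"non_overlapping"`.
#' @return A tibble of class `window_scheme`: `window_id`, `chrom`,
#'   `start_idx`, `end_idx` (within-chromosome marker indices, inclusive),
#'   `start_bp`, `end_bp`, with attributes `w` and `mode`.
#' @export
build_windows <- function(map, w, mode = c("overlapping", "non_overlapping")) {
  mode <- match.arg(mode)
  if (w < 1) stop_ssgwas("window size must be >= 1")
  map <- as_tibble(map)
  if (!nrow(map)) stop_ssgwas("empty marker map")
  chroms <- unique(map$chrom)
  out <- purrr::map(chroms, function(cc) {
    sub <- map[map$chrom == cc, , drop = FALSE]
    m <- nrow(sub)
    if (mode == "overlapping") {
      if (m < w) return(NULL)
      start <- seq_len(m - w + 1)
      end <- start + w - 1
    } else {
      start <- seq(1, m, by = w)
      end <- pmin(start + w - 1, m)
    }
    tibble(chrom = cc, start_idx = start, end_idx = end,
           start_bp = sub$pos_bp[start], end_bp = sub$pos_bp[end])
  })
  out <- bind_rows(out)
  if (nrow(out))
    out <- tibble(window_id = sprintf("w%d_%s_%05d", w,
                                      substr(mode, 1, 1), seq_len(nrow(out))),
                  out)
  else
    out <- tibble(window_id = character(0), chrom = character(0),
                  start_idx = integer(0), end_idx = integer(0),
                  start_bp = integer(0), end_bp = integer(0))
  attr(out, "w") <- as.integer(w)
  attr(out, "mode") <- mode
  class(out) <- c("window_scheme", class(out))
  out
}

# marker-index bookkeeping: per window, the (global) map rows it covers;
# within-chromosome map rows are contiguous, so the expansion is vectorised
window_members <- function(windows, map) {
  map <- as_tibble(map)
  if (!nrow(windows))
    return(tibble(window_id = character(0), marker = character(0)))
  rows_by_chrom <- split(seq_len(nrow(map)), map$chrom)
  first_row <- vapply(rows_by_chrom, `[`, numeric(1), 1)
  lens <- windows$end_idx - windows$start_idx + 1L
  base <- first_row[windows$chrom] + windows$start_idx - 1L
  rowidx <- sequence(lens, from = base)
  tibble(window_id = rep(windows$window_id, lens),
         marker = map$marker[rowidx])
}

#' Aggregate per-SNP variances into window variances
#'
#' Var(a_i) for window i is the sum of the per-SNP variances of its markers;
#' the percentage column divides by the trait's total additive genetic
#' variance (x100).
#'
#' @param windows A [build_windows()] scheme.
#' @param snp_table Tidy per-SNP table from [snp_effect_table()] (columns
#'   `marker`, `trait`, `variance`).
#' @param sigma_a2 Named vector of total additive variance per trait.
#' @return A `window_variance_tbl` tibble: `window_id`, `chrom`, `start_bp`,
#'   `end_bp`, `trait`, `var_ai`, `pct` (carries the scheme attributes).
#' @export
aggregate_windows <- function(windows, snp_table, sigma_a2) {
  if (any(sigma_a2 <= 0)) stop_ssgwas("sigma_a2 must be positive")
  members <- window_members(windows, distinct(snp_table, .data$marker,
                                              .data$chrom, .data$pos_bp))
  joined <- inner_join(members, snp_table, by = "marker",
                       relationship = "many-to-many")
  out <- joined |>
    group_by(.data$window_id, .data$trait) |>
    summarise(var_ai = sum(.data$variance), .groups = "drop") |>
    inner_join(select(windows, "window_id", "chrom", "start_bp", "end_bp"),
               by = "window_id") |>
    mutate(pct = .data$var_ai / unname(sigma_a2[.data$trait]) * 100) |>
    relocate("window_id", "chrom", "start_bp", "end_bp", "trait",
             "var_ai", "pct") |>
    arrange(match(.data$window_id, windows$window_id), .data$trait)
  attr(out, "w") <- attr(windows, "w")
  attr(out, "mode") <- attr(windows, "mode")
  class(out) <- c("window_variance_tbl", class(out))
  out
}

#' Select SNPs from windows passing a threshold
#'
#' A marker is selected (per trait) when it lies in at least one window
#' whose percentage of the additive genetic variance is greater than or
#' equal to the threshold ("at least": inclusive comparison).
#'
#' @param wvt A `window_variance_tbl` from [aggregate_windows()].
#' @param windows The matching [build_windows()] scheme.
#' @param map The marker map the scheme was built on.
#' @param threshold_pct Threshold in percent; defaults to
#'   [default_threshold()] of the scheme's window size.
#' @return A tibble `marker`, `chrom`, `pos_bp`, `trait` of selected SNPs.
#' @export
select_snps <- function(wvt, windows, map,
                        threshold_pct = default_threshold(attr(windows, "w"))) {
  if (threshold_pct < 0) stop_ssgwas("threshold must be >= 0")
  passing <- filter(wvt, .data$pct >= threshold_pct)
  members <- window_members(windows, map)
  sel <- inner_join(members,
                    select(passing, "window_id", "trait"),
                    by = "window_id", relationship = "many-to-many") |>
    distinct(.data$marker, .data$trait)
  map <- as_tibble(map)
  inner_join(sel, select(map, "marker", "chrom", "pos_bp"), by = "marker") |>
    relocate("marker", "chrom", "pos_bp", "trait") |>
    arrange(chrom_rank(.data$chrom), .data$pos_bp, .data$trait)
}
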