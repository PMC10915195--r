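map_for <- function(m_per_chrom) {
  tibble::tibble(
    marker = sprintf("m%03d", seq_len(sum(m_per_chrom))),
    chrom = rep(as.character(seq_along(m_per_chrom)), m_per_chrom),
    pos_bp = as.integer(unlist(lapply(m_per_chrom, function(m)
      seq(1000, by = 1000, length.out = m)))))
}

test_that("window construction follows the shift-by-one and partition rules", {
  map <- map_for(12)
  ov <- build_windows(map, 10, "overlapping")
  expect_equal(nrow(ov), 3)
  expect_equal(ov$start_idx, 1:3)
  expect_equal(ov$end_idx, 10:12)

  nov <- build_windows(map, 10, "non_overlapping")
  expect_equal(nrow(nov), 2)
  expect_equal(nov$start_idx, c(1L, 11L))
  expect_equal(nov$end_idx, c(10L, 12L))   # final partial window kept

  ## w = 1: both modes give one window per marker
  expect_equal(nrow(build_windows(map, 1, "overlapping")), 12)
  expect_equal(nrow(build_windows(map, 1, "non_overlapping")), 12)

  ## chromosome shorter than w: no overlapping windows, one partial block
  map2 <- map_for(c(12, 5))
  ov2 <- build_windows(map2, 10, "overlapping")
  expect_equal(sum(ov2$chrom == "2"), 0)
  nov2 <- build_windows(map2, 10, "non_overlapping")
  expect_equal(sum(nov2$chrom == "2"), 1)

  expect_error(build_windows(map[0, ], 10), "empty")
})

test_that("window counts satisfy the closed-form bookkeeping on random maps", {
  set.seed(33)
  for (i in 1:20) {
    m_per <- sample(1:40, sample(1:4, 1), replace = TRUE)
    map <- map_for(m_per)
    w <- sample(c(1, 3, 10, 30), 1)
    expect_equal(nrow(build_windows(map, w, "overlapping")),
                 sum(pmax(m_per - w + 1, 0)))
    expect_equal(nrow(build_windows(map, w, "non_overlapping")),
                 sum(ceiling(m_per / w)))
  }
})

snp_table_for <- function(map, v) {
  tibble::tibble(marker = map$marker, chrom = map$chrom, pos_bp = map$pos_bp,
                 trait = "vol", effect = 0, variance = v,
                 pct_sigma_a2 = v / 100 * 100)
}

test_that("window aggregation sums member variances and scales by sigma_a2", {
  map <- map_for(2)
  tab <- snp_table_for(map, c(0.5, 1.5))
  win <- build_windows(map, 2, "non_overlapping")
  wvt <- aggregate_windows(win, tab, c(vol = 100))
  expect_equal(wvt$var_ai, 2.0)
  expect_equal(wvt$pct, 2.0)

  ## all-zero variances give all-zero percentages
  wvt0 <- aggregate_windows(win, snp_table_for(map, c(0, 0)), c(vol = 100))
  expect_equal(wvt0$pct, 0)
  expect_error(aggregate_windows(win, tab, c(vol = 0)), "positive")
})

test_that("non-overlapping windows conserve total variance; overlapping weight by multiplicity", {
  set.seed(44)
  m_per <- c(23, 17)
  map <- map_for(m_per)
  v <- runif(nrow(map))
  tab <- snp_table_for(map, v)
  for (w in c(1, 5, 10)) {
    nov <- build_windows(map, w, "non_overlapping")
    wvt <- aggregate_windows(nov, tab, c(vol = 1))
    expect_equal(sum(wvt$var_ai), sum(v), tolerance = 1e-10)

    ov <- build_windows(map, w, "overlapping")
    if (nrow(ov)) {
      wvt_ov <- aggregate_windows(ov, tab, c(vol = 1))
      ## brute-force membership count per marker
      cnt <- setNames(numeric(nrow(map)), map$marker)
      for (i in seq_len(nrow(ov))) {
        sub <- map$marker[map$chrom == ov$chrom[i]]
        cnt[sub[ov$start_idx[i]:ov$end_idx[i]]] <-
          cnt[sub[ov$start_idx[i]:ov$end_idx[i]]] + 1
      }
      expect_equal(sum(wvt_ov$var_ai), sum(cnt * v), tolerance = 1e-10)
    }
  }
})

test_that("SNP selection is inclusive at the threshold and window-membership based", {
  map <- map_for(12)
  ## craft variances so only the overlapping window (2..11) passes
  v <- rep(0, 12); v[2:11] <- 0.1          # window 2-11 sums to 1.0
  v[1] <- 0; v[12] <- 0
  tab <- snp_table_for(map, v)
  ov <- build_windows(map, 10, "overlapping")
  wvt <- aggregate_windows(ov, tab, c(vol = 100))
  ## thresholds: window sums are (0.9, 1.0, 0.9) percent
  sel <- select_snps(wvt, ov, map, threshold_pct = 1.0)  # exact threshold
  expect_setequal(sel$marker, map$marker[2:11])
  expect_false("m001" %in% sel$marker)

  sel0 <- select_snps(wvt, ov, map, threshold_pct = 0)
  expect_setequal(sel0$marker, map$marker)

  ## monotone shrinkage with growing threshold
  sizes <- vapply(c(0, 0.9, 1.0, 1.1), function(th)
    nrow(select_snps(wvt, ov, map, threshold_pct = th)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("default thresholds match the standard per-size values", {
  expect_equal(default_threshold(1), 0.001)
  expect_equal(default_threshold(10), 0.01)
  expect_equal(default_threshold(30), 0.03)
  expect_equal(default_threshold(50), 0.05)
  expect_equal(default_threshold(100), 0.1)
  expect_error(default_threshold(7), "no default")
})

test_that("scaled thresholds reproduce the standard stringency", {
  ## at the reference panel size the scaled threshold recovers the standard
  ## values to within rounding
  expect_equal(scaled_threshold(10, 76519), 0.01, tolerance = 0.01)
  expect_equal(scaled_threshold(1, 76519), 0.001, tolerance = 0.01)
  ## linear in w and in the realized total percentage
  expect_equal(scaled_threshold(20, 1000, 50), 2 * scaled_threshold(10, 1000, 50))
})
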