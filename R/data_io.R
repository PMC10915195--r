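#' Read a pedigree table
#'
#' Reads a delimited text file with columns `animal`, `sire`, `dam` and,
#' optionally, one column per breed carrying that animal's breed fraction
#' (e.g. `holstein`, `other`). Unknown parents may be coded as `NA`, `0` or an
#' empty string. The returned tibble is sorted in topological (parents before
#' offspring) order, which every downstream relationship computation relies on.
#'
#' @param path Path to a TSV/CSV file with a header.
#' @return A tibble with columns `animal`, `sire`, `dam` (character, `NA` for
#'   unknown parents) plus any breed-fraction columns, topologically sorted.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  names(ped) <- tolower(names(ped))
  req <- c("animal", "sire", "dam")
  if (!all(req %in% names(ped)))
    stop_ssgwas("pedigree file must have columns animal, sire, dam")
  ped <- mutate(ped, across(dplyr::all_of(req), as.character))
  validate_pedigree(ped)
}

unknown_to_na <- function(x) {
  x <- as.character(x)
  x[x %in% c("", "0", "NA", ".")] <- NA_character_
  x
}

#' Validate a pedigree and sort it topologically
#'
#' Checks that no animal is its own ancestor (a topological order exists), that
#' parent identifiers refer to animals present in the table (or are unknown),
#' and that breed fractions, when present, sum to one per animal.
#'
#' @param ped A tibble with columns `animal`, `sire`, `dam` and optional
#'   numeric breed-fraction columns.
#' @return The pedigree tibble in topological order.
#' @export
validate_pedigree <- function(ped) {
  ped <- as_tibble(ped)
  ped$animal <- as.character(ped$animal)
  ped$sire <- unknown_to_na(ped$sire)
  ped$dam <- unknown_to_na(ped$dam)
  if (anyDuplicated(ped$animal))
    stop_ssgwas("duplicated animal ids in pedigree: ",
                paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "))
  for (p in c("sire", "dam")) {
    bad <- !is.na(ped[[p]]) & !(ped[[p]] %in% ped$animal)
    if (any(bad))
      stop_ssgwas(sprintf("%s ids not present as animals: %s", p,
                          paste(unique(ped[[p]][bad]), collapse = ", ")))
  }
  ord <- ped_topological_order(ped)
  ped <- ped[match(ord, ped$animal), , drop = FALSE]
  breed_cols <- setdiff(names(ped), c("animal", "sire", "dam", "generation", "sex"))
  breed_cols <- breed_cols[vapply(ped[breed_cols], is.numeric, logical(1))]
  if (length(breed_cols)) {
    s <- rowSums(as.matrix(ped[breed_cols]))
    if (any(abs(s - 1) > 1e-9))
      stop_ssgwas("breed fractions do not sum to 1 for animals: ",
                  paste(head(ped$animal[abs(s - 1) > 1e-9], 5), collapse = ", "))
  }
  ped
}

# Kahn's algorithm; errors (with the offending ids) when a cycle exists
ped_topological_order <- function(ped) {
  ids <- ped$animal
  sire <- ped$sire
  dam <- ped$dam
  placed <- setNames(rep(FALSE, length(ids)), ids)
  order_out <- character(0)
  remaining <- seq_along(ids)
  while (length(remaining)) {
    ready <- remaining[
      (is.na(sire[remaining]) | placed[sire[remaining]]) &
      (is.na(dam[remaining])  | placed[dam[remaining]])]
    if (!length(ready))
      stop_ssgwas("cycle in pedigree involving: ",
                  paste(ids[remaining], collapse = ", "))
    placed[ids[ready]] <- TRUE
    order_out <- c(order_out, ids[ready])
    remaining <- setdiff(remaining, ready)
  }
  order_out
}

#' Read a phenotype table of repeated records
#'
#' Expects a header with `animal`, the fixed-effect columns `cg` (contemporary
#' group, year-month of collection), `ejaculate` (order, 1 or 2), `age`
#' (months), `temp` (ambient temperature, degrees C), `het` (expected
#' heterozygosity in \\[0,1\\]) and one column per trait. Missing trait values
#' are allowed but every record must carry at least one observed trait.
#'
#' @param path Path to a TSV file.
#' @param traits Character vector of trait column names
#'   (default `c("vol","ns","mot")`).
#' @return A tibble of records.
#' @export
read_phenotypes <- function(path, traits = c("vol", "ns", "mot")) {
  phen <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(phen) <- tolower(names(phen))
  miss <- setdiff(c("animal", traits), names(phen))
  if (length(miss))
    stop_ssgwas("phenotype file lacks columns: ", paste(miss, collapse = ", "))
  phen$animal <- as.character(phen$animal)
  all_missing <- rowSums(!is.na(as.matrix(phen[traits]))) == 0
  if (any(all_missing))
    stop_ssgwas("records with all traits missing at rows: ",
                paste(head(which(all_missing), 5), collapse = ", "))
  phen
}

#' Construct a genotype-matrix object
#'
#' Container for 0/1/2 genotype codes (counted copies of allele 2) with a
#' marker map. Markers are stored sorted by (chromosome, position); chromosome
#' labels use natural ordering (1, 2, ..., 10, not 1, 10, 2).
#'
#' @param codes Numeric matrix, animals x markers, entries in \{0, 1, 2, NA\};
#'   rownames are animal ids, colnames marker ids.
#' @param map Tibble/data frame with columns `marker`, `chrom`, `pos_bp`.
#' @return An object of class `geno_mat`.
#' @export
geno_mat <- function(codes, map) {
  map <- as_tibble(map)
  if (!all(c("marker", "chrom", "pos_bp") %in% names(map)))
    stop_ssgwas("marker map needs columns marker, chrom, pos_bp")
  if (ncol(codes) != nrow(map))
    stop_ssgwas(sprintf("genotype matrix has %d markers but map has %d rows",
                        ncol(codes), nrow(map)))
  if (any(map$pos_bp <= 0))
    stop_ssgwas("marker positions must be positive integers")
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  if (is.null(colnames(codes))) colnames(codes) <- map$marker
  bad <- !is.na(codes) & !(codes %in% c(0, 1, 2))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop_ssgwas(sprintf("invalid genotype code %s for animal '%s', marker '%s'",
                        format(codes[w[1], w[2]]), rownames(codes)[w[1]],
                        colnames(codes)[w[2]]))
  }
  ord <- order(chrom_rank(map$chrom), map$pos_bp, map$marker)
  map <- map[ord, , drop = FALSE]
  codes <- codes[, map$marker, drop = FALSE]
  structure(list(codes = codes, map = map), class = "geno_mat")
}

#' @export
print.geno_mat <- function(x, ...) {
  cat(sprintf("<geno_mat> %d animals x %d markers on %d chromosome(s)\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.geno_mat <- function(x) dim(x$codes)

#' Read genotypes and a marker map
#'
#' The genotype file is a TSV with an `animal` column followed by one column
#' per marker holding codes 0/1/2 (`NA` for missing). The map file is a TSV
#' with columns `marker`, `chrom`, `pos_bp`. Markers are reordered to the map
#' sorted by (chromosome, position).
#'
#' @param path_matrix,path_map Paths to the two TSV files.
#' @return A [geno_mat()] object.
#' @export
read_genotypes <- function(path_matrix, path_map) {
  gm <- readr::read_tsv(path_matrix, show_col_types = FALSE, progress = FALSE)
  names(gm)[1] <- tolower(names(gm)[1])
  if (names(gm)[1] != "animal")
    stop_ssgwas("first column of the genotype matrix must be `animal`")
  map <- readr::read_tsv(path_map, show_col_types = FALSE, progress = FALSE)
  names(map) <- tolower(names(map))
  if ("bp" %in% names(map) && !"pos_bp" %in% names(map))
    map <- rename(map, pos_bp = "bp")
  codes <- as.matrix(gm[, -1, drop = FALSE])
  rownames(codes) <- as.character(gm$animal)
  missing_markers <- setdiff(colnames(codes), as.character(map$marker))
  if (length(missing_markers) || ncol(codes) != nrow(map))
    stop_ssgwas("genotype matrix columns and marker map disagree",
                if (length(missing_markers))
                  paste0(" (unmapped: ",
                         paste(head(missing_markers, 5), collapse = ", "), ")")
                else "")
  geno_mat(codes, map)
}

#' Quality-control filter for genotype markers
#'
#' Removes markers with a call rate below `min_call_rate` or a minor allele
#' frequency below `min_maf` (both comparisons strict, so a marker exactly at a
#' threshold is kept). Remaining missing codes are imputed to the marker's mean
#' observed code (2 p_j). The per-marker report is attached as attribute
#' `qc_report` and retrievable with [qc_report()].
#'
#' @param geno A [geno_mat()] object.
#' @param min_call_rate,min_maf Thresholds in (0, 1]; defaults 0.90 and 0.05.
#' @return The filtered `geno_mat` (codes become numeric after imputation).
#' @export
qc_filter <- function(geno, min_call_rate = 0.90, min_maf = 0.05) {
  stopifnot(inherits(geno, "geno_mat"))
  if (min_call_rate <= 0 || min_call_rate > 1 || min_maf < 0 || min_maf > 0.5)
    stop_ssgwas("QC thresholds out of range")
  codes <- geno$codes
  call_rate <- colMeans(!is.na(codes))
  p <- colMeans(codes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  reason <- rep(NA_character_, ncol(codes))
  reason[maf < min_maf] <- "maf"
  reason[call_rate < min_call_rate] <- "call_rate"
  keep <- is.na(reason)
  report <- tibble(marker = colnames(codes), call_rate = call_rate,
                   maf = maf, removed = !keep, reason = reason)
  if (!any(keep))
    stop_ssgwas("QC removed every marker")
  codes <- codes[, keep, drop = FALSE]
  # mean imputation (2 p_j) for codes still missing after filtering
  if (anyNA(codes)) {
    mu <- colMeans(codes, na.rm = TRUE)
    idx <- which(is.na(codes), arr.ind = TRUE)
    codes[idx] <- mu[idx[, 2]]
  }
  out <- geno_mat(codes, geno$map[keep, , drop = FALSE])
  attr(out, "qc_report") <- report
  out
}

#' @rdname qc_filter
#' @export
qc_report <- function(geno) attr(geno, "qc_report")

#' Read a gene annotation (GFF3 or BED)
#'
#' BED input (0-based, half-open) is converted to the internal 1-based
#' inclusive convention; GFF3 is used as is (only `gene`-type features are
#' kept when present). Parsing is delegated to `rtracklayer::import()` after a
#' light line-level validation that reports the first malformed line.
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file.
#' @return A tibble with columns `gene_id`, `chrom`, `start_bp`, `end_bp`,
#'   `strand` (1-based inclusive coordinates).
#' @export
read_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_ssgwas("read_annotation() needs the rtracklayer package")
  is_bed <- grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (is_bed) {
      if (length(f) < 4)
        stop_ssgwas(sprintf("malformed BED line %d: need >= 4 fields", i))
      if (suppressWarnings(as.numeric(f[3])) <= suppressWarnings(as.numeric(f[2])))
        stop_ssgwas(sprintf("malformed BED line %d: end <= start", i))
    } else {
      if (length(f) < 9)
        stop_ssgwas(sprintf("malformed GFF3 line %d: need 9 fields", i))
      if (suppressWarnings(as.numeric(f[5])) < suppressWarnings(as.numeric(f[4])))
        stop_ssgwas(sprintf("malformed GFF3 line %d: start > end", i))
    }
  }
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (!is_bed && "type" %in% names(df) && any(df$type == "gene"))
    df <- df[df$type == "gene", , drop = FALSE]
  id <- if ("name" %in% names(df) && !all(is.na(df$name))) df$name
        else if ("ID" %in% names(df)) df$ID
        else if ("Name" %in% names(df)) df$Name
        else if ("gene_id" %in% names(df)) df$gene_id
        else paste0("gene", seq_len(nrow(df)))
  ann <- tibble(gene_id = as.character(id),
                chrom = sub("^chr", "", as.character(df$seqnames)),
                start_bp = as.integer(df$start), end_bp = as.integer(df$end),
                strand = as.character(df$strand))
  if (any(ann$start_bp > ann$end_bp))
    stop_ssgwas("annotation has features with start > end")
  arrange(ann, chrom_rank(.data$chrom), .data$start_bp, .data$gene_id)
}

#' Read pathway gene sets in GMT format
#'
#' Each GMT line holds a pathway id, a description and one or more gene ids,
#' tab-separated. A pathway with zero genes is an error.
#'
#' @param path Path to a `.gmt` file.
#' @return A long tibble with columns `pathway`, `name`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  rows <- purrr::map(which(keep), function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      stop_ssgwas(sprintf("malformed GMT line %d: pathway with no genes", i))
    tibble(pathway = f[1], name = f[2], gene = f[-(1:2)])
  })
  out <- bind_rows(rows)
  if (anyDuplicated(distinct(out, .data$pathway, .data$name)$pathway))
    stop_ssgwas("duplicated pathway ids in GMT file")
  out
}

#' Write a pathway tibble as GMT
#'
#' @param pathways Long tibble (`pathway`, `name`, `gene`).
#' @param path Output path.
#' @return `pathways`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  sp <- split(pathways, pathways$pathway)
  lines <- vapply(sp, function(d)
    paste(c(d$pathway[1], d$name[1], d$gene), collapse = "\t"), character(1))
  writeLines(unname(lines), path)
  invisible(pathways)
}

#' Write a gene annotation as BED
#'
#' Converts the 1-based inclusive internal representation back to BED's
#' 0-based half-open convention.
#'
#' @param ann Annotation tibble (`gene_id`, `chrom`, `start_bp`, `end_bp`,
#'   `strand`).
#' @param path Output path.
#' @return `ann`, invisibly.
#' @export
write_annotation_bed <- function(ann, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", ann$chrom, ann$start_bp - 1L,
                   ann$end_bp, ann$gene_id, ann$strand)
  writeLines(lines, path)
  invisible(ann)
}

#' Write a tidy table (TSV)
#'
#' Thin wrapper over `readr::write_tsv()`; `read_table_tsv()` is its
#' round-trip counterpart.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(x)
}

#' @rdname write_table
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write genotypes and marker map as TSV
#'
#' @param geno A [geno_mat()] object.
#' @param path_matrix,path_map Output paths.
#' @return `geno`, invisibly.
#' @export
write_genotypes <- function(geno, path_matrix, path_map) {
  gm <- as_tibble(as.data.frame(geno$codes))
  gm <- tibble(animal = rownames(geno$codes), gm)
  readr::write_tsv(gm, path_matrix, progress = FALSE)
  readr::write_tsv(geno$map, path_map, progress = FALSE)
  invisible(geno)
}

#' Run configuration
#'
#' Bundles the knobs of a full pipeline run: window sizes and overlap modes,
#' per-size selection thresholds (percent of the additive genetic variance),
#' genotype QC thresholds, REML controls, the significance level for pathway
#' enrichment, and the global seed.
#'
#' @param window_sizes Integer vector, default `c(1, 10, 30, 50, 100)`.
#' @param overlap_modes Subset of `c("overlapping", "non_overlapping")`.
#' @param thresholds Named numeric vector (percent) keyed by window size;
#'   defaults to [default_threshold()] for the standard sizes.
#' @param min_call_rate,min_maf QC thresholds (defaults 0.90, 0.05).
#' @param seed Integer seed.
#' @param reml_max_iter,reml_tol REML iteration controls.
#' @param significance_alpha Enrichment significance level (strict `<`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(window_sizes = c(1, 10, 30, 50, 100),
                       overlap_modes = c("overlapping", "non_overlapping"),
                       thresholds = NULL,
                       min_call_rate = 0.90, min_maf = 0.05,
                       seed = 1L,
                       reml_max_iter = 200L, reml_tol = 1e-8,
                       significance_alpha = 0.05) {
  window_sizes <- as.integer(window_sizes)
  if (any(window_sizes < 1)) stop_ssgwas("window sizes must be positive")
  overlap_modes <- match.arg(overlap_modes,
                             c("overlapping", "non_overlapping"),
                             several.ok = TRUE)
  if (is.null(thresholds))
    thresholds <- setNames(vapply(window_sizes, default_threshold, numeric(1)),
                           window_sizes)
  missing_thr <- setdiff(as.character(window_sizes), names(thresholds))
  if (length(missing_thr))
    stop_ssgwas("no selection threshold for window size(s): ",
                paste(missing_thr, collapse = ", "))
  structure(list(window_sizes = window_sizes, overlap_modes = overlap_modes,
                 thresholds = thresholds, min_call_rate = min_call_rate,
                 min_maf = min_maf, seed = as.integer(seed),
                 reml_max_iter = as.integer(reml_max_iter),
                 reml_tol = reml_tol,
                 significance_alpha = significance_alpha),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML file whose keys mirror the `run_config()`
#'   arguments.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- y$thresholds
  if (!is.null(thr)) thr <- unlist(thr)
  run_config(window_sizes = y$window_sizes %||% c(1, 10, 30, 50, 100),
             overlap_modes = y$overlap_modes %||%
               c("overlapping", "non_overlapping"),
             thresholds = thr,
             min_call_rate = y$qc$min_call_rate %||% 0.90,
             min_maf = y$qc$min_maf %||% 0.05,
             seed = y$seed %||% 1L,
             reml_max_iter = y$reml$max_iter %||% 200L,
             reml_tol = y$reml$tolerance %||% 1e-8,
             significance_alpha = y$significance_alpha %||% 0.05)
}
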