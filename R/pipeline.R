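#' Run the full single-step window-GWAS pipeline
#'
#' Orchestrates every stage in dependency order: data loading or simulation,
#' genotype QC, relationship matrices, REML fitting of the repeatability
#' model, SNP-effect back-solution, window construction and aggregation for
#' every requested (size, mode) scheme, SNP selection, nearest-gene mapping,
#' pathway enrichment (traits pooled) and the pairwise scheme comparison.
#' All randomness derives from `config$seed`; two runs with the same inputs
#' and seed produce identical outputs.
#'
#' @param config A [run_config()].
#' @param inputs Either a [sim_spec()] (the seed is overridden by
#'   `config$seed`) or a named list of file paths: `pedigree`, `phenotypes`,
#'   `genotypes`, `map`, and optionally `annotation` (GFF3/BED) and
#'   `pathways` (GMT).
#' @param annotation,pathways Optional in-memory annotation tibble and
#'   pathway tibble, overriding file inputs (used with a `sim_spec`).
#' @param out_dir Optional output directory; when given, every stage table
#'   is written as TSV and a `manifest.yaml` records the configuration,
#'   seed, input checksums and output files.
#' @param verbose Print stage progress.
#' @return A list of class `ssgwas_run`: `data`, `relationships`, `fit`,
#'   `snp_table`, `schemes` (per-scheme list with windows, window variances,
#'   selected SNPs, gene assignments, enrichment), `enrichment` (combined
#'   tibble), `comparison`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), inputs,
                         annotation = NULL, pathways = NULL,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) inform(paste0(...))
  checksums <- NULL
  want_enrich <- TRUE
  ## ---- load or simulate -----------------------------------------------
  if (inherits(inputs, "sim_spec")) {
    inputs$seed <- config$seed
    say("simulating dataset (seed ", config$seed, ")")
    dat <- simulate_dataset(inputs)
    ped <- dat$ped; phen <- dat$phenotypes; geno <- dat$geno
    truth <- dat$truth
    traits <- inputs$traits
    if (is.null(annotation) || is.null(pathways)) want_enrich <- FALSE
  } else {
    req <- c("pedigree", "phenotypes", "genotypes", "map")
    miss <- setdiff(req, names(inputs))
    if (length(miss))
      stop_ssgwas("missing input paths: ", paste(miss, collapse = ", "))
    if (is.null(annotation) && is.null(inputs$annotation)) want_enrich <- FALSE
    if (is.null(pathways) && is.null(inputs$pathways)) want_enrich <- FALSE
    files <- unlist(inputs)
    checksums <- tools::md5sum(files[file.exists(files)])
    ped <- read_pedigree(inputs$pedigree)
    phen <- read_phenotypes(inputs$phenotypes)
    geno <- read_genotypes(inputs$genotypes, inputs$map)
    truth <- NULL
    traits <- setdiff(names(phen),
                      c("animal", "record", "cg", "ejaculate", "age",
                        "temp", "het"))
    if (!is.null(inputs$annotation)) annotation <- read_annotation(inputs$annotation)
    if (!is.null(inputs$pathways)) pathways <- read_gmt(inputs$pathways)
  }
  ## ---- QC, relationships, REML ----------------------------------------
  say("genotype QC")
  geno <- qc_filter(geno, config$min_call_rate, config$min_maf)
  say("relationship matrices")
  relset <- build_relationships(ped, geno)
  design <- build_design(phen, animals = rownames(relset$A), traits = traits)
  say("REML fit")
  fit <- reml_fit(design, relset$H_inv, max_iter = config$reml_max_iter,
                  tol = config$reml_tol, verbose = verbose)
  sigma_a2 <- setNames(diag(fit$Va), traits)
  say("SNP effect back-solution")
  snp_table <- snp_effect_table(fit, relset, sigma_a2, geno)
  ## ---- window schemes --------------------------------------------------
  background <- NULL
  if (want_enrich)
    background <- intersect(unique(annotation$gene_id),
                            unique(pathways$gene))
  schemes <- list()
  for (w in config$window_sizes) for (mode in config$overlap_modes) {
    key <- sprintf("sw%d_%s", w, mode)
    say("scheme ", key)
    windows <- build_windows(geno$map, w, mode)
    wvt <- aggregate_windows(windows, snp_table, sigma_a2)
    thr <- unname(config$thresholds[[as.character(w)]])
    selected <- select_snps(wvt, windows, geno$map, thr)
    entry <- list(w = w, mode = mode, threshold = thr, windows = windows,
                  window_variance = wvt, selected = selected)
    if (want_enrich) {
      assigned <- assign_nearest_gene(selected, annotation)
      genes <- unique(assigned$gene_id[!is.na(assigned$gene_id)])
      entry$assignments <- assigned
      entry$genes <- genes
      entry$enrichment <- enrich_pathways(genes, pathways, background,
                                          alpha = config$significance_alpha)
    }
    schemes[[key]] <- entry
  }
  ## ---- enrichment comparison ------------------------------------------
  comparison <- NULL; enrichment_all <- NULL; bin_counts <- NULL
  if (want_enrich) {
    enrichment_all <- bind_rows(purrr::imap(schemes, function(e, key)
      mutate(e$enrichment, scheme = .env$key)))
    gene_sets <- purrr::map(schemes, "genes")
    comparison <- compare_schemes(enrichment_all, gene_sets, pathways)
    bin_counts <- tabulate_bins(bind_rows(purrr::imap(schemes, function(e, key)
      mutate(e$assignments, scheme = .env$key))))
  }
  out <- structure(list(
    data = list(ped = ped, phenotypes = phen, geno = geno, truth = truth,
                annotation = annotation, pathways = pathways),
    relationships = relset, fit = fit, snp_table = snp_table,
    schemes = schemes, enrichment = enrichment_all,
    bin_counts = bin_counts, comparison = comparison,
    config = config), class = "ssgwas_run")
  out$manifest <- list(
    package_version = as.character(utils::packageVersion("ssgwas")),
    seed = config$seed,
    config = unclass(config),
    input_checksums = as.list(checksums),
    timestamp = format(Sys.time(), tz = "UTC"),
    schemes = names(schemes))
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

#' @export
print.ssgwas_run <- function(x, ...) {
  cat(sprintf("<ssgwas_run> %d schemes, %d markers after QC\n",
              length(x$schemes), nrow(x$data$geno$map)))
  print(x$fit)
  invisible(x)
}

# write every stage table; file set is fixed so reruns are byte-comparable
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, paste0(...))
  write_table(qc_report(run$data$geno), p("qc_report.tsv"))
  write_table(tidy(run$fit), p("variance_components.tsv"))
  write_table(run$fit$solutions$gebv, p("gebv.tsv"))
  write_table(run$fit$trace, p("reml_trace.tsv"))
  write_table(run$snp_table, p("snp_effects.tsv"))
  for (key in names(run$schemes)) {
    e <- run$schemes[[key]]
    write_table(e$window_variance, p("windows_", key, ".tsv"))
    write_table(e$selected, p("selected_", key, ".tsv"))
    if (!is.null(e$enrichment))
      write_table(e$enrichment, p("enrichment_", key, ".tsv"))
  }
  if (!is.null(run$comparison)) {
    write_table(tidy(run$comparison), p("comparison.tsv"))
    write_table(run$bin_counts, p("bin_counts.tsv"))
  }
  manifest <- run$manifest
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(run)
}
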