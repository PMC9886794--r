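#' Assemble / load a run configuration
#'
#' Defaults mirror the study's printed settings: 494 cases vs 572 controls
#' in 43 pools of up to 25 at ~378-fold pool coverage, rare/common boundary
#' at cohort MAF 0.010, nominal level 0.05, gene tests run under both
#' singleton policies, Bonferroni family size 660 candidate genes.
#'
#' @param path Optional YAML or JSON file; entries override the defaults.
#' @param ... Named overrides applied on top.
#' @return A validated configuration list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    n_cases = 494L, n_controls = 572L, pool_size = 25L,
    median_pool_coverage = 378.12, seq_error_rate = 0.002,
    n_variants = 2000L, frac_enriched = 0.01, n_genes = 100L,
    maf_threshold = 0.010, alpha = 0.05, top_alpha = 0.01,
    m_gene_tests = 660L,
    gene_test_method = "moment", gene_test_B = 1e4,
    singleton_policies = c("included", "excluded"),
    cadd_min = 15, regulome_max = 3, external_maf_max = 0.010,
    enrichment_B = 10000L,
    seed = 1L
  )
  if (!is.null(path)) {
    loaded <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    cfg[names(loaded)] <- loaded
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(cfg$maf_threshold > 0, cfg$alpha > 0, cfg$alpha < 1,
            cfg$seed < 2^31 - 16)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate (or load) the cohort; adjust minor alleles;
#' single-variant association with multiplicity correction and
#' rarity/enrichment partitioning; gene-based tests under both singleton
#' policies; amino-acid substitution classification; six-criterion
#' prioritization with hotspot detection; gene-set enrichment; summary.
#' Every stage's row counts are logged, and dropped records carry reason
#' codes. With a fixed seed the whole bundle (including the summary JSON)
#' is reproducible byte for byte.
#'
#' @param config A [run_config()] (or a path / named overrides via `...`).
#' @param out_dir Optional output directory for TSV/JSON exports and the run
#'   log.
#' @param variants Optional pre-loaded [variant_table()]; skips simulation.
#' @param genotypes Optional individual-level genotype matrix matching
#'   `variants`; when absent with pooled-only input, gene tests run in
#'   count-resampling mode (flagged).
#' @param ... Overrides forwarded to [run_config()].
#' @return A list of class `longevity_report` with the stage outputs
#'   (`variants`, `assoc`, `gene_scan`, `priorities`, `hotspots`,
#'   `enrichment`, `summary`, `log`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         variants = NULL, genotypes = NULL, ...) {
  if (is.character(config)) config <- run_config(config, ...)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log <<- c(log, msg)
  }

  design <- cohort_design(config$n_cases, config$n_controls, config$pool_size,
                          median_pool_coverage = config$median_pool_coverage,
                          seq_error_rate = config$seq_error_rate,
                          seed = config$seed)
  mode <- "individual"
  dropped <- NULL
  if (is.null(variants)) {
    specs <- simulate_variant_specs(config$n_variants,
                                    frac_enriched = config$frac_enriched,
                                    n_genes = config$n_genes,
                                    seed = config$seed)
    sim <- simulate_cohort(design, specs)
    variants <- sim$variants
    genotypes <- sim$genotypes
    dropped <- sim$dropped
    say("simulate: %d variants drawn, %d retained, %d dropped (%s)",
        config$n_variants, nrow(variants), nrow(sim$dropped),
        paste(names(table(sim$dropped$reason)),
              table(sim$dropped$reason), collapse = ", "))
  } else {
    variants <- variant_table(variants)
    say("load: %d variants", nrow(variants))
  }
  if (is.null(genotypes)) {
    genotypes <- genotypes_from_counts(adjust_minor_allele(variants),
                                       seed = config$seed + 2L)
    mode <- "count_resampling"
    say("genotypes: reconstructed from pooled counts (count-resampling mode)")
  }

  variants <- adjust_minor_allele(variants)
  say("adjust: %d records, %d minor-allele swaps", nrow(variants),
      sum(variants$swapped))

  assoc <- associate(variants, alpha = config$alpha,
                     maf_threshold = config$maf_threshold)
  say("associate: %d tests, %d at p <= %.3g", nrow(assoc),
      sum(assoc$p_value <= config$alpha), config$alpha)

  gene_of <- variants$gene[match(colnames(genotypes), variants$key)]
  if (anyNA(gene_of)) gene_of <- variants$gene   # simulated column order
  phen <- rep(c(1L, 0L), c(design$n_cases, design$n_controls))
  scan <- run_gene_scan(genotypes, gene_of, phen,
                        policies = config$singleton_policies,
                        maf_threshold = config$maf_threshold,
                        method = config$gene_test_method,
                        alpha = config$alpha, top_alpha = config$top_alpha,
                        B = config$gene_test_B, seed = config$seed + 3L)
  say("genescan: %d gene x policy rows, %d significant, %d top, %d untestable",
      nrow(scan), sum(scan$significant), sum(scan$top),
      sum(scan$status == "untestable"))

  variants <- classify_table(variants)
  say("classify: %d substitution labels", sum(!is.na(variants$aa_label)))

  pconf <- prioritize_config(alpha = config$alpha, cadd_min = config$cadd_min,
                             regulome_max = config$regulome_max,
                             external_maf_max = config$external_maf_max)
  prio <- rank_priorities(apply_criteria(assoc, variants, pconf))
  hots <- hotspot_genes(prio)
  say("prioritize: %d LAVs, %d hotspot genes", nrow(prio), nrow(hots))

  excl <- scan[scan$singleton_policy == utils::tail(config$singleton_policies, 1), ]
  lags <- unique(excl$gene[excl$significant %in% TRUE])
  cat_sim <- simulate_gwas_catalog(unique(variants$gene),
                                   seed = config$seed + 4L)
  catalog <- dedupe_catalog(filter_catalog(cat_sim$catalog,
                                           cat_sim$category_map))
  sets <- split(catalog$gene, catalog$category)
  enr <- if (length(lags) && length(sets))
    enrich_genesets(lags, sets, unique(variants$gene),
                    B = config$enrichment_B, seed = config$seed + 5L,
                    background_name = "candidate_list")
  else NULL
  say("enrich: %d categories against %d background genes (%d query genes)",
      length(sets), length(unique(variants$gene)), length(lags))

  summ <- list(
    n_variants = nrow(variants),
    distributions = lapply(
      summarize_distributions(assoc, alpha = config$alpha),
      function(x) if (is.table(x)) as.list(x) else x),
    distributions_no_singletons = lapply(
      summarize_distributions(assoc, exclude_singletons = TRUE,
                              alpha = config$alpha),
      function(x) if (is.table(x)) as.list(x) else x),
    bonferroni_threshold = config$alpha / config$m_gene_tests,
    genes_significant = sort(unique(scan$gene[scan$significant])),
    genes_top = sort(unique(scan$gene[scan$top])),
    lav = lav_summary(prio),
    hotspot_genes = hots$gene,
    enrichment = if (!is.null(enr))
      stats::setNames(as.list(enr$p_empirical), enr$category),
    mode = mode
  )

  out <- list(variants = variants, assoc = assoc, gene_scan = scan,
              priorities = prio, hotspots = hots, enrichment = enr,
              dropped = dropped, summary = summ, log = log, config = config)
  class(out) <- "longevity_report"
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' Write a report bundle to disk
#'
#' Emits the association table, Manhattan-ready export, gene-scan table,
#' prioritized variants, hotspot list and enrichment table as TSV, the
#' summary as JSON, and the run log.
#'
#' @param report A `longevity_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(out_dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(report$assoc, "association.tsv")
  write_manhattan(report$assoc, file.path(out_dir, "manhattan.tsv"))
  wt(report$gene_scan, "gene_scan.tsv")
  wt(report$priorities, "prioritized_variants.tsv")
  wt(report$hotspots, "hotspot_genes.tsv")
  if (!is.null(report$enrichment)) wt(report$enrichment, "enrichment.tsv")
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(report$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.longevity_report <- function(x, ...) {
  cat("Longevity pooled-sequencing analysis report\n")
  cat(sprintf("  %d variants | %d LAVs | %d hotspot genes | %d significant genes\n",
              nrow(x$variants), nrow(x$priorities), nrow(x$hotspots),
              length(x$summary$genes_significant)))
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}
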