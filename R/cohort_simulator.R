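#' Describe a pooled-sequencing case/control cohort design
#'
#' Captures the layout of a pooled target-capture sequencing experiment:
#' centenarian cases and younger controls are combined in equimolar pools of
#' up to `pool_size` individuals, each pool homogeneous by case/control
#' status, and every pool is sequenced to a depth centred on
#' `median_pool_coverage`.
#'
#' The defaults describe an AJ-style longevity cohort: 494 cases and 572
#' controls in 43 pools of up to 25 individuals (20 case pools + 23 control
#' pools), sequenced at ~378-fold per pool, i.e. ~15-fold per sample.
#'
#' @param n_cases,n_controls Number of case (proband/centenarian) and control
#'   individuals.
#' @param pool_size Maximum number of individuals per pool.
#' @param n_pools Total number of pools. Defaults to the smallest number of
#'   group-homogeneous pools that fits the cohort,
#'   `ceiling(n_cases/pool_size) + ceiling(n_controls/pool_size)`.
#' @param median_pool_coverage Expected read depth per pool per site (fold).
#' @param seq_error_rate Per-read allele miscall probability, in `[0, 0.05]`.
#' @param seed Optional integer RNG seed carried by the design and used by
#'   the simulation functions; must be below `2^31`.
#' @return An object of class `cohort_design`.
#' @examples
#' d <- cohort_design()
#' d$n_pools  # 43
#' @export
cohort_design <- function(n_cases = 494L, n_controls = 572L, pool_size = 25L,
                          n_pools = NULL,
                          median_pool_coverage = 378.12,
                          seq_error_rate = 0.002, seed = NULL) {
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  pool_size <- as.integer(pool_size)
  if (n_cases <= 0L || n_controls <= 0L || pool_size <= 0L)
    stop("n_cases, n_controls and pool_size must be positive")
  n_case_pools <- as.integer(ceiling(n_cases / pool_size))
  n_ctrl_pools <- as.integer(ceiling(n_controls / pool_size))
  if (is.null(n_pools)) n_pools <- n_case_pools + n_ctrl_pools
  n_pools <- as.integer(n_pools)
  if (n_pools <= 0L) stop("n_pools must be positive")
  if (n_pools * pool_size < n_cases + n_controls)
    stop("n_pools * pool_size must cover the whole cohort")
  if (n_pools < n_case_pools + n_ctrl_pools)
    stop("n_pools too small for group-homogeneous pools of at most pool_size")
  if (median_pool_coverage <= 0) stop("median_pool_coverage must be positive")
  if (seq_error_rate < 0 || seq_error_rate > 0.05)
    stop("seq_error_rate must lie in [0, 0.05]")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed) || abs(seed) >= 2^31 - 16) stop("seed out of integer range")
  }
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 pool_size = pool_size, n_pools = n_pools,
                 n_case_pools = n_case_pools, n_ctrl_pools = n_ctrl_pools,
                 median_pool_coverage = median_pool_coverage,
                 seq_error_rate = seq_error_rate, seed = seed),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("Pooled-sequencing cohort design\n")
  cat(sprintf("  %d cases + %d controls in %d pools (<= %d individuals each)\n",
              x$n_cases, x$n_controls, x$n_pools, x$pool_size))
  cat(sprintf("  %d case pools, %d control pools (homogeneous by group)\n",
              x$n_case_pools, x$n_ctrl_pools))
  cat(sprintf("  ~%.2f-fold median coverage per pool (~%.2f-fold per sample)\n",
              x$median_pool_coverage, x$median_pool_coverage / x$pool_size))
  cat(sprintf("  per-read miscall rate %.4g", x$seq_error_rate))
  if (!is.null(x$seed)) cat(sprintf(", seed %d", x$seed))
  cat("\n")
  invisible(x)
}

#' Deterministic pool membership for a cohort design
#'
#' Individuals are assigned round-robin within their group: case `i` goes to
#' case pool `((i - 1) %% n_case_pools) + 1`, and likewise for controls.
#' Pools never mix cases and controls, and under-full pools are permitted.
#'
#' @param design A [cohort_design()].
#' @return A data frame with columns `individual`, `group`
#'   (`"case"`/`"control"`) and `pool` (1-based, case pools first).
#' @export
pool_assignment <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  case_pool <- ((seq_len(design$n_cases) - 1L) %% design$n_case_pools) + 1L
  ctrl_pool <- ((seq_len(design$n_controls) - 1L) %% design$n_ctrl_pools) + 1L +
    design$n_case_pools
  data.frame(
    individual = seq_len(design$n_cases + design$n_controls),
    group = rep(c("case", "control"), c(design$n_cases, design$n_controls)),
    pool = c(case_pool, ctrl_pool)
  )
}

.valid_consequences <- c("nonsynonymous", "synonymous", "stop_gain",
                         "frameshift", "inframe_indel", "utr3", "utr5",
                         "intronic", "upstream", "downstream", "splice")
.coding_consequences <- c("nonsynonymous", "synonymous", "stop_gain",
                          "frameshift", "inframe_indel")

#' Draw a synthetic variant panel
#'
#' Generates per-variant simulation truths emulating the composition of a
#' mitonuclear candidate-gene capture panel: a 1/f-shaped allele-frequency
#' spectrum extending below the cohort detection limit (so that roughly half
#' of the variants detected in a cohort of ~1000 individuals are singletons),
#' consequence-class proportions matching a coding/non-coding capture design
#' (about two thirds of coding variants nonsynonymous), and annotation
#' columns (impact scores, regulatory ranks, external population frequencies,
#' conservation flags) with realistic missingness.
#'
#' A configurable fraction of variants is "planted" as case-enriched: their
#' true case MAF exceeds the control MAF, and their annotations qualify under
#' the six-criterion prioritization cascade (nonsynonymous, damaging scores,
#' externally rare, with a-priori evidence), which supports end-to-end
#' parameter-recovery experiments.
#'
#' @param n_variants Number of variants to draw.
#' @param frac_enriched Fraction of variants planted as case-enriched.
#' @param maf_enriched_cases,maf_enriched_controls True minor-allele
#'   frequencies of planted variants in cases and controls.
#' @param n_genes Number of gene symbols to spread variants over.
#' @param coding_fraction Fraction of variants in coding classes.
#' @param maf_range Range of the log-uniform common/low-frequency component
#'   of the null spectrum (both groups share the null frequency).
#' @param ultra_range,ultra_weight Range and mixture weight of the
#'   ultra-rare spectrum component. The default 0.9 weight makes roughly
#'   half of the variants *detected* in a ~1,000-individual cohort
#'   singletons, the hallmark of deep candidate-gene sequencing.
#' @param seed Optional integer seed.
#' @return A data frame of variant specifications with annotation columns and
#'   a logical `planted` column.
#' @export
simulate_variant_specs <- function(n_variants, frac_enriched = 0,
                                   maf_enriched_cases = 0.02,
                                   maf_enriched_controls = 0.002,
                                   n_genes = max(2L, ceiling(n_variants / 25)),
                                   coding_fraction = 0.35,
                                   maf_range = c(1e-3, 0.5),
                                   ultra_range = c(5e-6, 1e-3),
                                   ultra_weight = 0.9,
                                   seed = NULL) {
  if (n_variants < 1) stop("n_variants must be >= 1")
  if (frac_enriched < 0 || frac_enriched > 1) stop("frac_enriched in [0,1]")
  if (any(c(maf_enriched_cases, maf_enriched_controls) < 0) ||
      any(c(maf_enriched_cases, maf_enriched_controls) > 0.5))
    stop("true minor-allele frequencies must lie in [0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_variants)
  genes <- sprintf("GENE%04d", seq_len(n_genes))

  # 1/f-shaped spectrum: mixture of log-uniform ultra-rare and
  # common/low-frequency components
  ultra <- stats::runif(n) < ultra_weight
  f0 <- ifelse(ultra,
               exp(stats::runif(n, log(ultra_range[1]), log(ultra_range[2]))),
               exp(stats::runif(n, log(maf_range[1]), log(maf_range[2]))))
  planted <- stats::runif(n) < frac_enriched
  f_case <- ifelse(planted, maf_enriched_cases, f0)
  f_ctrl <- ifelse(planted, maf_enriched_controls, f0)

  # consequence classes: coding split 67/26/4/2.5/0.5, non-coding dominated by
  # intronic and UTR capture targets
  coding <- stats::runif(n) < coding_fraction
  cons <- character(n)
  cons[coding] <- sample(.coding_consequences, sum(coding), replace = TRUE,
                         prob = c(0.67, 0.26, 0.04, 0.025, 0.005))
  cons[!coding] <- sample(c("intronic", "utr3", "utr5", "upstream",
                            "downstream", "splice"),
                          sum(!coding), replace = TRUE,
                          prob = c(0.40, 0.25, 0.10, 0.11, 0.10, 0.04))
  cons[planted] <- "nonsynonymous"  # planted LAVs are nsVs by construction

  aa <- .random_aa_changes(n, cons)

  nsv <- cons == "nonsynonymous"
  cadd <- ifelse(stats::runif(n) < 0.35, NA_real_,
                 round(stats::rgamma(n, shape = 2, scale = 4), 2))
  condel <- ifelse(stats::runif(n) < 0.5, NA_character_,
                   sample(c("deleterious", "neutral"), n, TRUE, c(0.25, 0.75)))
  condel[!nsv] <- NA_character_
  regulome <- ifelse(stats::runif(n) < 0.6, NA_integer_,
                     sample(1:7, n, TRUE, prob = c(2, 3, 6, 10, 16, 30, 33)))
  regulome[coding] <- NA_integer_

  # external population MAFs: mostly absent for rare variants, tracking the
  # simulated cohort frequency when present
  ext <- function(p_missing) {
    m <- stats::runif(n) < p_missing
    v <- signif(pmin(0.5, f0 * exp(stats::rnorm(n, 0, 0.5))), 3)
    v[m] <- NA_real_
    v
  }
  maf_1kg <- ext(0.6); maf_gnomad <- ext(0.35)
  maf_exac <- ext(0.45); maf_discovehr <- ext(0.55)

  vert_conserved <- stats::runif(n) < 0.15
  invert_conserved <- vert_conserved & stats::runif(n) < 0.5
  evidence_notes <- stats::rpois(n, 0.10)

  # planted variants carry a qualifying annotation profile, including a
  # non-conservative/radical substitution
  if (any(planted)) {
    k <- sum(planted)
    radical <- list(c("K", "E"), c("D", "G"), c("R", "W"), c("G", "R"),
                    c("S", "F"))
    pick <- radical[sample.int(length(radical), k, replace = TRUE)]
    aa$ref[planted] <- vapply(pick, `[`, "", 1)
    aa$alt[planted] <- vapply(pick, `[`, "", 2)
    aa$pos[planted] <- sample.int(1500L, k, replace = TRUE)
    cadd[planted] <- round(stats::runif(k, 20, 35), 2)
    condel[planted] <- "deleterious"
    maf_1kg[planted] <- NA_real_
    maf_gnomad[planted] <- signif(stats::runif(k, 1e-5, 5e-3), 3)
    maf_exac[planted] <- NA_real_
    maf_discovehr[planted] <- NA_real_
    vert_conserved[planted] <- TRUE
    invert_conserved[planted] <- stats::runif(k) < 0.8
    evidence_notes[planted] <- 1L + stats::rpois(k, 1.2)
  }

  data.frame(
    gene = sample(genes, n, replace = TRUE),
    true_maf_cases = f_case, true_maf_controls = f_ctrl,
    consequence_class = cons,
    aa_ref = aa$ref, aa_pos = aa$pos, aa_alt = aa$alt,
    cadd_phred = cadd, condel_label = condel, regulome_rank = regulome,
    maf_1kg = maf_1kg, maf_gnomad = maf_gnomad, maf_exac = maf_exac,
    maf_discovehr = maf_discovehr,
    vert_conserved = vert_conserved, invert_conserved = invert_conserved,
    evidence_notes = evidence_notes,
    planted = planted,
    stringsAsFactors = FALSE
  )
}

# random amino-acid substitutions for nonsynonymous specs (stop gains and
# other classes carry no substitution)
.random_aa_changes <- function(n, cons) {
  residues <- c("A","R","N","D","C","Q","E","G","H","I",
                "L","K","M","F","P","S","T","W","Y","V")
  ref <- pos <- alt <- rep(NA_character_, n)
  nsv <- which(cons == "nonsynonymous")
  if (length(nsv)) {
    r <- sample(residues, length(nsv), TRUE)
    a <- sample(residues, length(nsv), TRUE)
    bump <- a == r
    a[bump] <- residues[(match(a[bump], residues)) %% 20L + 1L]
    ref[nsv] <- r; alt[nsv] <- a
    pos[nsv] <- as.character(sample.int(1500L, length(nsv), TRUE))
  }
  list(ref = ref, pos = as.integer(pos), alt = alt)
}

#' Simulate individual diploid genotypes
#'
#' Draws Hardy-Weinberg genotypes (minor-allele dosage 0/1/2) for every
#' individual at every variant, using the group-specific true minor-allele
#' frequencies in `specs`. Cases occupy the first rows.
#'
#' @param design A [cohort_design()].
#' @param specs A variant-specification data frame as produced by
#'   [simulate_variant_specs()] (columns `true_maf_cases`,
#'   `true_maf_controls` are required).
#' @param seed Integer seed; defaults to the design seed.
#' @return An integer matrix of dimension `(n_cases + n_controls) x nrow(specs)`
#'   with a `"group"` attribute marking case/control rows.
#' @export
simulate_genotypes <- function(design, specs, seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(specs) || nrow(specs) == 0) stop("specs must be non-empty")
  fc <- specs$true_maf_cases; ft <- specs$true_maf_controls
  if (any(fc < 0 | fc > 0.5 | ft < 0 | ft > 0.5))
    stop("true minor-allele frequencies must lie in [0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  nca <- design$n_cases; nco <- design$n_controls
  V <- nrow(specs)
  g_case <- matrix(stats::rbinom(nca * V, 2L, rep(fc, each = nca)), nca, V)
  g_ctrl <- matrix(stats::rbinom(nco * V, 2L, rep(ft, each = nco)), nco, V)
  g <- rbind(g_case, g_ctrl)
  storage.mode(g) <- "integer"
  rownames(g) <- sprintf("IND%04d", seq_len(nca + nco))
  colnames(g) <- sprintf("V%05d", seq_len(V))
  attr(g, "group") <- rep(c("case", "control"), c(nca, nco))
  g
}

#' Simulate pooled sequencing reads
#'
#' Individuals are pooled per [pool_assignment()] (pools homogeneous by
#' case/control status). For each pool and variant the read depth is Poisson
#' around the design's median pool coverage, and the number of reads carrying
#' the minor allele is binomial with success probability equal to the pool's
#' minor-chromosome fraction perturbed by the symmetric per-read miscall rate
#' `e`: `f*(1-e) + (1-f)*e`.
#'
#' @param genotypes Matrix from [simulate_genotypes()].
#' @param design The matching [cohort_design()].
#' @param seed Integer seed; defaults to `design$seed + 1` when the design
#'   carries a seed.
#' @return An object of class `pooled_reads`: list with matrices `alt` and
#'   `depth` (pools x variants) and a data frame `pools` (pool, group,
#'   n individuals).
#' @export
pool_and_sequence <- function(genotypes, design,
                              seed = if (!is.null(design$seed)) design$seed + 1L) {
  stopifnot(inherits(design, "cohort_design"))
  pa <- pool_assignment(design)
  if (nrow(genotypes) != nrow(pa))
    stop("genotype rows must equal the cohort size of the design")
  sizes <- tabulate(pa$pool, nbins = design$n_case_pools + design$n_ctrl_pools)
  if (any(sizes == 0L)) stop("pool with zero assigned individuals")
  if (!is.null(seed)) set.seed(seed)

  minor_chrom <- rowsum(genotypes, pa$pool)          # pools x variants
  frac <- minor_chrom / (2 * sizes)
  e <- design$seq_error_rate
  p_read <- frac * (1 - e) + (1 - frac) * e
  np <- length(sizes); V <- ncol(genotypes)
  depth <- matrix(stats::rpois(np * V, design$median_pool_coverage), np, V)
  alt <- matrix(stats::rbinom(np * V, as.vector(depth), as.vector(p_read)),
                np, V)
  pools <- data.frame(pool = seq_len(np),
                      group = rep(c("case", "control"),
                                  c(design$n_case_pools, design$n_ctrl_pools)),
                      n = sizes)
  structure(list(alt = alt, depth = depth, pools = pools, design = design),
            class = "pooled_reads")
}

# round half away from zero (preserves singletons better than truncation)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Estimate diploid group allele counts from pooled reads
#'
#' For every pool the minor-chromosome fraction is estimated from the read
#' fraction, debiased for the per-read miscall rate
#' (`(alt/depth - e) / (1 - 2e)`, floored at 0), converted to a per-pool
#' integer minor-allele count (`round(2 * n_pool * f)`, halves away from
#' zero), and summed within each group. Per-pool rounding, rather than
#' rounding one depth-weighted group mean, is what preserves singletons:
#' a single carrier chromosome concentrates in one pool where it is a 1/(2n)
#' read fraction, well above the error floor.
#'
#' Variants with zero depth in every pool are flagged dropped
#' (`"no_coverage"`); variants whose estimated cohort minor count is 0 are
#' flagged dropped as monomorphic.
#'
#' @param reads A `pooled_reads` object.
#' @param design The matching [cohort_design()]; defaults to the design
#'   stored in `reads`.
#' @param error_rate Miscall rate assumed by the estimator; defaults to the
#'   design's generative value.
#' @return A data frame with one row per variant: estimated `min_case`,
#'   `maj_case`, `min_ctrl`, `maj_ctrl`, logical `dropped` and
#'   `drop_reason` (`NA`, `"no_coverage"` or `"monomorphic"`).
#' @export
estimate_pooled_counts <- function(reads, design = reads$design,
                                   error_rate = design$seq_error_rate) {
  stopifnot(inherits(reads, "pooled_reads"))
  e <- error_rate
  with_depth <- reads$depth > 0
  fhat <- matrix(0, nrow(reads$alt), ncol(reads$alt))
  fhat[with_depth] <- pmax(0, (reads$alt[with_depth] / reads$depth[with_depth] - e) /
                              (1 - 2 * e))
  n_pool <- reads$pools$n
  cnt <- .round_half_away(fhat * 2 * n_pool)
  cnt <- pmin(cnt, 2 * n_pool)            # a pool cannot exceed its chromosomes
  cnt[!with_depth] <- 0
  is_case <- reads$pools$group == "case"
  min_case <- pmin(colSums(cnt[is_case, , drop = FALSE]), 2 * design$n_cases)
  min_ctrl <- pmin(colSums(cnt[!is_case, , drop = FALSE]), 2 * design$n_controls)
  no_cov <- colSums(with_depth) == 0
  mono <- !no_cov & (min_case + min_ctrl) == 0
  out <- data.frame(
    min_case = as.integer(min_case),
    maj_case = as.integer(2 * design$n_cases - min_case),
    min_ctrl = as.integer(min_ctrl),
    maj_ctrl = as.integer(2 * design$n_controls - min_ctrl),
    dropped = no_cov | mono,
    drop_reason = ifelse(no_cov, "no_coverage",
                         ifelse(mono, "monomorphic", NA_character_)),
    stringsAsFactors = FALSE
  )
  out$min_case[no_cov] <- out$min_ctrl[no_cov] <- NA_integer_
  out$maj_case[no_cov] <- out$maj_ctrl[no_cov] <- NA_integer_
  out
}

#' Simulate a full pooled-sequencing cohort
#'
#' Convenience wrapper running [simulate_genotypes()], [pool_and_sequence()]
#' and [estimate_pooled_counts()] and assembling a variant table ready for
#' [adjust_minor_allele()] and the downstream association stages. Dropped
#' variants (no coverage, or monomorphic after estimation) are excluded from
#' the variant table but reported in the `dropped` element.
#'
#' @param design A [cohort_design()].
#' @param specs A variant-specification data frame; defaults to a null panel
#'   of `n_variants` variants drawn with the design seed.
#' @param n_variants Panel size used when `specs` is not supplied.
#' @param keep_genotypes Keep the individual-level genotype matrix in the
#'   result (needed for exact gene-based testing).
#' @return A list of class `sim_cohort` with elements `variants` (a variant
#'   table, see [variant_table()]), `genotypes` (optional), `reads`,
#'   `dropped` (data frame of dropped variants with reasons), `truth`
#'   (the generating specs joined to variant keys) and `design`.
#' @export
simulate_cohort <- function(design, specs = NULL, n_variants = 1000L,
                            keep_genotypes = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(specs))
    specs <- simulate_variant_specs(n_variants, seed = design$seed)
  g <- simulate_genotypes(design, specs)
  reads <- pool_and_sequence(g, design)
  est <- estimate_pooled_counts(reads, design)

  V <- nrow(specs)
  chrom <- paste0("chr", rep_len(1:22, V))
  pos <- seq_len(V) * 101L + 1000L
  vt <- data.frame(
    chrom = chrom, pos = pos,
    ref = rep_len(c("A", "C", "G", "T"), V),
    alt = rep_len(c("G", "T", "A", "C"), V),
    gene = specs$gene, consequence = specs$consequence_class,
    est[, c("min_case", "maj_case", "min_ctrl", "maj_ctrl")],
    swapped = FALSE,
    specs[, setdiff(colnames(specs),
                    c("gene", "consequence_class",
                      "true_maf_cases", "true_maf_controls", "planted"))],
    stringsAsFactors = FALSE
  )
  vt$key <- variant_key(vt)
  truth <- cbind(key = vt$key, specs, stringsAsFactors = FALSE)
  dropped <- data.frame(key = vt$key[est$dropped],
                        reason = est$drop_reason[est$dropped],
                        stringsAsFactors = FALSE)
  keep <- !est$dropped
  out <- list(variants = variant_table(vt[keep, , drop = FALSE]),
              genotypes = if (keep_genotypes) g[, keep, drop = FALSE],
              reads = reads, dropped = dropped, truth = truth,
              design = design)
  class(out) <- "sim_cohort"
  out
}

#' Write a simulated cohort to disk
#'
#' Emits the retained variants as a minimal VCF v4.2 (`cohort.vcf`, with
#' INFO keys `MINC_CASE`, `MINC_CTRL`, `N_CASE`, `N_CTRL`) plus an
#' annotation TSV (`annotations.tsv`) keyed by `CHROM:POS:REF:ALT`, and the
#' true simulation parameters (generating frequencies, planted flags,
#' dropped variants, design) as a JSON sidecar (`truth.json`) for
#' parameter-recovery experiments.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "cohort.vcf")
  ann <- file.path(dir, "annotations.tsv")
  truth <- file.path(dir, "truth.json")
  write_variants(sim$variants, vcf, ann)
  jsonlite::write_json(
    list(design = unclass(sim$design), truth = sim$truth,
         dropped = sim$dropped),
    truth, auto_unbox = TRUE, digits = 10, dataframe = "columns")
  invisible(c(vcf = vcf, ann = ann, truth = truth))
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Simulated pooled-sequencing cohort: %d variants retained, %d dropped\n",
              nrow(x$variants), nrow(x$dropped)))
  print(x$design)
  invisible(x)
}
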