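#' Two-sided Fisher exact p-value for diploid allele-count tables
#'
#' For each variant the 2x2 table (minor/major allele by case/control) is
#' tested with Fisher's exact test, two-sided by the minimum-likelihood rule:
#' the p-value is the sum of hypergeometric probabilities of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table (with the standard `1 + 1e-7` relative guard against
#' floating-point ties, as in [stats::fisher.test()]). Vectorized over
#' variants; degenerate tables with both minor cells zero return `p = 1`.
#'
#' @param min_case,maj_case,min_ctrl,maj_ctrl Non-negative integer vectors of
#'   diploid allele counts (recycled to common length).
#' @return Numeric vector of two-sided p-values in `(0, 1]`.
#' @export
fisher_exact_two_sided <- function(min_case, maj_case, min_ctrl, maj_ctrl) {
  n <- max(length(min_case), length(maj_case), length(min_ctrl), length(maj_ctrl))
  a <- rep_len(as.numeric(min_case), n); b <- rep_len(as.numeric(maj_case), n)
  c_ <- rep_len(as.numeric(min_ctrl), n); d <- rep_len(as.numeric(maj_ctrl), n)
  if (any(c(a, b, c_, d) < 0)) stop("allele counts must be non-negative")
  if (any(a + b <= 0) || any(c_ + d <= 0)) stop("both row sums must be positive")
  p <- numeric(n)
  for (i in seq_len(n)) {
    k <- a[i] + c_[i]                     # total minor alleles
    r1 <- a[i] + b[i]                     # case chromosomes
    N <- r1 + c_[i] + d[i]
    lo <- max(0, k - (N - r1)); hi <- min(k, r1)
    x <- lo:hi
    pr <- stats::dhyper(x, k, N - k, r1)
    p[i] <- min(1, sum(pr[pr <= pr[a[i] - lo + 1] * (1 + 1e-7)]))
  }
  p
}

#' Odds ratio with continuity correction
#'
#' `(min_case * maj_ctrl) / (maj_case * min_ctrl)`, with 0.5 added to every
#' cell when any cell is zero. For reporting only; never used for p-values.
#'
#' @inheritParams fisher_exact_two_sided
#' @return Numeric vector of odds ratios.
#' @export
odds_ratio <- function(min_case, maj_case, min_ctrl, maj_ctrl) {
  zero <- min_case == 0 | maj_case == 0 | min_ctrl == 0 | maj_ctrl == 0
  cc <- ifelse(zero, 0.5, 0)
  ((min_case + cc) * (maj_ctrl + cc)) / ((maj_case + cc) * (min_ctrl + cc))
}

#' Per-variant association analysis
#'
#' Runs the two-sided Fisher exact test on every variant of an adjusted
#' variant table, attaches minor-allele frequencies, enrichment
#' directionality, rarity and singleton labels ([partition()]) and
#' multiplicity-adjusted values ([correct_multiplicity()]).
#'
#' @param variants An adjusted [variant_table()] (see
#'   [adjust_minor_allele()]).
#' @param alpha Nominal significance level.
#' @param maf_threshold Cohort-MAF boundary between rare and common
#'   (`rare` is inclusive: `MAF <= maf_threshold`).
#' @param m Number of tests for multiplicity correction; defaults to the
#'   number of variants.
#' @return A data frame of class `assoc_result`: one row per variant with
#'   `key`, `gene`, `chrom`, `pos`, `consequence`, `p_value`, `odds_ratio`,
#'   `maf_cases`, `maf_controls`, `maf_cohort`, `enriched`, `rarity`,
#'   `singleton`, `p_bonferroni`, `q_bh`.
#' @export
associate <- function(variants, alpha = 0.05, maf_threshold = 0.010, m = NULL) {
  variants <- adjust_minor_allele(variants)
  res <- data.frame(
    key = variants$key, gene = variants$gene,
    chrom = variants$chrom, pos = variants$pos,
    consequence = variants$consequence,
    min_case = variants$min_case, maj_case = variants$maj_case,
    min_ctrl = variants$min_ctrl, maj_ctrl = variants$maj_ctrl,
    p_value = fisher_exact_two_sided(variants$min_case, variants$maj_case,
                                     variants$min_ctrl, variants$maj_ctrl),
    odds_ratio = odds_ratio(variants$min_case, variants$maj_case,
                            variants$min_ctrl, variants$maj_ctrl),
    maf_cases = maf(variants, "cases"),
    maf_controls = maf(variants, "controls"),
    maf_cohort = maf(variants, "cohort"),
    stringsAsFactors = FALSE
  )
  res <- partition(res, maf_threshold = maf_threshold)
  res <- correct_multiplicity(res, m = if (is.null(m)) nrow(res) else m,
                              alpha = alpha)
  class(res) <- unique(c("assoc_result", class(res)))
  res
}

#' Multiplicity correction (Bonferroni and Benjamini-Hochberg)
#'
#' Adds `p_bonferroni = min(1, p * m)` and the step-up Benjamini-Hochberg
#' adjusted value `q_bh` (computed over `m` tests); the per-test Bonferroni
#' threshold `alpha / m` is stored as the `"bonferroni_threshold"` attribute.
#' With the study's 660 candidate-gene tests and `alpha = 0.05` the threshold
#' is 7.58e-5.
#'
#' @param results A data frame with a `p_value` column.
#' @param m Total number of tests (`>=` the number of rows).
#' @param alpha Familywise level, in `(0, 1)`.
#' @return `results` with `p_bonferroni` and `q_bh` columns.
#' @export
correct_multiplicity <- function(results, m = nrow(results), alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (m < nrow(results)) stop("m must be at least the number of results")
  results$p_bonferroni <- pmin(1, results$p_value * m)
  results$q_bh <- stats::p.adjust(results$p_value, method = "BH", n = m)
  attr(results, "bonferroni_threshold") <- alpha / m
  attr(results, "m_tests") <- m
  results
}

#' Label rarity, singleton status and enrichment directionality
#'
#' `rarity` is `"rare"` iff the cohort MAF is at most `maf_threshold`
#' (boundary inclusive); `singleton` iff the cohort minor-allele count is
#' exactly 1; `enriched` iff the case MAF strictly exceeds the control MAF
#' (ties count as depleted).
#'
#' @param results A data frame with `min_case`, `min_ctrl`, `maf_cases`,
#'   `maf_controls`, `maf_cohort` columns.
#' @param maf_threshold Rare/common boundary.
#' @return `results` with `enriched`, `rarity`, `singleton` columns.
#' @export
partition <- function(results, maf_threshold = 0.010) {
  results$enriched <- results$maf_cases > results$maf_controls
  results$rarity <- ifelse(results$maf_cohort <= maf_threshold, "rare", "common")
  results$singleton <- (results$min_case + results$min_ctrl) == 1
  results
}

#' Summaries of the variant distribution
#'
#' Produces the per-class counts and percentages (overall and within coding
#' variants), and the centenarian-enriched fraction by rarity stratum, both
#' over all variants and restricted to nominally significant ones.
#'
#' @param results An [associate()] result.
#' @param exclude_singletons Drop singletons before summarising.
#' @param alpha Significance level for the significant-only stratification.
#' @return A list with elements `n`, `class_counts`, `class_percent`,
#'   `coding_counts`, `coding_percent`, `coding_share`,
#'   `enriched_fraction` and `enriched_fraction_significant` (each a named
#'   vector/table; percentages in 0-100).
#' @export
summarize_distributions <- function(results, exclude_singletons = FALSE,
                                    alpha = 0.05) {
  if (nrow(results) == 0) {
    warning("empty association table; empty summary")
    return(list(n = 0L))
  }
  if (exclude_singletons) results <- results[!results$singleton, , drop = FALSE]
  cls <- table(factor(results$consequence, levels = .valid_consequences))
  coding <- results$consequence %in% .coding_consequences
  ccl <- table(factor(results$consequence[coding], levels = .coding_consequences))
  enr_frac <- function(df) {
    sp <- split(df$enriched, df$rarity)
    vapply(sp, function(z) 100 * mean(z), numeric(1))
  }
  sig <- results[results$p_value <= alpha, , drop = FALSE]
  list(
    n = nrow(results),
    class_counts = cls,
    class_percent = 100 * cls / sum(cls),
    coding_counts = ccl,
    coding_percent = if (sum(ccl) > 0) 100 * ccl / sum(ccl) else ccl,
    coding_share = 100 * mean(coding),
    enriched_fraction = enr_frac(results),
    enriched_fraction_significant = if (nrow(sig)) enr_frac(sig) else numeric(0)
  )
}

#' Export a Manhattan-ready table
#'
#' @param results An [associate()] result.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_manhattan <- function(results, path) {
  out <- data.frame(chrom = results$chrom, pos = results$pos,
                    gene = results$gene, p = results$p_value,
                    neglog10_p = -log10(results$p_value))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
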