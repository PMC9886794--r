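#' Prioritization thresholds
#'
#' @param alpha Single-variant association gate (criterion 1).
#' @param cadd_min CADD-phred score counting as a damaging prediction
#'   (criterion 4; 15 = possibly damaging, 20 = likely damaging).
#' @param regulome_max Maximum Regulome rank counting as regulatory evidence
#'   for non-coding variants (criterion 4).
#' @param external_maf_max Maximum external population MAF corroborating
#'   rarity (criterion 5); total absence from external populations passes.
#' @return A validated list of thresholds.
#' @export
prioritize_config <- function(alpha = 0.05, cadd_min = 15, regulome_max = 3,
                              external_maf_max = 0.010) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (cadd_min < 0) stop("cadd_min must be non-negative")
  if (!regulome_max %in% 1:7) stop("regulome_max must be an integer rank 1-7")
  if (external_maf_max < 0 || external_maf_max > 1)
    stop("external_maf_max must lie in [0, 1]")
  list(alpha = alpha, cadd_min = cadd_min, regulome_max = regulome_max,
       external_maf_max = external_maf_max)
}

.external_maf_cols <- c("maf_1kg", "maf_gnomad", "maf_exac", "maf_discovehr")

#' Apply the six-criterion variant filter
#'
#' Evaluates, for every nominally significant variant, the annotation
#' cascade used to nominate longevity-associated variants (LAVs):
#' \enumerate{
#'   \item association signal `p <= alpha` (hard gate: failing variants are
#'     not emitted);
#'   \item enrichment directionality (case MAF strictly above control MAF) —
#'     a priority key, not a gate, since depleted variants may still rank;
#'   \item location tier: nonsynonymous > other coding > non-coding;
#'   \item predicted impact: a nonsynonymous variant passes with a
#'     non-conservative or radical substitution *and* a damaging prediction
#'     (Condel deleterious or CADD-phred at least `cadd_min`); other coding
#'     variants pass on a damaging prediction alone; non-coding variants
#'     pass on a strong Regulome rank (`<= regulome_max`) or an explicit
#'     regulatory-evidence flag; missing evidence yields `unknown`, never a
#'     pass;
#'   \item external rarity corroboration: every available external
#'     population MAF at most `external_maf_max`, with total absence
#'     passing (absence from all populations being the strongest rarity
#'     signal) and no external record at all marked `pass` as well;
#'   \item a-priori biological evidence: an integer count of evidence lines
#'     (conservation flags plus curated evidence notes), used as a ranking
#'     key.
#' }
#'
#' @param assoc An [associate()] result.
#' @param variants The matching classified [variant_table()] (see
#'   [classify_table()]).
#' @param config Thresholds from [prioritize_config()].
#' @return A data frame of class `priority_records`: one row per
#'   criterion-1-passing variant with every criterion state recorded.
#' @export
apply_criteria <- function(assoc, variants, config = prioritize_config()) {
  idx <- match(assoc$key, variants$key)
  if (anyNA(idx)) stop("association results and variant table do not match")
  keep <- assoc$p_value <= config$alpha
  a <- assoc[keep, , drop = FALSE]
  v <- variants[idx[keep], , drop = FALSE]

  tier <- ifelse(v$consequence == "nonsynonymous", "nsV",
                 ifelse(v$consequence %in% .coding_consequences,
                        "other_coding", "ncV"))

  cadd <- if ("cadd_phred" %in% colnames(v)) v$cadd_phred else rep(NA_real_, nrow(v))
  condel <- if ("condel_label" %in% colnames(v)) v$condel_label else rep(NA_character_, nrow(v))
  regulome <- if ("regulome_rank" %in% colnames(v)) v$regulome_rank else rep(NA_integer_, nrow(v))
  reg_flag <- if ("regulatory_evidence" %in% colnames(v)) v$regulatory_evidence %in% TRUE else rep(FALSE, nrow(v))
  label <- if ("aa_label" %in% colnames(v)) v$aa_label else rep(NA_character_, nrow(v))

  damaging <- ifelse(!is.na(condel) & condel == "deleterious", TRUE,
                     ifelse(!is.na(cadd) & cadd >= config$cadd_min, TRUE,
                            ifelse(is.na(condel) & is.na(cadd), NA, FALSE)))
  c4 <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    c4[i] <- switch(tier[i],
      nsV = {
        if (is.na(label[i])) "unknown"
        else if (label[i] == "C") "fail"
        else if (is.na(damaging[i])) "unknown"
        else if (damaging[i]) "pass" else "fail"
      },
      other_coding = {
        if (is.na(damaging[i])) "unknown"
        else if (damaging[i]) "pass" else "fail"
      },
      ncV = {
        strong <- !is.na(regulome[i]) & regulome[i] <= config$regulome_max
        if (strong || reg_flag[i]) "pass"
        else if (is.na(regulome[i]) && !reg_flag[i]) "unknown" else "fail"
      })
  }

  ext <- as.matrix(v[, intersect(.external_maf_cols, colnames(v)), drop = FALSE])
  if (ncol(ext)) {
    any_high <- rowSums(ext > config$external_maf_max, na.rm = TRUE) > 0
    c5 <- ifelse(any_high, "fail", "pass")   # absence everywhere passes
  } else {
    c5 <- rep("pass", nrow(v))
  }

  ev <- integer(nrow(v))
  if ("vert_conserved" %in% colnames(v)) ev <- ev + (v$vert_conserved %in% TRUE)
  if ("invert_conserved" %in% colnames(v)) ev <- ev + (v$invert_conserved %in% TRUE)
  if ("evidence_notes" %in% colnames(v)) {
    en <- v$evidence_notes; en[is.na(en)] <- 0L
    ev <- ev + as.integer(en)
  }

  out <- data.frame(
    key = a$key, gene = a$gene, chrom = a$chrom, pos = a$pos,
    p_value = a$p_value, maf_cases = a$maf_cases,
    maf_controls = a$maf_controls, rarity = a$rarity,
    c1_assoc = rep("pass", nrow(a)),
    c2_enriched = ifelse(a$enriched, "pass", "fail"),
    c3_location_tier = tier, c4_impact = c4, c5_external = c5,
    c6_evidence = ev,
    vert_conserved = if ("vert_conserved" %in% colnames(v))
      v$vert_conserved %in% TRUE else rep(FALSE, nrow(v)),
    invert_conserved = if ("invert_conserved" %in% colnames(v))
      v$invert_conserved %in% TRUE else rep(FALSE, nrow(v)),
    stringsAsFactors = FALSE
  )
  class(out) <- unique(c("priority_records", class(out)))
  out
}

#' Rank prioritized variants
#'
#' Deterministic lexicographic ordering following the criteria's order:
#' enriched before depleted; nonsynonymous before other coding before
#' non-coding; impact pass > unknown > fail; external corroboration
#' pass > unknown > fail; more a-priori evidence first; then ascending
#' p-value; then genomic coordinate (`chrom`, `pos`) as the final tiebreak.
#' The order is a stable total order, invariant to input permutation.
#'
#' @param records Output of [apply_criteria()].
#' @return `records` sorted, with a `rank` column.
#' @export
rank_priorities <- function(records) {
  lv <- function(x, levels) as.integer(factor(x, levels = levels))
  o <- order(lv(records$c2_enriched, c("pass", "fail")),
             lv(records$c3_location_tier, c("nsV", "other_coding", "ncV")),
             lv(records$c4_impact, c("pass", "unknown", "fail")),
             lv(records$c5_external, c("pass", "unknown", "fail")),
             -records$c6_evidence,
             records$p_value,
             records$chrom, records$pos)
  out <- records[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Hotspot genes with multiple prioritized nonsynonymous variants
#'
#' @param records Ranked [priority records][rank_priorities()].
#' @param min_nsv Minimum number of prioritized nonsynonymous variants.
#' @return A data frame `gene`, `n_nsv`, `variants` (comma-separated keys);
#'   empty when no gene qualifies.
#' @export
hotspot_genes <- function(records, min_nsv = 2L) {
  nsv <- records[records$c3_location_tier == "nsV", , drop = FALSE]
  if (!nrow(nsv))
    return(data.frame(gene = character(), n_nsv = integer(),
                      variants = character(), stringsAsFactors = FALSE))
  sp <- split(nsv$key, nsv$gene)
  sp <- sp[lengths(sp) >= min_nsv]
  data.frame(gene = names(sp), n_nsv = lengths(sp),
             variants = vapply(sp, paste, "", collapse = ","),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summary counts over the prioritized variant set
#'
#' Shares are recomputed from the record list, never stored.
#'
#' @param records Ranked [priority records][rank_priorities()].
#' @return A list with `n_prioritized`, `n_nsv`, `enriched_share_percent`,
#'   `rare_share_percent`, `n_vert_conserved`, `n_invert_conserved`.
#' @export
lav_summary <- function(records) {
  n <- nrow(records)
  list(
    n_prioritized = n,
    n_nsv = sum(records$c3_location_tier == "nsV"),
    enriched_share_percent = if (n) 100 * mean(records$c2_enriched == "pass") else NA_real_,
    rare_share_percent = if (n) 100 * mean(records$rarity == "rare") else NA_real_,
    n_vert_conserved = sum(records$vert_conserved),
    n_invert_conserved = sum(records$invert_conserved)
  )
}
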