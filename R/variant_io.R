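#' Construct and validate a variant table
#'
#' The central data structure of the package is a plain data frame with one
#' row per bi-allelic site. Required columns: `chrom`, `pos` (1-based),
#' `ref`, `alt`, `gene`, `consequence` (controlled vocabulary), and the
#' diploid allele counts `min_case`, `maj_case`, `min_ctrl`, `maj_ctrl`.
#' Any further columns (impact scores, external population frequencies,
#' conservation flags, amino-acid change fields, ...) are carried through
#' verbatim. A `key` column (`CHROM:POS:REF:ALT`) and a logical `swapped`
#' column are added when absent.
#'
#' @param x A data frame with the required columns.
#' @return The validated data frame, with class `c("variant_table","data.frame")`.
#' @export
variant_table <- function(x) {
  req <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
           "min_case", "maj_case", "min_ctrl", "maj_ctrl")
  miss <- setdiff(req, colnames(x))
  if (length(miss))
    stop("variant table misses required columns: ", paste(miss, collapse = ", "))
  if (any(x$pos < 1)) stop("positions are 1-based and must be >= 1")
  bad <- setdiff(unique(x$consequence), .valid_consequences)
  if (length(bad))
    stop("unknown consequence class: ", paste(bad, collapse = ", "))
  cnt <- as.matrix(x[, c("min_case", "maj_case", "min_ctrl", "maj_ctrl")])
  if (any(cnt < 0, na.rm = TRUE)) stop("allele counts must be non-negative")
  if (nrow(x) > 1) {
    if (length(unique(x$min_case + x$maj_case)) != 1 ||
        length(unique(x$min_ctrl + x$maj_ctrl)) != 1)
      stop("group chromosome totals must be constant across variants")
  }
  if (is.null(x$swapped)) x$swapped <- FALSE
  if (is.null(x$key)) x$key <- variant_key(x)
  rownames(x) <- NULL
  class(x) <- unique(c("variant_table", class(x)))
  x
}

#' Canonical variant key
#'
#' @param x A data frame with `chrom`, `pos`, `ref`, `alt` columns.
#' @return Character vector `CHROM:POS:REF:ALT`.
#' @export
variant_key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

#' Ensure ALT is the minor allele
#'
#' Whenever the cohort frequency of the ALT allele strictly exceeds 0.5, the
#' REF/ALT alleles are exchanged and the minor/major counts of both groups
#' swapped consistently; the `swapped` flag records the exchange. A cohort
#' frequency of exactly 0.5 is left untouched (ties keep ALT as the minor
#' allele). The operation is idempotent.
#'
#' @param variants A [variant_table()].
#' @return The adjusted variant table (keys recomputed for swapped rows).
#' @export
adjust_minor_allele <- function(variants) {
  variants <- variant_table(variants)
  minc <- variants$min_case + variants$min_ctrl
  tot <- minc + variants$maj_case + variants$maj_ctrl
  swap <- minc / tot > 0.5
  if (any(swap)) {
    v <- variants[swap, ]
    variants[swap, c("min_case", "maj_case", "min_ctrl", "maj_ctrl")] <-
      v[, c("maj_case", "min_case", "maj_ctrl", "min_ctrl")]
    variants[swap, c("ref", "alt")] <- v[, c("alt", "ref")]
    variants$swapped[swap] <- !v$swapped
    variants$key[swap] <- variant_key(variants[swap, ])
  }
  variants
}

#' Minor-allele frequency of a variant table
#'
#' Cohort MAF is guaranteed in `[0, 0.5]` after [adjust_minor_allele()];
#' a single group's frequency may exceed 0.5 because the adjustment is made
#' at cohort level.
#'
#' @param variants A [variant_table()].
#' @param group `"cohort"`, `"cases"` or `"controls"`.
#' @return Numeric vector of frequencies.
#' @export
maf <- function(variants, group = c("cohort", "cases", "controls")) {
  group <- match.arg(group)
  num <- switch(group,
                cohort = variants$min_case + variants$min_ctrl,
                cases = variants$min_case,
                controls = variants$min_ctrl)
  den <- switch(group,
                cohort = variants$min_case + variants$maj_case +
                  variants$min_ctrl + variants$maj_ctrl,
                cases = variants$min_case + variants$maj_case,
                controls = variants$min_ctrl + variants$maj_ctrl)
  if (any(den == 0, na.rm = TRUE)) stop("zero chromosome total")
  num / den
}

# ---- file formats -----------------------------------------------------------

.vcf_header <- function(n_case, n_ctrl) c(
  "##fileformat=VCFv4.2",
  "##source=longevar",
  "##INFO=<ID=MINC_CASE,Number=A,Type=Integer,Description=\"Minor allele count in cases (diploid)\">",
  "##INFO=<ID=MINC_CTRL,Number=A,Type=Integer,Description=\"Minor allele count in controls (diploid)\">",
  sprintf("##INFO=<ID=N_CASE,Number=1,Type=Integer,Description=\"Number of case individuals (%d)\">", n_case),
  sprintf("##INFO=<ID=N_CTRL,Number=1,Type=Integer,Description=\"Number of control individuals (%d)\">", n_ctrl),
  "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Mapped gene symbol\">",
  "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"Consequence class\">",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
)

#' Write a variant table as a minimal VCF plus annotation TSV
#'
#' The VCF (v4.2, sites only) encodes diploid group allele counts in INFO
#' keys `MINC_CASE`, `MINC_CTRL`, `N_CASE`, `N_CTRL` plus `GENE` and `CSQ`.
#' All remaining columns are written to a tab-separated annotation file keyed
#' by `CHROM:POS:REF:ALT`.
#'
#' @param variants A [variant_table()].
#' @param vcf_path,ann_path Output paths (annotation file optional).
#' @return Invisibly, the paths written.
#' @export
write_variants <- function(variants, vcf_path, ann_path = NULL) {
  variants <- variant_table(variants)
  n_case <- (variants$min_case + variants$maj_case)[1] / 2
  n_ctrl <- (variants$min_ctrl + variants$maj_ctrl)[1] / 2
  info <- sprintf("MINC_CASE=%d;MINC_CTRL=%d;N_CASE=%d;N_CTRL=%d;GENE=%s;CSQ=%s",
                  variants$min_case, variants$min_ctrl,
                  as.integer(n_case), as.integer(n_ctrl),
                  variants$gene, variants$consequence)
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", info, sep = "\t")
  writeLines(c(.vcf_header(n_case, n_ctrl), body), vcf_path)
  if (!is.null(ann_path)) {
    ann_cols <- setdiff(colnames(variants),
                        c("chrom", "pos", "ref", "alt", "gene", "consequence",
                          "min_case", "maj_case", "min_ctrl", "maj_ctrl",
                          "swapped"))
    ann <- variants[, c("key", setdiff(ann_cols, "key")), drop = FALSE]
    utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(c(vcf = vcf_path, ann = ann_path))
}

.parse_info_field <- function(info) {
  kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- vapply(kv, function(p) if (length(p) > 1) p[2] else "", "")
  names(vals) <- vapply(kv, `[`, "", 1)
  vals
}

#' Read variants from a VCF (or flat TSV) and an annotation TSV
#'
#' Sites are read with `vcfR`; multi-allelic records are split into one
#' bi-allelic record per ALT allele, attributing the per-allele INFO entries
#' (`Number=A`) to the matching ALT. Records are joined to the annotation
#' table by `CHROM:POS:REF:ALT`; annotation rows without a matching site are
#' reported via a message but are not fatal, and unknown annotation columns
#' are preserved verbatim.
#'
#' @param vcf_path Path to a VCF v4.2 file with the INFO keys written by
#'   [write_variants()], or a flat tab-separated file with the variant-table
#'   columns (detected by extension `.tsv`/`.txt`).
#' @param ann_path Optional annotation TSV keyed by `CHROM:POS:REF:ALT`.
#' @return A [variant_table()].
#' @export
read_variants <- function(vcf_path, ann_path = NULL) {
  if (!file.exists(vcf_path)) stop("no such file: ", vcf_path)
  if (grepl("\\.(tsv|txt)$", vcf_path, ignore.case = TRUE)) {
    vt <- utils::read.delim(vcf_path, stringsAsFactors = FALSE)
  } else {
    v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
    fix <- vcfR::getFIX(v, getINFO = TRUE)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    rows <- lapply(seq_len(nrow(fix)), function(i) {
      alts <- unname(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
      info <- .parse_info_field(fix[i, "INFO"])
      per_a <- function(key) {
        x <- unname(strsplit(info[[key]], ",", fixed = TRUE)[[1]])
        rep_len(x, length(alts))
      }
      info <- lapply(info, unname)
      for (key in c("MINC_CASE", "MINC_CTRL", "N_CASE", "N_CTRL", "GENE", "CSQ"))
        if (!key %in% names(info))
          stop("INFO key ", key, " absent at ", fix[i, "CHROM"], ":", fix[i, "POS"])
      data.frame(chrom = unname(fix[i, "CHROM"]),
                 pos = as.integer(fix[i, "POS"]),
                 ref = unname(fix[i, "REF"]), alt = alts,
                 gene = per_a("GENE"), consequence = per_a("CSQ"),
                 min_case = as.integer(per_a("MINC_CASE")),
                 min_ctrl = as.integer(per_a("MINC_CTRL")),
                 n_case = as.integer(info[["N_CASE"]]),
                 n_ctrl = as.integer(info[["N_CTRL"]]),
                 stringsAsFactors = FALSE)
    })
    vt <- do.call(rbind, rows)
    vt$maj_case <- 2L * vt$n_case - vt$min_case
    vt$maj_ctrl <- 2L * vt$n_ctrl - vt$min_ctrl
    vt$n_case <- vt$n_ctrl <- NULL
  }
  vt <- variant_table(vt)
  if (!is.null(ann_path)) {
    ann <- utils::read.delim(ann_path, stringsAsFactors = FALSE, na.strings = "")
    if (!"key" %in% colnames(ann)) stop("annotation TSV must carry a 'key' column")
    unmatched <- setdiff(ann$key, vt$key)
    if (length(unmatched))
      message(length(unmatched), " annotation row(s) without a matching site (ignored)")
    idx <- match(vt$key, ann$key)
    for (col in setdiff(colnames(ann), "key")) vt[[col]] <- ann[[col]][idx]
    vt <- variant_table(vt)
  }
  vt
}
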