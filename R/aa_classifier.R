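#' Amino-acid R-group property table
#'
#' The packaged table assigns, for each of the 20 canonical residues, a
#' charge class (K/R/H positive, D/E negative), a polarity class, a
#' hydropathy class derived from the sign of the Kyte-Doolittle index
#' (`> 0` hydrophobic, `< -1` hydrophilic, `[-1, 0]` neutral) and a size
#' class binned on residue volume (tiny `< 95` cubic Angstrom, small
#' `95-125`, medium `125-160`, large `> 160`). The table ships as an
#' editable TSV so alternative property conventions can be substituted.
#'
#' @param path Optional path to an alternative property TSV with the same
#'   columns.
#' @return A data frame with one row per canonical residue.
#' @export
aa_properties <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aa_properties.tsv", package = "longevar",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("residue", "charge", "polarity", "hydropathy", "size_class")
  miss <- setdiff(req, colnames(tab))
  if (length(miss)) stop("property table misses: ", paste(miss, collapse = ", "))
  if (nrow(tab) != 20L || anyDuplicated(tab$residue))
    stop("property table must contain exactly the 20 canonical residues")
  if (anyNA(tab[req])) stop("every property field must be populated")
  tab
}

#' Classify amino-acid substitutions as conservative / non-conservative / radical
#'
#' A substitution is compared property-by-property (charge, polarity,
#' hydropathy, size): `C` (conservative) iff zero properties differ, `R`
#' (radical) iff at least two differ *including* a change in size (a size
#' change is treated as the more drastic alteration because of potential
#' steric effects), and `NC` (non-conservative) otherwise. Vectorized over
#' pairs; the per-property difference flags are returned for auditability.
#'
#' @param ref_aa,alt_aa One-letter codes of the reference and substituted
#'   residues (recycled to common length). Non-canonical codes
#'   (B, Z, X, U, O, `*`, ...) are an error.
#' @param properties Property table from [aa_properties()].
#' @return A data frame with `ref_aa`, `alt_aa`, the four per-property
#'   `diff_*` flags, `n_diffs` and `label` (`"C"`, `"NC"`, `"R"`).
#' @export
classify_aa <- function(ref_aa, alt_aa, properties = aa_properties()) {
  n <- max(length(ref_aa), length(alt_aa))
  ref_aa <- rep_len(toupper(ref_aa), n); alt_aa <- rep_len(toupper(alt_aa), n)
  i <- match(ref_aa, properties$residue)
  j <- match(alt_aa, properties$residue)
  if (anyNA(i))
    stop("non-canonical residue: ", paste(unique(ref_aa[is.na(i)]), collapse = ", "))
  if (anyNA(j))
    stop("non-canonical residue: ", paste(unique(alt_aa[is.na(j)]), collapse = ", "))
  d <- sapply(c("charge", "polarity", "hydropathy", "size_class"),
              function(pp) properties[[pp]][i] != properties[[pp]][j])
  if (n == 1L) d <- matrix(d, nrow = 1,
                           dimnames = list(NULL, c("charge", "polarity",
                                                   "hydropathy", "size_class")))
  n_diffs <- rowSums(d)
  label <- ifelse(n_diffs == 0, "C",
                  ifelse(n_diffs >= 2 & d[, "size_class"], "R", "NC"))
  data.frame(ref_aa = ref_aa, alt_aa = alt_aa,
             diff_charge = d[, "charge"], diff_polarity = d[, "polarity"],
             diff_hydropathy = d[, "hydropathy"], diff_size = d[, "size_class"],
             n_diffs = as.integer(n_diffs), label = label,
             stringsAsFactors = FALSE)
}

#' Attach substitution labels to the nonsynonymous variants of a table
#'
#' Non-nonsynonymous records are left untouched (`aa_label` is `NA`); stop
#' gains carry no substituted residue and are not classified. Nonsynonymous
#' records lacking the amino-acid change annotation are labelled missing and
#' reported via a message.
#'
#' @param variants A [variant_table()] with `aa_ref` and `aa_alt` columns on
#'   its nonsynonymous rows.
#' @param properties Property table from [aa_properties()].
#' @return `variants` with `aa_label` and `aa_n_diffs` columns added.
#' @export
classify_table <- function(variants, properties = aa_properties()) {
  variants$aa_label <- NA_character_
  variants$aa_n_diffs <- NA_integer_
  nsv <- which(variants$consequence == "nonsynonymous")
  if (!length(nsv)) return(variants)
  has <- nsv[!is.na(variants$aa_ref[nsv]) & !is.na(variants$aa_alt[nsv])]
  missing <- setdiff(nsv, has)
  if (length(missing))
    message(length(missing),
            " nonsynonymous variant(s) without an amino-acid change annotation; labelled missing")
  if (length(has)) {
    cl <- classify_aa(variants$aa_ref[has], variants$aa_alt[has], properties)
    variants$aa_label[has] <- cl$label
    variants$aa_n_diffs[has] <- cl$n_diffs
  }
  variants
}
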