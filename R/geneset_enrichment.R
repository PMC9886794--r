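#' Filter an association-catalog table by trait-class p-value thresholds
#'
#' Rows mapped to lifespan-type traits ("lifespan", "aging", "longevity")
#' are kept at the laxer threshold `lifespan_p_max`; all other (age-related
#' disease) rows at `disease_p_max`. Both thresholds are inclusive.
#'
#' @param rows A data frame with columns `gene`, `trait`, `p_reported`,
#'   `study` (study accession/id).
#' @param category_map A data frame mapping `trait` to `category`, with a
#'   logical `is_lifespan` column; see [read_category_map()].
#' @param disease_p_max,lifespan_p_max Inclusion thresholds.
#' @return The filtered rows with a `category` column attached.
#' @export
filter_catalog <- function(rows, category_map, disease_p_max = 1e-8,
                           lifespan_p_max = 1e-6) {
  if (!nrow(rows)) {
    rows$category <- character(0)
    return(rows)
  }
  idx <- match(rows$trait, category_map$trait)
  rows$category <- category_map$category[idx]
  lifespan <- category_map$is_lifespan[idx] %in% TRUE
  keep <- ifelse(lifespan, rows$p_reported <= lifespan_p_max,
                 rows$p_reported <= disease_p_max)
  rows[keep, , drop = FALSE]
}

#' Remove duplicate catalog associations
#'
#' Within each (gene, trait, study) group only the most significant row is
#' retained; ties on p keep the first occurrence in input order.
#'
#' @param rows A catalog data frame with `gene`, `trait`, `study`,
#'   `p_reported`.
#' @return Deduplicated rows, original order preserved among survivors.
#' @export
dedupe_catalog <- function(rows) {
  if (!nrow(rows)) return(rows)
  grp <- paste(rows$gene, rows$trait, rows$study, sep = "\r")
  best <- tapply(seq_len(nrow(rows)), grp, function(i) i[which.min(rows$p_reported[i])])
  rows[sort(unlist(best)), , drop = FALSE]
}

#' Permutation gene-set enrichment against a configurable background
#'
#' For each category gene set, the observed overlap with the query set is
#' compared to overlaps of `B` random query-sized gene sets drawn uniformly
#' without replacement from the background; the empirical p-value is
#' `(1 + #permutation overlaps >= observed) / (B + 1)`. Typical backgrounds
#' are the whole genome (~21,000 genes), the mitochondrial proteome
#' (~2,220) or the sequenced candidate list (~660). Converges to the
#' hypergeometric upper tail as `B` grows.
#'
#' @param query Character vector of query gene symbols (must be a subset of
#'   the background).
#' @param sets Named list of category gene sets.
#' @param background Character vector of background gene symbols.
#' @param B Number of permutations (`>= 1000`).
#' @param seed Integer seed.
#' @param background_name Label recorded in the output.
#' @return A data frame of class `enrichment_result`: one row per category
#'   with `observed`, `expected`, `p_empirical`, `n_permutations`,
#'   `background`.
#' @export
enrich_genesets <- function(query, sets, background, B = 10000L, seed = 1L,
                            background_name = "background") {
  query <- unique(query); background <- unique(background)
  missing <- setdiff(query, background)
  if (length(missing))
    stop("query gene(s) absent from background: ",
         paste(utils::head(missing, 10), collapse = ", "))
  if (B < 1000) stop("B must be at least 1000")
  set.seed(seed)
  k <- length(query)
  member <- lapply(sets, function(s) background %in% s)
  obs <- vapply(sets, function(s) length(intersect(query, s)), integer(1))
  perm_counts <- matrix(0L, B, length(sets))
  nb <- length(background)
  for (b in seq_len(B)) {
    draw <- sample.int(nb, k)
    perm_counts[b, ] <- vapply(member, function(mm) sum(mm[draw]), integer(1))
  }
  p <- vapply(seq_along(sets), function(j)
    (1 + sum(perm_counts[, j] >= obs[j])) / (B + 1), numeric(1))
  out <- data.frame(category = names(sets), observed = obs,
                    expected = colMeans(perm_counts), p_empirical = p,
                    n_permutations = B, background = background_name,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- unique(c("enrichment_result", class(out)))
  out
}

#' Read a newline-delimited gene list
#' @param path File with one gene symbol per line (blank lines ignored).
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Read a trait-to-category map
#'
#' @param path TSV with columns `trait`, `category` and optionally
#'   `is_lifespan` (defaults to categories named "lifespan").
#' @return A data frame with `trait`, `category`, `is_lifespan`.
#' @export
read_category_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("trait", "category") %in% colnames(m)))
    stop("category map needs 'trait' and 'category' columns")
  if (is.null(m$is_lifespan)) m$is_lifespan <- m$category == "lifespan"
  m$is_lifespan <- m$is_lifespan %in% c(TRUE, "TRUE", "true", 1)
  m
}

#' Simulate a small GWAS-style association catalog
#'
#' Synthetic stand-in used by self-contained pipeline runs: draws
#' gene-trait-study rows over the supplied genes, with one category planted
#' at elevated frequency so enrichment is detectable.
#'
#' @param genes Gene symbols to draw from.
#' @param categories Category names.
#' @param n_rows Number of catalog rows.
#' @param planted_category Category over-represented among the first
#'   `length(genes) %/% 4` genes.
#' @param seed Integer seed.
#' @return A list with `catalog` (rows) and `category_map`.
#' @export
simulate_gwas_catalog <- function(genes,
                                  categories = c("metabolic", "cardiovascular",
                                                 "neurodegenerative",
                                                 "inflammatory", "cancer",
                                                 "lifespan"),
                                  n_rows = 400L, planted_category = "metabolic",
                                  seed = 1L) {
  set.seed(seed)
  traits <- paste0(rep(categories, each = 3), "_trait", 1:3)
  map <- data.frame(trait = traits,
                    category = rep(categories, each = 3),
                    is_lifespan = rep(categories == "lifespan", each = 3),
                    stringsAsFactors = FALSE)
  planted_genes <- genes[seq_len(max(1L, length(genes) %/% 4))]
  gene <- sample(genes, n_rows, replace = TRUE)
  trait <- sample(traits, n_rows, replace = TRUE)
  planted <- trait %in% map$trait[map$category == planted_category]
  gene[planted] <- sample(planted_genes, sum(planted), replace = TRUE)
  catalog <- data.frame(
    gene = gene, trait = trait,
    p_reported = 10^-stats::runif(n_rows, 6, 20),
    study = sprintf("GCST%04d", sample.int(40L, n_rows, replace = TRUE)),
    stringsAsFactors = FALSE)
  list(catalog = catalog, category_map = map)
}
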