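#' Intercept-only logistic null model for case/control status
#'
#' The study design has no covariates, so the null fit is closed-form: the
#' fitted probability is the case fraction, residuals are `y - mean(y)` and
#' the Bernoulli variance weight is constant.
#'
#' @param phenotype 0/1 vector (1 = case/centenarian).
#' @return An object of class `lv_null` with elements `y`, `n`, `n_case`,
#'   `mu` (fitted probability), `resid`, `v` (Bernoulli variance `mu(1-mu)`)
#'   and `s2` (the exact permutation variance factor `sum(resid^2)/(n-1)`).
#' @export
null_model <- function(phenotype) {
  y <- as.integer(phenotype)
  if (any(is.na(y)) || any(!y %in% c(0L, 1L))) stop("phenotype must be 0/1")
  if (length(unique(y)) < 2L) stop("both phenotype classes must be present")
  n <- length(y); mu <- mean(y)
  r <- y - mu
  structure(list(y = y, n = n, n_case = sum(y), mu = mu, resid = r,
                 v = mu * (1 - mu), s2 = sum(r^2) / (n - 1)),
            class = "lv_null")
}

#' @export
print.lv_null <- function(x, ...) {
  cat(sprintf("Intercept-only case/control null model: %d cases / %d controls (fitted p = %.4f)\n",
              x$n_case, x$n - x$n_case, x$mu))
  invisible(x)
}

#' Beta-density minor-allele-frequency weights
#'
#' The conventional up-weighting of rare variants in kernel association
#' tests: `w_j = dbeta(maf_j, a1, a2)`. The default `(1, 25)` concentrates
#' weight below 1% MAF; `(0.5, 0.5)` gives the milder weighting used for the
#' common-variant partition of the combined test.
#'
#' @param maf Minor-allele frequencies in `[0, 0.5]`.
#' @param shape Length-2 beta shape parameters.
#' @return Numeric weight vector.
#' @export
beta_maf_weights <- function(maf, shape = c(1, 25)) {
  stats::dbeta(maf, shape[1], shape[2])
}

# observed minor-allele frequency per genotype column
.geno_maf <- function(G) {
  f <- colMeans(G) / 2
  pmin(f, 1 - f)
}

.check_genotypes <- function(G) {
  if (is.null(dim(G))) G <- matrix(G, ncol = 1)
  poly <- apply(G, 2, function(g) stats::var(g) > 0)
  if (!any(poly)) stop("untestable gene: no polymorphic variants")
  G[, poly, drop = FALSE]
}

#' Variance-component kernel statistic
#'
#' `Q = sum_j w_j^2 (sum_i resid_i g_ij)^2`, the squared weighted score sums
#' over the variants of one gene. `Q = 0` iff every weighted score is 0.
#'
#' @param genotypes Individuals x variants minor-dosage matrix (0/1/2) for
#'   one gene.
#' @param null A [null_model()] fit on the same individuals.
#' @param weights Per-variant weights; defaults to
#'   [beta_maf_weights()] of the observed MAFs.
#' @return The scalar statistic `Q`.
#' @export
kernel_statistic <- function(genotypes, null, weights = NULL) {
  G <- .check_genotypes(genotypes)
  if (is.null(weights)) weights <- beta_maf_weights(.geno_maf(G))
  if (length(weights) != ncol(G)) stop("one weight per (polymorphic) variant")
  S <- drop(crossprod(G, null$resid))
  sum((weights * S)^2)
}

# shared internals: weighted centred genotype factor and observed Q
.kernel_parts <- function(G, null, weights) {
  Zc <- scale(G, center = TRUE, scale = FALSE)
  Zw <- Zc * rep(weights, each = nrow(Zc))
  S <- drop(crossprod(G, null$resid))
  list(Zw = Zw, S = S, Qs = sum((weights * S)^2),
       Qb = sum(weights * S)^2)
}

.moment_p <- function(Q, Zw, null) {
  lam <- eigen(crossprod(Zw), symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-12 * max(lam)]
  .p_exact_mv(Q, lam, .perm_moments_quadform(Zw, null$n, null$n_case))
}

#' Rare-variant kernel association test for one gene
#'
#' The variance-component score test of joint association of all variants in
#' a gene. The `"moment"` method matches a chi-square-family shape (from the
#' kernel eigenvalues) to the exact finite-sample permutation mean and
#' variance of `Q`; the `"permutation"` method computes a seeded
#' case-relabelling p-value directly (used automatically when fewer than 3
#' positive eigenvalues make the analytic shape unreliable).
#'
#' @inheritParams kernel_statistic
#' @param method `"moment"` or `"permutation"`.
#' @param B Number of permutations for the permutation method.
#' @param adaptive Stop permuting once `min_exceed` exceedances are seen.
#' @param min_exceed Adaptive stopping threshold.
#' @param seed Integer seed for the permutation method.
#' @return A list with `p`, `Q`, `n_variants`, `method`.
#' @export
skat_test <- function(genotypes, null, weights = NULL,
                      method = c("moment", "permutation"),
                      B = 1e5, seed = 1L, adaptive = TRUE, min_exceed = 200L) {
  method <- match.arg(method)
  G <- .check_genotypes(genotypes)
  if (is.null(weights)) weights <- beta_maf_weights(.geno_maf(G))
  kp <- .kernel_parts(G, null, weights)
  if (method == "moment" && ncol(G) >= 3L) {
    p <- .moment_p(kp$Qs, kp$Zw, null)
  } else {
    method <- "permutation"
    p <- .perm_p_single(G, null, function(S) colSums((weights * S)^2), kp$Qs,
                        B = B, seed = seed, adaptive = adaptive,
                        min_exceed = min_exceed)
  }
  list(p = p, Q = kp$Qs, n_variants = ncol(G), method = method)
}

# adaptive seeded permutation p for a statistic computed from score sums
.perm_p_single <- function(G, null, stat_fun, Q_obs, B, seed, adaptive,
                           min_exceed) {
  set.seed(seed)
  done <- 0L; exceed <- 0L
  chunk <- 5000L
  while (done < B) {
    b <- as.integer(min(chunk, B - done))
    S <- .perm_scores(G, null$n_case, null$mu, b)
    exceed <- exceed + sum(stat_fun(S) >= Q_obs - 1e-12)
    done <- done + b
    if (adaptive && exceed >= min_exceed) break
  }
  (1 + exceed) / (done + 1)
}

#' Combined common-plus-rare kernel test
#'
#' Variants are partitioned at the rarity threshold; the kernel statistic is
#' computed on the rare partition with `beta(1, 25)` weights and on the
#' common partition with `beta(0.5, 0.5)` weights, and the two statistics are
#' combined as a weighted sum (`phi` on rare, `1 - phi` on common; the
#' default `phi = 0.5` is the equally weighted sum). The null distribution is
#' the quadratic form of the concatenated weighted kernel, so a gene with an
#' empty partition reduces exactly to the other partition's test.
#'
#' @inheritParams skat_test
#' @param maf_threshold Rare/common MAF boundary (rare inclusive).
#' @param phi Weight on the rare-partition statistic, in `[0, 1]`.
#' @param rare_shape,common_shape Beta weight shapes for the two partitions.
#' @return A list with `p`, `Q`, `n_variants`, `n_rare`, `n_common`,
#'   `method`.
#' @export
combined_test <- function(genotypes, null, maf_threshold = 0.010, phi = 0.5,
                          rare_shape = c(1, 25), common_shape = c(0.5, 0.5),
                          method = c("moment", "permutation"),
                          B = 1e5, seed = 1L, adaptive = TRUE,
                          min_exceed = 200L) {
  method <- match.arg(method)
  G <- .check_genotypes(genotypes)
  f <- .geno_maf(G)
  rare <- f <= maf_threshold
  w <- ifelse(rare,
              sqrt(2 * phi) * beta_maf_weights(f, rare_shape),
              sqrt(2 * (1 - phi)) * beta_maf_weights(f, common_shape))
  kp <- .kernel_parts(G, null, w)
  if (method == "moment" && ncol(G) >= 3L) {
    p <- .moment_p(kp$Qs, kp$Zw, null)
  } else {
    method <- "permutation"
    p <- .perm_p_single(G, null, function(S) colSums((w * S)^2), kp$Qs,
                        B = B, seed = seed, adaptive = adaptive,
                        min_exceed = min_exceed)
  }
  list(p = p, Q = kp$Qs, n_variants = ncol(G), n_rare = sum(rare),
       n_common = sum(!rare), method = method)
}

#' Optimal directional combination test (rho-grid)
#'
#' Evaluates `Q_rho = (1 - rho) * Q_kernel + rho * Q_burden` over a grid of
#' `rho` values, where `Q_burden` is the squared weighted-sum (burden) score
#' that is powerful when variants in a gene shift frequency in the same
#' direction. The reported p-value accounts for the minimisation over the
#' grid: the `"moment"` method uses the one-dimensional integral over the
#' common burden direction (each per-rho p-value from the exact-moment
#' recalibrated approximation), the `"permutation"` method a seeded min-p
#' permutation procedure. Genes with fewer than 3 positive kernel
#' eigenvalues, or an integration failure, fall back to permutation.
#'
#' @inheritParams skat_test
#' @param rho_grid Grid of combination weights in `[0, 1]`.
#' @return A list with `p`, `rho_optimal`, `p_rho` (per-grid-point
#'   p-values), `n_variants`, `method`.
#' @export
optimal_test <- function(genotypes, null,
                         rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                         weights = NULL, method = c("moment", "permutation"),
                         B = 1e5, seed = 1L) {
  method <- match.arg(method)
  G <- .check_genotypes(genotypes)
  if (is.null(weights)) weights <- beta_maf_weights(.geno_maf(G))
  m <- ncol(G)
  kp <- .kernel_parts(G, null, weights)

  if (m == 1L) {
    # degenerate grid: every rho gives the single-variant (burden) test
    p <- .moment_p(kp$Qs, kp$Zw, null)
    return(list(p = p, rho_optimal = 1, p_rho = rep(p, length(rho_grid)),
                n_variants = 1L, method = "moment"))
  }
  if (method == "moment" && m >= 3L) {
    out <- tryCatch(.skato_moment(kp, null, rho_grid),
                    error = function(e) NULL)
    if (!is.null(out)) return(c(out, list(n_variants = m, method = "moment")))
  }
  out <- .skato_permutation(G, null, weights, rho_grid, B = B, seed = seed)
  c(out, list(n_variants = m, method = "permutation"))
}

# analytic min-p combination: per-rho exact-moment p-values, minimisation
# corrected by integrating over the shared burden direction
.skato_moment <- function(kp, null, rho_grid) {
  Zw <- kp$Zw; m <- ncol(Zw)
  rho_c <- pmin(rho_grid, 0.999)          # rho = 1 handled as 0.999
  per <- lapply(rho_c, function(rho) {
    Zr <- Zw %*% .rho_sqrt(m, rho)
    lam <- eigen(crossprod(Zr), symmetric = TRUE, only.values = TRUE)$values
    lam <- lam[lam > 1e-12 * max(lam)]
    mv <- .perm_moments_quadform(Zr, null$n, null$n_case)
    Q <- (1 - rho) * kp$Qs + rho * kp$Qb
    list(lam = lam, mv = mv, p = .p_exact_mv(Q, lam, mv))
  })
  p_rho <- vapply(per, `[[`, numeric(1), "p")
  Tmin <- min(p_rho)
  qmin <- vapply(seq_along(per), function(i)
    .q_exact_mv(Tmin, per[[i]]$lam, per[[i]]$mv), numeric(1))

  # Gaussian-frame parameters of the kernel component orthogonal to the
  # burden direction (integration over the burden chi-square)
  Z1 <- sqrt(null$s2) * Zw
  zbar <- rowMeans(Z1)
  zb2 <- sum(zbar^2)
  cof <- drop(crossprod(zbar, Z1)) / zb2
  Zp <- outer(zbar, cof)                  # component along the burden direction
  Zi <- Z1 - Zp
  lam2 <- eigen(crossprod(Zi), symmetric = TRUE, only.values = TRUE)$values
  lam2 <- lam2[lam2 > 1e-12 * max(lam2)]
  MuQ <- sum(lam2)
  VarZeta <- 4 * sum(crossprod(Zp) * crossprod(Zi))
  VarQ <- 2 * sum(lam2^2) + VarZeta
  KerQ <- 12 * sum(lam2^4) / sum(lam2^2)^2
  Df <- 12 / KerQ
  tau <- vapply(rho_c, function(rho) (m^2 * rho + (1 - rho) * sum(cof^2)) * zb2,
                numeric(1))

  fint <- function(x) {
    vapply(x, function(xx) {
      tmp <- min((qmin - tau * xx) / (1 - rho_c))
      q <- (tmp - MuQ) / sqrt(VarQ) * sqrt(2 * Df) + Df
      stats::pchisq(q, df = Df) * stats::dchisq(xx, df = 1)
    }, numeric(1))
  }
  int <- stats::integrate(fint, 0, 40, subdivisions = 2000L, abs.tol = 1e-10)
  p <- 1 - int$value
  p <- min(p, Tmin * length(rho_grid))    # never worse than Bonferroni
  p <- min(1, max(p, Tmin, 1e-300))       # min-p is a lower bound
  list(p = p, rho_optimal = rho_grid[which.min(p_rho)], p_rho = p_rho)
}

# seeded min-p permutation: per-rho p-values are ranks within the joint
# permutation sample; the min over the grid is re-ranked the same way
.skato_permutation <- function(G, null, weights, rho_grid, B, seed) {
  set.seed(seed)
  S_obs <- drop(crossprod(G, null$resid))
  Qs_obs <- sum((weights * S_obs)^2); Qb_obs <- sum(weights * S_obs)^2
  S <- .perm_scores(G, null$n_case, null$mu, as.integer(B))
  WS <- weights * S
  Qs <- colSums(WS^2); Qb <- colSums(WS)^2
  nr <- length(rho_grid)
  p_rho_obs <- numeric(nr)
  Tb <- rep(Inf, B)
  for (i in seq_len(nr)) {
    rho <- rho_grid[i]
    q <- (1 - rho) * Qs + rho * Qb
    q_obs <- (1 - rho) * Qs_obs + rho * Qb_obs
    p_rho_obs[i] <- (1 + sum(q >= q_obs - 1e-12)) / (B + 1)
    # upper-tail rank of each permuted value within the permutation sample
    pb <- (B + 1 - rank(q, ties.method = "min")) / B
    Tb <- pmin(Tb, pb)
  }
  Tobs <- min(p_rho_obs)
  p <- (1 + sum(Tb <= Tobs)) / (B + 1)
  list(p = p, rho_optimal = rho_grid[which.min(p_rho_obs)], p_rho = p_rho_obs)
}

#' Reconstruct individual genotypes from pooled group allele counts
#'
#' When only pooled counts exist, gene-based tests run on a randomized
#' reconstruction: for each group, the observed minor-allele count is placed
#' on chromosomes drawn uniformly without replacement, and chromosomes are
#' paired into diploid individuals. This preserves group allele frequencies
#' exactly but randomizes carrier identity; results carry a
#' `"count_resampling"` mode flag and should be interpreted as the
#' documented approximation it is.
#'
#' @param variants An adjusted [variant_table()].
#' @param seed Integer seed.
#' @return Integer genotype matrix (cases first) with attributes `group` and
#'   `mode = "count_resampling"`.
#' @export
genotypes_from_counts <- function(variants, seed = 1L) {
  set.seed(seed)
  n_case <- (variants$min_case + variants$maj_case)[1] / 2
  n_ctrl <- (variants$min_ctrl + variants$maj_ctrl)[1] / 2
  V <- nrow(variants)
  g <- matrix(0L, n_case + n_ctrl, V)
  place <- function(count, n_ind) {
    gg <- integer(n_ind)
    if (count > 0) {
      chrom <- sample.int(2L * n_ind, count)
      tab <- tabulate((chrom - 1L) %/% 2L + 1L, nbins = n_ind)
      gg <- as.integer(tab)
    }
    gg
  }
  for (j in seq_len(V)) {
    g[, j] <- c(place(variants$min_case[j], n_case),
                place(variants$min_ctrl[j], n_ctrl))
  }
  colnames(g) <- variants$key
  attr(g, "group") <- rep(c("case", "control"), c(n_case, n_ctrl))
  attr(g, "mode") <- "count_resampling"
  g
}

#' Gene-based association scan
#'
#' Runs the three gene-level tests (rare-variant kernel, combined
#' common+rare, optimal directional combination) on every gene, under one or
#' both singleton policies. Under `"excluded"`, variants whose cohort
#' minor-allele count is exactly 1 are removed from the genotype matrix
#' before testing. Monomorphic variants are always excluded; a gene left
#' with no variants is reported as untestable rather than dropped silently.
#'
#' @param genotypes Individuals x variants minor-dosage matrix.
#' @param genes Character vector assigning each genotype column to a gene.
#' @param phenotype 0/1 vector, or an existing [null_model()].
#' @param policies Singleton policies to run (`"included"`, `"excluded"`).
#' @param maf_threshold Rare/common boundary for the combined test.
#' @param method p-value method passed to the tests.
#' @param alpha Nominal level flagging longevity-associated genes.
#' @param top_alpha Level flagging the top tier.
#' @param B,seed Permutation settings.
#' @return A data frame of class `gene_scan`: one row per gene per policy
#'   with `p_rare_kernel`, `p_combined`, `p_optimal`, `rho_optimal`,
#'   `n_variants_used`, `method`, `status`, `significant`, `top`.
#' @export
run_gene_scan <- function(genotypes, genes, phenotype,
                          policies = c("included", "excluded"),
                          maf_threshold = 0.010,
                          method = c("moment", "permutation"),
                          alpha = 0.05, top_alpha = 0.01,
                          B = 1e4, seed = 1L) {
  method <- match.arg(method)
  policies <- match.arg(policies, c("included", "excluded"), several.ok = TRUE)
  null <- if (inherits(phenotype, "lv_null")) phenotype else null_model(phenotype)
  if (length(genes) != ncol(genotypes))
    stop("gene annotation must be present for every variant column")
  n2 <- 2L * nrow(genotypes)
  minor_count <- pmin(colSums(genotypes), n2 - colSums(genotypes))
  rows <- list()
  for (policy in policies) {
    keep <- if (policy == "excluded") minor_count != 1L else rep(TRUE, length(genes))
    for (gene in unique(genes)) {
      cols <- which(genes == gene & keep & minor_count > 0L)
      if (!length(cols)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, singleton_policy = policy, n_variants_used = 0L,
          p_rare_kernel = NA_real_, p_combined = NA_real_,
          p_optimal = NA_real_, rho_optimal = NA_real_,
          method = NA_character_, status = "untestable",
          significant = FALSE, top = FALSE, stringsAsFactors = FALSE)
        next
      }
      G <- genotypes[, cols, drop = FALSE]
      s <- skat_test(G, null, method = method, B = B, seed = seed)
      co <- combined_test(G, null, maf_threshold = maf_threshold,
                          method = method, B = B, seed = seed + 1L)
      op <- optimal_test(G, null, method = method, B = B, seed = seed + 2L)
      pmin_all <- min(s$p, co$p, op$p)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, singleton_policy = policy,
        n_variants_used = s$n_variants,
        p_rare_kernel = s$p, p_combined = co$p,
        p_optimal = op$p, rho_optimal = op$rho_optimal,
        method = paste(unique(c(s$method, co$method, op$method)), collapse = "+"),
        status = "ok", significant = pmin_all <= alpha,
        top = pmin_all <= top_alpha, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(attr(genotypes, "mode")))
    attr(out, "mode") <- attr(genotypes, "mode")
  class(out) <- unique(c("gene_scan", class(out)))
  out
}

#' @export
print.gene_scan <- function(x, ...) {
  ok <- x$status == "ok"
  cat(sprintf("Gene-based scan: %d gene x policy rows (%d untestable)\n",
              nrow(x), sum(!ok)))
  if (!is.null(attr(x, "mode")))
    cat(sprintf("  genotype mode: %s (flagged approximation)\n", attr(x, "mode")))
  cat(sprintf("  significant in >=1 test: %d; top tier: %d\n",
              sum(x$significant), sum(x$top)))
  invisible(x)
}
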