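test_that("the intercept-only null model has its closed form", {
  y <- rep(c(1L, 0L), c(494, 572))
  nm <- null_model(y)
  expect_equal(nm$mu, 494 / 1066)
  expect_equal(sum(nm$resid), 0)
  expect_equal(unique(round(nm$resid[y == 1], 10)), round(1 - 494 / 1066, 10))
  expect_equal(unique(round(nm$resid[y == 0], 10)), round(-494 / 1066, 10))
  expect_equal(nm$v * nm$n, sum((y - nm$mu)^2) * nm$n / nm$n)  # n p(1-p)
  expect_error(null_model(rep(1L, 10)), "both phenotype classes")
})

test_that("the kernel statistic is a weighted squared score with its degeneracies", {
  y <- rep(c(1L, 0L), each = 30)
  nm <- null_model(y)
  expect_error(kernel_statistic(matrix(0L, 60, 3), nm), "untestable")
  G <- toy_genotypes(60, c(0.2, 0.1, 0.3), seed = 1)
  w <- c(1, 2, 0.5)
  S <- drop(crossprod(G, nm$resid))
  expect_equal(kernel_statistic(G, nm, w), sum((w * S)^2))
  expect_equal(kernel_statistic(G, nm, 2 * w), 4 * kernel_statistic(G, nm, w))
})

test_that("the quadratic-form tail is exact for one eigenvalue and errors on none", {
  expect_equal(pvalue_quadratic_form(7.3, 2.5),
               pchisq(7.3 / 2.5, df = 1, lower.tail = FALSE), tolerance = 1e-8)
  expect_equal(pvalue_quadratic_form(0, c(1, 2)), 1)
  expect_error(pvalue_quadratic_form(3, c(0, 0)), "eigenvalues")
})

test_that("a single variant reduces to the classical score test", {
  y <- rep(c(1L, 0L), c(40, 60))
  nm <- null_model(y)
  g <- toy_genotypes(100, 0.25, seed = 3)
  S <- sum(g * nm$resid)
  lam <- nm$s2 * sum((g - mean(g))^2)
  # op-level identity: one-eigenvalue moment matching IS the score chi-square
  expect_equal(pvalue_quadratic_form(S^2, lam),
               pchisq(S^2 / lam, df = 1, lower.tail = FALSE), tolerance = 1e-8)
  # test-level p (exact-moment recalibrated) stays within the finite-sample
  # skewness correction of the classical value
  ot <- optimal_test(matrix(g, ncol = 1), nm)
  expect_lt(abs(ot$p - pchisq(S^2 / lam, df = 1, lower.tail = FALSE)), 0.02)
  expect_equal(ot$rho_optimal, 1)
})

test_that("the exact permutation moments match exhaustive subset enumeration", {
  # the permutation null of Q is the distribution over all case subsets;
  # at n = 12, nc = 5 all 792 subsets can be enumerated exactly
  set.seed(4)
  for (trial in 1:3) {
    n <- 12L; nc <- 5L; m <- sample(2:4, 1)
    G <- matrix(rbinom(n * m, 2, runif(1, 0.2, 0.4)), n, m)
    if (any(apply(G, 2, var) == 0)) next
    Z <- scale(G, scale = FALSE)
    A <- tcrossprod(Z)
    subs <- utils::combn(n, nc)
    Q <- apply(subs, 2, function(S) {
      chi <- numeric(n); chi[S] <- 1
      drop(chi %*% A %*% chi)
    })
    mv <- longevar:::.perm_moments_quadform(Z, n, nc)
    expect_equal(mv[["mean"]], mean(Q), tolerance = 1e-10)
    expect_equal(mv[["var"]], mean((Q - mean(Q))^2), tolerance = 1e-10)
    expect_equal(mv[["mu3"]], mean((Q - mean(Q))^3), tolerance = 1e-8)
  }
})

test_that("moment and permutation p-values agree on small genes", {
  set.seed(11)
  y <- rep(c(1L, 0L), each = 50)
  nm <- null_model(y)
  for (rep_i in 1:3) {
    G <- toy_genotypes(100, runif(4, 0.1, 0.35), seed = 20 + rep_i)
    s_m <- skat_test(G, nm)$p
    s_p <- skat_test(G, nm, method = "permutation", B = 30000, seed = 1,
                     adaptive = FALSE)$p
    # analytic vs exact permutation: pointwise gaps of a few hundredths are
    # expected at n = 100 (documented); the oracle check below is exact
    expect_lt(abs(s_m - s_p), 0.1)
    orc <- oracle_perm_gene(G, y, B = 30000, seed = 99 + rep_i)
    expect_lt(abs(s_p - orc$p_skat), 3 * sqrt(orc$p_skat * (1 - orc$p_skat) *
                                                (2 / 30000)))
  }
})

test_that("the combined test reduces to its partitions and handles mixtures", {
  y <- rep(c(1L, 0L), each = 100)
  nm <- null_model(y)
  # only rare variants: identical to the rare kernel
  Gr <- toy_genotypes(200, c(0.006, 0.009, 0.008, 0.005), seed = 31)
  expect_equal(combined_test(Gr, nm)$p, skat_test(Gr, nm)$p, tolerance = 1e-10)
  # only common variants: the common-partition kernel with beta(0.5,0.5)
  Gc <- toy_genotypes(200, c(0.2, 0.3, 0.25), seed = 32)
  f <- pmin(colMeans(Gc) / 2, 1 - colMeans(Gc) / 2)
  wc <- beta_maf_weights(f, c(0.5, 0.5))
  expect_equal(combined_test(Gc, nm)$p,
               skat_test(Gc, nm, weights = wc)$p, tolerance = 1e-10)
  # mixed gene: agrees with the permutation oracle
  Gm <- cbind(toy_genotypes(200, c(0.008, 0.006), seed = 33),
              toy_genotypes(200, 0.25, seed = 34))
  cp <- combined_test(Gm, nm, method = "permutation", B = 30000, seed = 2)$p
  orc <- oracle_perm_gene(Gm, y, B = 30000, seed = 77)
  expect_lt(abs(cp - orc$p_comb),
            3 * sqrt(orc$p_comb * (1 - orc$p_comb) * (2 / 30000)))
})

test_that("the optimal test favours burden under directional signal", {
  # consistently case-enriched variants: the burden end of the grid wins
  set.seed(42)
  G <- matrix(0L, 200, 4)
  for (j in 1:4) {
    G[sample(100, 8), j] <- 1L          # 8 carriers among cases
    G[100 + sample(100, 2), j] <- 1L    # 2 among controls
  }
  nm <- null_model(rep(c(1L, 0L), each = 100))
  ot <- optimal_test(G, nm)
  expect_equal(ot$rho_optimal, 1)
  expect_lt(ot$p_rho[length(ot$p_rho)], ot$p_rho[1])   # burden beats kernel
  expect_true(ot$p > 0 && ot$p <= 1)
  # reproducible under fixed seed (permutation path)
  o1 <- optimal_test(G, nm, method = "permutation", B = 5000, seed = 3)
  o2 <- optimal_test(G, nm, method = "permutation", B = 5000, seed = 3)
  expect_identical(o1, o2)
})

test_that("the gene scan applies singleton policies and flags tiers", {
  d <- cohort_design(n_cases = 100, n_controls = 100, pool_size = 25, seed = 51)
  # one gene with a strong planted burden, one null gene
  sp <- rbind(
    simulate_variant_specs(8, frac_enriched = 1, maf_enriched_cases = 0.10,
                           maf_enriched_controls = 0.01, seed = 51),
    simulate_variant_specs(8, seed = 52))
  sp$gene <- rep(c("BURDEN", "NULLG"), each = 8)
  g <- simulate_genotypes(d, sp, seed = 53)
  y <- rep(c(1L, 0L), c(100, 100))
  scan <- run_gene_scan(g, sp$gene, y, seed = 54)
  expect_equal(nrow(scan), 4L)
  burden <- scan[scan$gene == "BURDEN", ]
  expect_true(all(burden$significant))
  # singleton exclusion removes count-1 variants before testing
  minor <- pmin(colSums(g), 2 * nrow(g) - colSums(g))
  n_singl <- sum(minor == 1 & minor > 0)
  incl <- scan$n_variants_used[scan$singleton_policy == "included"]
  excl <- scan$n_variants_used[scan$singleton_policy == "excluded"]
  expect_equal(sum(incl) - sum(excl), n_singl)
  # untestable gene is reported, not dropped
  g0 <- cbind(g, MONO = 0L)
  scan0 <- run_gene_scan(g0, c(sp$gene, "EMPTY"), y, policies = "included",
                         seed = 54)
  expect_true("untestable" %in% scan0$status[scan0$gene == "EMPTY"])
})

test_that("count-resampling genotypes preserve group allele counts exactly", {
  v <- toy_variants()
  g <- genotypes_from_counts(v, seed = 9)
  expect_equal(attr(g, "mode"), "count_resampling")
  grp <- attr(g, "group")
  expect_equal(unname(colSums(g[grp == "case", , drop = FALSE])), v$min_case)
  expect_equal(unname(colSums(g[grp == "control", , drop = FALSE])), v$min_ctrl)
  expect_true(all(g >= 0 & g <= 2))
})

test_that("null gene-scan significance rate is nominal", {
  # 200 null genes at alpha 0.05: expected ~10 significant per policy
  d <- cohort_design(n_cases = 150, n_controls = 150, pool_size = 25, seed = 61)
  sp <- simulate_variant_specs(1200, seed = 61,
                               maf_range = c(0.01, 0.4), ultra_weight = 0.3,
                               n_genes = 200)
  g <- simulate_genotypes(d, sp)
  y <- rep(c(1L, 0L), c(150, 150))
  scan <- run_gene_scan(g, sp$gene, y, policies = "included", seed = 62)
  ok <- scan$status == "ok"
  rate <- mean(scan$p_rare_kernel[ok] <= 0.05, na.rm = TRUE)
  expect_lt(rate, 0.10)   # calibrated, not wildly anticonservative
})
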