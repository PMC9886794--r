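test_that("design validation enforces the pooled layout invariants", {
  d <- cohort_design()
  expect_equal(d$n_pools, 43L)
  expect_equal(d$n_case_pools, 20L)
  expect_equal(d$n_ctrl_pools, 23L)
  expect_error(cohort_design(seq_error_rate = 0.2), "seq_error_rate")
  expect_error(cohort_design(n_pools = 10), "cover")
  expect_error(cohort_design(n_cases = 0), "positive")
  # per-sample coverage arithmetic
  expect_equal(d$median_pool_coverage / d$pool_size, 15.1248)
})

test_that("pool assignment is deterministic, homogeneous and under-full only at the tail", {
  d <- cohort_design()
  pa <- pool_assignment(d)
  expect_identical(pa, pool_assignment(d))
  mixed <- tapply(pa$group, pa$pool, function(g) length(unique(g)))
  expect_true(all(mixed == 1))
  sizes <- tabulate(pa$pool, d$n_pools)
  expect_true(all(sizes >= 1 & sizes <= d$pool_size))
  expect_equal(sum(sizes), d$n_cases + d$n_controls)
})

test_that("degenerate frequencies give all-zero genotypes and fixed seeds reproduce", {
  d <- cohort_design(n_cases = 20, n_controls = 30, pool_size = 10, seed = 5)
  sp <- data.frame(true_maf_cases = 0, true_maf_controls = 0)
  g <- simulate_genotypes(d, sp)
  expect_true(all(g == 0L))
  sp2 <- data.frame(true_maf_cases = c(0.1, 0.3), true_maf_controls = c(0.1, 0.3))
  expect_identical(simulate_genotypes(d, sp2), simulate_genotypes(d, sp2))
  expect_error(simulate_genotypes(d, data.frame(true_maf_cases = 0.7,
                                                true_maf_controls = 0.1)),
               "frequencies")
  expect_error(simulate_genotypes(d, sp[0, , drop = FALSE]), "non-empty")
})

test_that("empirical allele frequencies converge to the truth", {
  d <- cohort_design(seed = 21)
  sp <- data.frame(true_maf_cases = rep(0.02, 5000),
                   true_maf_controls = rep(0.02, 5000))
  g <- simulate_genotypes(d, sp)
  expect_lt(abs(mean(colMeans(g) / 2) - 0.02), 0.002)
})

test_that("pooled read sampling respects conservation and the error model", {
  d <- cohort_design(n_cases = 25, n_controls = 25, pool_size = 25,
                     seq_error_rate = 0, seed = 2)
  g <- matrix(0L, 50, 20)
  reads <- pool_and_sequence(g, d)
  expect_true(all(reads$alt == 0))                 # no alt chromosomes, no error
  expect_true(all(reads$alt <= reads$depth))
  # alt-chromosome fraction 0.5: mean alt reads ~ depth/2
  g2 <- matrix(1L, 50, 500)
  reads2 <- pool_and_sequence(g2, d)
  expect_lt(abs(mean(reads2$alt) - d$median_pool_coverage / 2), 3)
  # pure error floor on an all-reference pool
  d3 <- cohort_design(n_cases = 25, n_controls = 25, pool_size = 25,
                      seq_error_rate = 0.005, seed = 3)
  reads3 <- pool_and_sequence(matrix(0L, 50, 2000), d3)
  frac <- sum(reads3$alt) / sum(reads3$depth)
  expect_lt(abs(frac - 0.005), 3 * sqrt(0.005 / sum(reads3$depth)))
})

test_that("count estimation recovers noiseless pools exactly and flags drops", {
  d <- cohort_design(n_cases = 25, n_controls = 25, pool_size = 25,
                     seq_error_rate = 0)
  reads <- structure(list(
    alt = matrix(c(0L, 0L), 2, 1),
    depth = matrix(c(400L, 400L), 2, 1),
    pools = data.frame(pool = 1:2, group = c("case", "control"), n = c(25L, 25L)),
    design = d), class = "pooled_reads")
  est <- estimate_pooled_counts(reads)
  expect_equal(est$min_case, 0L)
  expect_equal(est$min_ctrl, 0L)
  expect_equal(est$drop_reason, "monomorphic")
  # one carrier chromosome among 25 diploid individuals, deep sequencing limit
  reads$alt <- matrix(c(8000L, 0L), 2, 1)          # fraction exactly 1/50
  reads$depth <- matrix(c(400000L, 400000L), 2, 1)
  est2 <- estimate_pooled_counts(reads)
  expect_equal(est2$min_case, 1L)
  expect_false(est2$dropped)
  # all pools at zero depth: dropped with a reason
  reads$depth <- matrix(c(0L, 0L), 2, 1)
  est3 <- estimate_pooled_counts(reads)
  expect_equal(est3$drop_reason, "no_coverage")
  expect_true(is.na(est3$min_case))
})

test_that("singleton recovery from pooled reads matches its simulation oracle", {
  # a cohort singleton at the study's coverage and a 0.001 miscall rate is
  # recovered as count 1 in roughly 82% of replicates (the information limit
  # of per-pool integer estimation at ~378x); far above chance, below 90%
  d <- cohort_design(seq_error_rate = 0.001, seed = 77)
  n_rep <- 300
  sp <- data.frame(true_maf_cases = numeric(0), true_maf_controls = numeric(0))
  set.seed(77)
  g <- matrix(0L, d$n_cases + d$n_controls, n_rep)
  carriers <- sample.int(d$n_cases + d$n_controls, n_rep, replace = TRUE)
  g[cbind(carriers, seq_len(n_rep))] <- 1L
  reads <- pool_and_sequence(g, d, seed = 78)
  est <- estimate_pooled_counts(reads)
  rate <- mean(est$min_case + est$min_ctrl == 1)
  expect_gt(rate, 0.75)
  expect_lt(rate, 0.92)
})

test_that("estimated counts are conserved and bounded", {
  d <- cohort_design(n_cases = 50, n_controls = 60, pool_size = 25, seed = 9)
  sp <- simulate_variant_specs(200, seed = 9)
  g <- simulate_genotypes(d, sp)
  reads <- pool_and_sequence(g, d)
  expect_true(all(reads$alt <= reads$depth))
  est <- estimate_pooled_counts(reads)
  ok <- !est$dropped
  expect_true(all(est$min_case[ok] >= 0 & est$min_case[ok] <= 2 * d$n_cases))
  expect_true(all(est$min_ctrl[ok] >= 0 & est$min_ctrl[ok] <= 2 * d$n_controls))
})

test_that("simulated cohorts are reproducible bit for bit under a fixed seed", {
  d <- cohort_design(n_cases = 40, n_controls = 50, pool_size = 25, seed = 123)
  sp <- simulate_variant_specs(100, seed = 123)
  s1 <- simulate_cohort(d, sp)
  s2 <- simulate_cohort(d, sp)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$genotypes, s2$genotypes)
})

test_that("a simulated cohort round-trips through its on-disk form", {
  d <- cohort_design(n_cases = 40, n_controls = 50, pool_size = 25, seed = 321)
  sim <- simulate_cohort(d, simulate_variant_specs(60, seed = 321))
  out <- write_cohort(sim, tempfile())
  r <- read_variants(out[["vcf"]], out[["ann"]])
  expect_equal(r$min_case, sim$variants$min_case)
  expect_equal(r$min_ctrl, sim$variants$min_ctrl)
  expect_equal(r$cadd_phred, sim$variants$cadd_phred)
  truth <- jsonlite::read_json(out[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$design$n_cases, 40L)
  expect_equal(length(truth$truth$key), 60L)
})

test_that("the detected panel reproduces deep-candidate-sequencing features", {
  d <- cohort_design(seed = 31)
  sp <- simulate_variant_specs(3000, seed = 31)
  sim <- simulate_cohort(d, sp)
  a <- associate(sim$variants)
  # roughly half of detected variants are singletons
  expect_gt(mean(a$singleton), 0.35)
  expect_lt(mean(a$singleton), 0.60)
  # nonsynonymous dominate the coding fraction (~2/3)
  cd <- a$consequence[a$consequence %in% c("nonsynonymous", "synonymous",
                                           "stop_gain", "frameshift",
                                           "inframe_indel")]
  expect_gt(mean(cd == "nonsynonymous"), 0.55)
  expect_lt(mean(cd == "nonsynonymous"), 0.80)
})

test_that("null Fisher p-values are close to nominal through both count paths", {
  # on true diploid counts the discrete Fisher test is conservative
  # (type I below nominal); the pooled read path adds sampling noise that
  # inflates it slightly above nominal at the study's ~378x coverage
  d <- cohort_design(seed = 404)
  sp <- simulate_variant_specs(4000, ultra_weight = 0,
                               maf_range = c(0.05, 0.45), seed = 404)
  sim <- simulate_cohort(d, sp)
  g <- sim$genotypes
  grp <- attr(g, "group")
  true_case <- colSums(g[grp == "case", , drop = FALSE])
  true_ctrl <- colSums(g[grp == "control", , drop = FALSE])
  p_true <- fisher_exact_two_sided(true_case, 2 * d$n_cases - true_case,
                                   true_ctrl, 2 * d$n_controls - true_ctrl)
  expect_lte(mean(p_true <= 0.05), 0.06)
  a <- associate(sim$variants)
  expect_lte(mean(a$p_value <= 0.05), 0.08)
})

test_that("planted case-enrichment is detected in a majority of replicates", {
  d <- cohort_design(seed = 55)
  sp <- simulate_variant_specs(60, frac_enriched = 1, seed = 55)
  sim <- simulate_cohort(d, sp)
  a <- associate(sim$variants)
  hit <- a$p_value <= 0.05 & a$enriched
  expect_gt(mean(hit), 0.5)
})
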