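make_prio_fixture <- function() {
  df <- data.frame(
    chrom = "chr1", pos = 1:6 * 10L, ref = "A", alt = "G",
    gene = c("GA", "GA", "GB", "GC", "GC", "GD"),
    consequence = c("nonsynonymous", "nonsynonymous", "intronic",
                    "nonsynonymous", "synonymous", "utr3"),
    min_case = c(8L, 9L, 12L, 10L, 9L, 11L),
    min_ctrl = c(1L, 1L, 2L, 1L, 1L, 30L),
    aa_ref = c("K", "D", NA, "R", NA, NA),
    aa_pos = c(5L, 6L, NA, 7L, NA, NA),
    aa_alt = c("E", "G", NA, "W", NA, NA),
    cadd_phred = c(24, 28, NA, NA, 16, 3),
    condel_label = c(NA, "deleterious", NA, NA, NA, NA),
    regulome_rank = c(NA, NA, 2L, NA, NA, 6L),
    maf_gnomad = c(NA, 0.002, 0.05, NA, 0.004, 0.2),
    vert_conserved = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    invert_conserved = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    evidence_notes = c(1L, 2L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
  df$maj_case <- 1000L - df$min_case
  df$maj_ctrl <- 1200L - df$min_ctrl
  classify_table(variant_table(df))
}

test_that("criterion 1 is a hard gate and every state is recorded", {
  v <- make_prio_fixture()
  a <- associate(v)
  pr <- apply_criteria(a, v)
  # the utr3 variant is depleted-ish and common in controls; the gate is on p
  expect_true(all(pr$p_value <= 0.05))
  expect_true(all(a$key[a$p_value <= 0.05] %in% pr$key))
  expect_false(any(a$key[a$p_value > 0.05] %in% pr$key))
  expect_true(all(c("c1_assoc", "c2_enriched", "c3_location_tier",
                    "c4_impact", "c5_external", "c6_evidence") %in% colnames(pr)))
})

test_that("criterion evaluation follows the stated rules on a constructed fixture", {
  v <- make_prio_fixture()
  a <- associate(v)
  pr <- apply_criteria(a, v)
  r <- pr[match(v$key, pr$key), ]
  # variant 1: nsV, K->E radical, CADD 24, no external record anywhere -> c4/c5 pass
  expect_equal(r$c4_impact[1], "pass")
  expect_equal(r$c5_external[1], "pass")
  # variant 2: deleterious Condel, gnomAD 0.002 <= 0.010 -> pass/pass, evidence 3
  expect_equal(r$c4_impact[2], "pass")
  expect_equal(r$c5_external[2], "pass")
  expect_equal(r$c6_evidence[2], 3L)
  # variant 3: ncV with Regulome rank 2 -> impact pass; external 0.05 -> c5 fail
  expect_equal(r$c3_location_tier[3], "ncV")
  expect_equal(r$c4_impact[3], "pass")
  expect_equal(r$c5_external[3], "fail")
  # variant 4: nsV with NO impact prediction -> unknown, still emitted
  expect_equal(r$c4_impact[4], "unknown")
  # variant 5: synonymous -> other_coding tier, CADD 16 >= 15 -> pass
  expect_equal(r$c3_location_tier[5], "other_coding")
  expect_equal(r$c4_impact[5], "pass")
})

test_that("ranking is the stated lexicographic order with deterministic tiebreaks", {
  v <- make_prio_fixture()
  a <- associate(v)
  pr <- rank_priorities(apply_criteria(a, v))
  # enriched nsVs with c4 pass come first; c6 breaks ties among them
  expect_equal(pr$c2_enriched[1], "pass")
  expect_equal(pr$c3_location_tier[1], "nsV")
  # higher evidence outranks lower at equal prefix
  first_two <- pr[pr$c4_impact == "pass" & pr$c3_location_tier == "nsV", ]
  expect_true(all(diff(first_two$c6_evidence) <= 0))
  # unknown c4 ranks below pass within nsV
  i_pass <- which(pr$c3_location_tier == "nsV" & pr$c4_impact == "pass")
  i_unk <- which(pr$c3_location_tier == "nsV" & pr$c4_impact == "unknown")
  expect_true(max(i_pass) < min(i_unk))
  # an enriched ncV outranks any depleted nsV (c2 dominates c3)
  df <- pr[0, ]
  x <- pr[rep(1, 2), ]
  x$c2_enriched <- c("pass", "fail")
  x$c3_location_tier <- c("ncV", "nsV")
  x$key <- c("a", "b")
  expect_equal(rank_priorities(x)$key, c("a", "b"))
  # complete tie -> genomic coordinate
  y <- pr[rep(1, 2), ]
  y$key <- c("k1", "k2"); y$chrom <- "chr1"; y$pos <- c(500L, 40L)
  expect_equal(rank_priorities(y)$pos, c(40L, 500L))
})

test_that("ranking is invariant to input permutation", {
  v <- make_prio_fixture()
  a <- associate(v)
  pr <- apply_criteria(a, v)
  set.seed(8)
  perm <- pr[sample(nrow(pr)), ]
  expect_equal(rank_priorities(pr)$key, rank_priorities(perm)$key)
})

test_that("tightening thresholds never grows the impact-pass set", {
  v <- make_prio_fixture()
  a <- associate(v)
  loose <- apply_criteria(a, v, prioritize_config(cadd_min = 15))
  tight <- apply_criteria(a, v, prioritize_config(cadd_min = 25))
  expect_true(all(tight$key[tight$c4_impact == "pass"] %in%
                  loose$key[loose$c4_impact == "pass"]))
  expect_error(prioritize_config(regulome_max = 9), "regulome")
  expect_error(prioritize_config(alpha = 0), "alpha")
})

test_that("hotspot genes require the nonsynonymous minimum", {
  v <- make_prio_fixture()
  a <- associate(v)
  pr <- rank_priorities(apply_criteria(a, v))
  h <- hotspot_genes(pr, min_nsv = 2)
  expect_true("GA" %in% h$gene)          # two prioritized nsVs
  expect_false("GC" %in% h$gene)         # two prioritized variants, one nsV
  expect_equal(nrow(hotspot_genes(pr[0, ])), 0L)
})

test_that("LAV summary counts are recomputed from the records", {
  v <- make_prio_fixture()
  a <- associate(v)
  pr <- rank_priorities(apply_criteria(a, v))
  s <- lav_summary(pr)
  expect_equal(s$n_prioritized, nrow(pr))
  expect_equal(s$n_nsv, sum(pr$c3_location_tier == "nsV"))
  expect_equal(s$enriched_share_percent, 100 * mean(pr$c2_enriched == "pass"))
  expect_equal(s$n_vert_conserved, sum(pr$vert_conserved))
})
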