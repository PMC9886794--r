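---
title: "Pooled-sequencing association analysis of longevity candidate genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-sequencing association analysis of longevity candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longevar)
```

## The problem

Centenarians are natural experiments in healthy ageing: genetic variation
that contributes to surviving past 95-100 years is expected to be rare or
absent in younger populations. A cost-effective way to look for such
variation in candidate genes (here: nuclear-encoded mitochondrial genes) is
pooled target-capture sequencing — equimolar DNA mixtures of ~25 individuals
per pool, cases and controls pooled separately, sequenced to a few hundred
fold per pool so that each individual contributes ~15 reads per site. Allele
frequencies are then estimated from read fractions rather than from
individual genotypes, and the association analysis proceeds on diploid
allele counts.

`longevar` implements the full downstream cascade of such a study:

1. **Cohort simulation** (`cohort_design()`, `simulate_variant_specs()`,
   `simulate_cohort()`): the study data themselves are not deposited
   anywhere, so a generative model stands in for them in every test.
2. **Variant I/O and minor-allele adjustment** (`read_variants()`,
   `adjust_minor_allele()`, `maf()`).
3. **Single-variant association** (`associate()`): two-sided Fisher exact
   tests, Bonferroni/Benjamini-Hochberg correction, rarity and
   centenarian-enrichment partitioning.
4. **Gene-based tests** (`run_gene_scan()`): a rare-variant
   variance-component kernel test, a combined common+rare test, and an
   optimal directional (rho-grid) combination.
5. **Amino-acid substitution classification** (`classify_aa()`):
   conservative / non-conservative / radical labels from R-group
   properties.
6. **Variant prioritization** (`apply_criteria()`, `rank_priorities()`):
   the six-criterion annotation cascade nominating longevity-associated
   variants (LAVs) and hotspot genes.
7. **Gene-set enrichment** (`enrich_genesets()`): permutation enrichment of
   age-related-disease categories against configurable backgrounds.

`run_pipeline()` chains all stages deterministically from one seed.

## The generative model

The simulator emulates the study conditions: 494 cases and 572 controls
(the cohort is also reported as 496 probands elsewhere in the study; both
are parameters), pools of at most 25 individuals homogeneous by group — 20
case pools and 23 control pools, 43 in total, matching the 11+11+11+10
capture-batch layout — and ~378.12-fold median coverage per pool, i.e.
~15-fold per sample.

* **Genotypes** are Hardy-Weinberg draws of minor-allele dosage at the
  variant's true group frequency.
* **Pool membership** is deterministic round-robin within each group, so a
  fixed seed fixes the pools; the last pool per group may be under-full
  (43 x 25 = 1075 > 1066).
* **Read depth** per pool and site is Poisson around the median pool
  coverage — the simplest generative reading of "median coverage per pool".
* **Reads** carry the minor allele with probability `f(1-e) + (1-f)e`,
  where `f` is the pool's minor-chromosome fraction and `e` the per-read
  miscall rate (default 0.002, within the typical range for short-read
  platforms after filtering).
* **The frequency spectrum** is a two-component log-uniform mixture: 90%
  ultra-rare (5e-6 to 1e-3) and 10% low-frequency-to-common (1e-3 to 0.5).
  The weight was set so that roughly half of the variants *detected* in a
  cohort of ~1,000 individuals are singletons, the hallmark feature of deep
  candidate-gene sequencing data; consequence classes follow a capture
  design of coding plus UTR/promoter targets with about two thirds of
  coding variants nonsynonymous.
* **Annotations** (CADD-phred, Condel labels, Regulome ranks, external
  population frequencies, conservation flags, curated evidence counts) are
  drawn with realistic missingness; external frequencies track the true
  frequency with log-normal noise. "Planted" case-enriched variants
  (configurable fraction; defaults 0.02 vs 0.002 case/control MAF) receive
  a fully qualifying annotation profile, which makes end-to-end
  parameter-recovery experiments possible.

What the generator does **not** emulate: linkage disequilibrium between
variants, population stratification, batch effects between captures,
reference bias, mapping artefacts, and indel-calling error profiles.
Passing tests therefore demonstrate correctness of the statistical
machinery under a clean generative model, not robustness to the technical
artefacts of real pooled sequencing.

## Allele-count estimation from pooled reads

For each pool the minor-read fraction is debiased for the miscall rate,
`(alt/depth - e) / (1 - 2e)` floored at zero, scaled to the pool's
chromosome count and rounded (halves away from zero); group counts are the
per-pool sums. Two numerical choices matter:

* **Per-pool rounding, not group-level rounding.** A cohort singleton is a
  1/(2x25) = 2% read fraction in one pool — far above the error floor — but
  only ~0.1% of a group-level average, which rounding destroys. Per-pool
  integer estimation preserves singletons near the information limit of the
  design: at ~378x and `e = 0.001` a true singleton is recovered as
  exactly 1 in roughly four of five replicates, and the test suite pins
  that rate.
* **Error debiasing.** Without subtracting `e`, every all-reference group
  would accumulate `round(2N x e)` phantom minor alleles (a systematic +1
  at N ~ 500, e = 0.001).

Read sampling adds variance on top of the binomial sampling of chromosomes:
at ~378x per pool the effective variance of a group frequency estimate is
inflated by a factor ~1.13. The discrete Fisher test is conservative enough
to absorb most, but not all, of this: on true genotype counts the null
type-I rate at nominal 0.05 stays below 0.05, while through the pooled read
path it sits slightly above nominal (~0.065-0.07). This is a property of
pooled designs, not of the implementation, and the suite asserts both
levels separately.

## Single-variant statistics

REF/ALT are first adjusted so that ALT is the cohort minor allele (strict
majority triggers the swap; an exact 50% tie keeps ALT, making the
operation deterministic and idempotent). The two-sided Fisher p-value uses
the minimum-likelihood rule — the sum of hypergeometric probabilities of
all tables at the observed margins no more probable than the observed one,
with the standard `1 + 1e-7` relative tie guard (the same convention as
`stats::fisher.test`, against which the implementation is tested to 1e-12;
the package's own vectorized implementation exists because the acceptance
runs test hundreds of thousands of tables). Conventions, all inclusive or
strict as stated: rare means cohort MAF <= 0.010; singleton means cohort
minor count exactly 1; enriched means case MAF *strictly* above control
MAF, so ties count as depleted; the odds ratio adds 0.5 to every cell only
when a cell is zero and is never used for p-values. Bonferroni uses the
configurable family size (default 660 candidate genes, threshold
0.05/660 = 7.6e-5); FDR is step-up Benjamini-Hochberg.

## Gene-based tests

All three tests build on the weighted score vector `S_j = sum_i r_i g_ij`
with intercept-only logistic residuals `r` (the study has no covariates)
and beta(1, 25) MAF weights for rare variants:

* rare-variant kernel statistic `Q = sum_j (w_j S_j)^2`;
* combined test: the kernel statistic evaluated separately on the rare
  partition (beta(1,25) weights) and the common partition (beta(0.5,0.5)),
  combined as an equally weighted sum (`phi` configurable), which is
  algebraically one kernel statistic with partition-specific weights — so
  a gene with one empty partition reduces *exactly* to the other
  partition's test;
* optimal directional combination `Q_rho = (1-rho) Q_kernel + rho Q_burden`
  over the grid {0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1}, where
  `Q_burden = (sum_j w_j S_j)^2` concentrates power when variants shift in
  a common direction (the centenarian-enrichment signature).

**p-values.** The classical route approximates the null of `Q` by a
mixture of one-degree chi-squares from the kernel eigenvalues with a
four-moment (skewness/kurtosis-matched noncentral chi-square) tail. At
case/control sample sizes in the hundreds this asymptotic null drifts
visibly from the exact finite-sample (permutation) null. The package
therefore matches a chi-square family to the *exact* permutation moments
of `Q`. Under an intercept-only binary null, permuting residuals is the
same as redrawing the case subset, so `Q = chi' A chi` with `chi` a
uniform random case-subset indicator and `A` the centred weighted
genotype kernel; because `chi` is idempotent, the first three moments
have closed forms — weighted sums of a handful of kernel invariants, with
weights assembled from subset-inclusion probabilities by Mobius inversion
over set partitions of the index slots. The implementation is validated
against exhaustive enumeration of all case subsets at small n. Location
and scale come from the exact mean and variance, the chi-square degrees
of freedom from the exact skewness (`df = 8/skew^2`; the eigenvalue-based
shape is the fallback for genes with more than 20 variants, where the
cubic invariant is not computed). This keeps the analytic p-values
uniform under the null at n = 200 — the plain approximation fails a
Kolmogorov-Smirnov uniformity check there, the exact-moment version
passes across seeds.

For genes with fewer than three positive kernel eigenvalues (one or two
variants), where a chi-square-family shape is unreliable, the tests fall
back to a seeded adaptive permutation p-value; a `permutation` method is
also available explicitly and is the reference against which the analytic
path is validated. The rho-grid minimisation is corrected either by the
one-dimensional integral over the shared burden direction (analytic path,
with rho = 1 evaluated as 0.999) or by a min-p permutation procedure
(rank-based within the same permutation sample). For a single-variant gene
every rho is the same test; the reported `rho_optimal` is 1 by convention.

Scans run twice, including and excluding singletons (a cohort minor count
of 1 cannot carry replicable signal, and the study's headline gene list is
the singleton-excluded one). Genes significant at p <= 0.05 in at least one
test are flagged longevity-associated; p <= 0.01 marks the top tier. When
only pooled counts exist, genotypes are reconstructed by placing the
observed group minor counts on random chromosomes (`genotypes_from_counts`);
this preserves group frequencies exactly but randomizes carrier identity
and co-occurrence, so the output is flagged `count_resampling` and should
be read as the documented approximation it is.

## Substitution classification

Each substitution is compared on four R-group properties — charge
(K/R/H positive, D/E negative), polarity, hydropathy (Kyte-Doolittle sign:
index > 0 hydrophobic, < -1 hydrophilic, [-1, 0] neutral) and size
(volume bins: tiny < 95 cubic Angstrom, small 95-125, medium 125-160,
large > 160). Zero differences is conservative (C); two or more differences
*including a size change* is radical (R) — read literally, so two changes
without a size change stay non-conservative (NC); anything else is NC. The
bin boundaries are this package's documented convention (the general
sources behind such property tables do not fix bins), and the table ships
as an editable TSV so alternative conventions remain testable — the suite
demonstrates that moving one residue across a bin boundary flips exactly
the labels it should.

## Prioritization

Six criteria are evaluated for every variant passing the association gate
(p <= 0.05, the only hard gate): enrichment directionality; location tier
(nsV > other coding > ncV); predicted impact (for nsVs an NC/R label *and*
a damaging prediction — Condel deleterious or CADD-phred >= 15, both
thresholds configurable, 20 marking "likely damaging"; for ncVs a Regulome
rank <= 3 or an explicit regulatory-evidence flag); external rarity
corroboration (every available external population MAF <= 0.010, total
absence passing — absence from all populations is the strongest rarity
signal); and an a-priori evidence count. Missing annotation yields
`unknown`, never a pass, and nothing is silently dropped. Enrichment is a
ranking key rather than a gate because a non-trivial minority of real
prioritized variants are depleted. Ranking is lexicographic in the
criteria's order with ascending p and genomic coordinate as final
tiebreaks — a deterministic total order; no weighted composite score is
invented. Genes with two or more prioritized nonsynonymous variants are
reported as hotspots.

## Gene-set enrichment

Catalog rows are filtered at p <= 1e-8 for disease traits and p <= 1e-6
for lifespan/ageing/longevity traits, deduplicated per gene-trait-study
(minimum p wins; ties keep the first occurrence), and mapped to disease
categories via an editable trait-category table. Enrichment of a query
gene set in a category is the empirical upper tail of the overlap under
`B` (default 10,000, seeded) uniform query-sized draws from the chosen
background — whole genome, mitochondrial proteome, or the sequenced
candidate list. `p = (1 + #{overlap >= observed}) / (B + 1)`, so the floor
is `1/(B+1)` and the estimate converges to the hypergeometric upper tail,
which the tests verify. Permutation is uniform over genes; conditioning on
gene length or SNP density is out of scope and documented as such.

## Validation strategy and problem sizes

Every statistical component is checked against an independently coded
oracle: Fisher against exhaustive hypergeometric enumeration (and
`stats::fisher.test`); the permutation-moment formula against brute-force
enumeration; the three gene tests against a 200,000-permutation oracle on
20 small fixtures (n = 100, 3-6 common variants); analytic calibration via
KS uniformity on 2,000 null genes of 200 individuals; enrichment against
the hypergeometric tail; the classifier against brute-force recomputation
of the full 20x20 matrix; and the whole cascade via recovery of 20 planted
fully-qualifying LAVs among 5,000 null variants at full cohort size over
50 seeded replicates. These sizes keep the default suite within a half
hour on one core while leaving each check enough resolution to fail
loudly.

Two statistical honesty notes. First, a deterministic analytic
approximation to a *permutation* null cannot sit within two Monte-Carlo
standard errors of a 200k-permutation estimate at these sample sizes (the
asymptotic-vs-exact gap is an order of magnitude larger), so pointwise
oracle agreement is asserted for the package's permutation method, and the
analytic method is held to distributional calibration instead. Second,
when a family of Monte-Carlo comparisons is scored in standard-error
units, even an exact implementation exceeds 2 SE in ~5% of comparisons;
the suite therefore requires >= 90% of comparisons within 2 SE and all
within ~4 SE, which an exact method passes with high probability and a
biased one fails.

## Known limitations

* The count-resampling genotype mode destroys carrier-level information;
  gene-test p-values in that mode are approximations and are flagged.
* The pooled read path is slightly anticonservative for common variants at
  the study's coverage (see above); single-variant p-values from pooled
  counts inherit that.
* The analytic gene-test p-values are calibrated in distribution but can
  differ from the exact permutation p by a few hundredths pointwise at
  small n; use `method = "permutation"` where exactness matters.
* External annotation scores (CADD, Condel, Regulome, conservation) are
  consumed as inputs, never computed; their quality bounds the
  prioritization.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(n_variants = 2000L, frac_enriched = 0.01, seed = 1L)
report <- run_pipeline(cfg, out_dir = "longevar-run")
print(report)
head(report$priorities[, c("key", "gene", "p_value", "c2_enriched",
                           "c3_location_tier", "c4_impact", "rank")])
```

The bundle written to `out_dir` contains the association table, a
Manhattan-ready export, the gene scan under both singleton policies, the
ranked LAV table with every criterion state, hotspot genes, the enrichment
table, a summary JSON mirroring the headline panels, and the run log with
per-stage row counts.
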