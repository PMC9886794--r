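# longevar

Association analysis of pooled target-capture sequencing for human
longevity candidate-gene studies.

## The problem

Exceptional human longevity (surviving past ~95–100 years) has a strong
genetic component, and the variants involved are expected to be rare or
absent in younger controls. A cost-effective discovery design sequences
candidate genes — here, nuclear-encoded mitochondrial ("mitonuclear")
genes — in *pools*: equimolar DNA mixtures of up to 25 individuals, cases
(centenarians/probands) and controls pooled separately, ~43 pools at
~378-fold coverage per pool (~15-fold per sample). Allele frequencies are
estimated from read fractions, and every downstream statistic runs on
diploid allele counts.

`longevar` implements that downstream cascade end to end, for
statisticians and genetic epidemiologists who want a tested, reproducible
reference implementation:

* **Synthetic cohort generator** — Hardy–Weinberg genotypes for 494 cases
  vs 572 controls (configurable), deterministic group-homogeneous pooling,
  Poisson depth and binomial read sampling with a per-read miscall rate,
  a frequency spectrum in which roughly half the detected variants are
  singletons, and annotation columns with realistic missingness. The study
  data are not publicly deposited, so the generator is a first-class,
  tested module, not a fixture.
* **Allele-count estimation** — per-pool error-debiased read fractions,
  rounded per pool (which preserves singletons near the design's
  information limit) and summed per group.
* **Single-variant association** — two-sided Fisher exact test
  (minimum-likelihood rule), odds ratios with continuity correction,
  Bonferroni (default family: 660 gene tests, threshold
  0.05/660 ≈ 7.6×10⁻⁵) and Benjamini–Hochberg adjustment, and the
  rare/common (cohort MAF ≤ 0.010), singleton, and centenarian-enriched
  (MAF_cases > MAF_controls, ties depleted) partitions.
* **Gene-based tests** — the variance-component kernel statistic
  Q = Σⱼ wⱼ²(Σᵢ rᵢ gᵢⱼ)² with beta(1,25) MAF weights; a combined
  common+rare test (beta(0.5,0.5) on the common partition); and the
  optimal directional combination Q_ρ = (1−ρ)Q_kernel + ρQ_burden over
  ρ ∈ {0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1}. p-values come from a
  chi-square-family approximation matched to the **exact finite-sample
  permutation moments** of Q (mean, variance, and third moment in closed
  form), or from a seeded permutation method; scans run with and without
  singletons.
* **Amino-acid substitution classifier** — conservative (C) /
  non-conservative (NC) / radical (R) labels from R-group charge,
  polarity, hydropathy and size (R = ≥2 property changes including size).
* **Six-criterion prioritizer** — association gate (p ≤ 0.05), enrichment
  directionality, location tier (nsV > other coding > ncV), predicted
  impact (NC/R + Condel/CADD for coding; Regulome for non-coding),
  external-population rarity corroboration, and a-priori evidence count;
  deterministic lexicographic ranking and hotspot-gene detection.
* **Gene-set enrichment** — seeded permutation enrichment of age-related
  disease categories against configurable backgrounds (whole genome,
  mitochondrial proteome, candidate list), converging to the
  hypergeometric tail.

## A worked example

```r
library(longevar)
cfg <- run_config(n_variants = 2000L, frac_enriched = 0.01, seed = 1L)
report <- run_pipeline(cfg, out_dir = "longevar-run")
```

The run logs every stage's row counts:

```
simulate: 2000 variants drawn, 714 retained, 1286 dropped (monomorphic 1286)
adjust: 714 records, 1 minor-allele swaps
associate: 714 tests, 37 at p <= 0.05
genescan: 200 gene x policy rows, 54 significant, 42 top, 1 untestable
classify: 182 substitution labels
prioritize: 37 LAVs, 3 hotspot genes
enrich: 6 categories against 100 background genes (27 query genes)
```

Of the 2000 simulated variants, 714 are detected at the pooled coverage
(the rest are too rare to appear in ~1000 individuals — the generator's
spectrum makes roughly half of the detected panel singletons). 37 variants
pass the nominal single-variant gate and survive as ranked
longevity-associated variants (LAVs); the ~20 planted case-enriched
variants (1% of 2000, most of them detected) dominate the top ranks:

```r
head(report$priorities[, c("key", "gene", "p_value", "c2_enriched",
                           "c3_location_tier", "c4_impact", "rank")], 5)
#>                key     gene      p_value c2_enriched c3_location_tier c4_impact rank
#> 1  chr22:74326:C:T GENE0024 1.029550e-05        pass              nsV      pass    1
#> 2  chr1:141087:G:A GENE0059 2.092441e-06        pass              nsV      pass    2
#> 3 chr13:133411:G:A GENE0061 8.249798e-06        pass              nsV      pass    3
#> 4   chr5:83719:G:A GENE0090 1.640056e-05        pass              nsV      pass    4
#> 5 chr13:113413:A:G GENE0058 5.293959e-03        pass              nsV      pass    5
```

All five are enriched in centenarians (`c2`), nonsynonymous (`c3`) with a
damaging-and-non-conservative impact profile (`c4`); ranking is
lexicographic in the six criteria with p-value and genomic position as
tiebreaks. The enrichment table reports the empirical permutation p of
each disease category's overlap with the significant-gene set against the
candidate-list background (here a null synthetic catalog, so no category
is significant):

```r
report$enrichment[report$enrichment$category == "metabolic", ]
#>    category observed expected p_empirical n_permutations     background
#>   metabolic        7    5.955   0.3751625          10000 candidate_list
```

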