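# Independent oracles and fixture builders used across the suite.
# Each oracle is written directly from first principles, separately from the
# package code paths it checks.

# two-sided Fisher p by explicit enumeration of all tables at the observed
# margins, probabilities from log-binomial coefficients
oracle_fisher <- function(a, b, cc, d) {
  r1 <- a + b; k <- a + cc; N <- a + b + cc + d
  lo <- max(0, k - (N - r1)); hi <- min(k, r1)
  lp <- lchoose(r1, lo:hi) + lchoose(N - r1, k - (lo:hi)) - lchoose(N, k)
  pr <- exp(lp)
  sum(pr[pr <= pr[a - lo + 1] * (1 + 1e-7)])
}

# brute-force C/NC/R label straight from a property table row pair
oracle_aa_label <- function(ref, alt, tab) {
  i <- tab[tab$residue == ref, ]; j <- tab[tab$residue == alt, ]
  d <- c(i$charge != j$charge, i$polarity != j$polarity,
         i$hydropathy != j$hydropathy, i$size_class != j$size_class)
  nd <- sum(d)
  if (nd == 0) "C" else if (nd >= 2 && d[4]) "R" else "NC"
}

# hypergeometric upper-tail probability of a set overlap
oracle_hyper_tail <- function(obs, set_size, query_size, background_size) {
  stats::phyper(obs - 1, set_size, background_size - set_size, query_size,
                lower.tail = FALSE)
}

# brute-force phenotype-permutation null for the three gene statistics:
# permutes the phenotype vector itself and recomputes scores from residuals.
# Returns upper-tail p-values (and the min-p grid combination) at fixed seed.
oracle_perm_gene <- function(G, y, B, seed, maf_threshold = 0.010,
                             rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                             phi = 0.5) {
  set.seed(seed)
  mu <- mean(y)
  f <- colMeans(G) / 2; f <- pmin(f, 1 - f)
  w_sk <- dbeta(f, 1, 25)
  w_cb <- ifelse(f <= maf_threshold, sqrt(2 * phi) * dbeta(f, 1, 25),
                 sqrt(2 * (1 - phi)) * dbeta(f, 0.5, 0.5))
  stat <- function(S) {
    WS <- w_sk * S
    c(skat = sum(WS^2), burden = sum(WS)^2, comb = sum((w_cb * S)^2))
  }
  obs <- stat(drop(crossprod(G, y - mu)))
  nrho <- length(rho_grid)
  Qsk <- Qb <- Qcb <- numeric(B)
  done <- 0L
  while (done < B) {
    b <- min(20000L, B - done)
    Y <- vapply(seq_len(b), function(j) sample(y), numeric(length(y)))
    S <- crossprod(G, Y - mu)
    WS <- w_sk * S
    idx <- (done + 1L):(done + b)
    Qsk[idx] <- colSums(WS^2)
    Qb[idx] <- colSums(WS)^2
    Qcb[idx] <- colSums((w_cb * S)^2)
    done <- done + b
  }
  p_skat <- (1 + sum(Qsk >= obs["skat"] - 1e-12)) / (B + 1)
  p_comb <- (1 + sum(Qcb >= obs["comb"] - 1e-12)) / (B + 1)
  # min-p over the rho grid, ranks within the same permutation sample
  Tmin_obs <- Inf; Tb <- rep(Inf, B)
  for (rho in rho_grid) {
    q <- (1 - rho) * Qsk + rho * Qb
    q_obs <- (1 - rho) * obs["skat"] + rho * obs["burden"]
    Tmin_obs <- min(Tmin_obs, (1 + sum(q >= q_obs - 1e-12)) / (B + 1))
    Tb <- pmin(Tb, (B + 1 - rank(q, ties.method = "min")) / B)
  }
  p_opt <- (1 + sum(Tb <= Tmin_obs)) / (B + 1)
  list(p_skat = p_skat, p_comb = p_comb, p_opt = p_opt)
}

# small deterministic variant-table fixture
toy_variants <- function() {
  variant_table(data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr3"),
    pos = c(100L, 200L, 50L, 75L, 10L),
    ref = c("A", "C", "G", "T", "A"),
    alt = c("G", "T", "A", "C", "T"),
    gene = c("G1", "G1", "G2", "G2", "G3"),
    consequence = c("nonsynonymous", "synonymous", "intronic",
                    "nonsynonymous", "stop_gain"),
    min_case = c(10L, 0L, 30L, 1L, 3L),
    maj_case = c(990L, 1000L, 970L, 999L, 997L),
    min_ctrl = c(2L, 5L, 40L, 0L, 3L),
    maj_ctrl = c(1098L, 1095L, 1060L, 1100L, 1097L),
    aa_ref = c("K", NA, NA, "L", NA),
    aa_pos = c(10L, NA, NA, 20L, NA),
    aa_alt = c("E", NA, NA, "L", NA),
    stringsAsFactors = FALSE
  ))
}

# genotype fixture with a given per-variant MAF vector
toy_genotypes <- function(n, mafs, seed) {
  set.seed(seed)
  G <- vapply(mafs, function(f) rbinom(n, 2, f), numeric(n))
  storage.mode(G) <- "integer"
  G
}
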