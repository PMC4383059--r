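# Fixtures and independent oracles shared across the suite.

# iid binomial genotype matrix with alternating case/control labels.
random_gm <- function(m, n, seed, missing_rate = 0, maf = c(0.1, 0.5)) {
  set.seed(seed)
  f <- runif(m, maf[1], maf[2])
  g <- matrix(rbinom(m * n, 2L, rep(f, n)), nrow = m)
  if (missing_rate > 0) g[runif(m * n) < missing_rate] <- NA
  storage.mode(g) <- "integer"
  genotype_matrix(g, rep_len(c(0L, 1L), n))
}

# Textbook Pearson chi-squared on a raw 2 x C count matrix, coded
# independently of the package (explicit double loop over cells); empty
# columns skipped, df = C - 1.
reference_chi2 <- function(counts) {
  counts <- unname(counts)
  n <- sum(counts)
  rm_ <- rowSums(counts)
  cm <- colSums(counts)
  score <- 0
  for (i in 1:2) {
    for (j in seq_along(cm)) {
      if (cm[j] == 0) next
      e <- rm_[i] * cm[j] / n
      score <- score + (counts[i, j] - e)^2 / e
    }
  }
  df <- length(cm) - 1
  list(score = score, df = df,
       p_value = pchisq(score, df, lower.tail = FALSE))
}

# Random 2 x 3^k table with both row sums positive.
random_table <- function(k, seed) {
  set.seed(seed)
  repeat {
    counts <- matrix(rpois(2 * 3^k, lambda = runif(1, 0.5, 30)), nrow = 2)
    if (all(rowSums(counts) > 0)) break
  }
  episcan:::new_contingency_table(counts, k)
}

# Pure-epistasis penetrance for a pair: elevated risk when the two genotype
# values have opposite parity (XOR-like), low risk otherwise.
xor_penetrance <- function(high = 0.8, low = 0.1) {
  d <- expand.grid(g2 = 0:2, g1 = 0:2)   # column order of the 2x9 table
  penetrance_model(2, table = ifelse((d$g1 + d$g2) %% 2 == 1, high, low))
}

# Null case/control cohort from the mosaic simulator: phenotype assigned
# Bernoulli(0.5) independently of all genotypes.
null_cohort <- function(m, n, seed, recomb_rate = 0.5,
                        maf_range = c(0.2, 0.5), h = 100) {
  panel <- generate_panel(h, m, maf_range = maf_range,
                          recomb_rate = recomb_rate, seed = seed)
  gm <- simulate_genotypes(panel, n, seed = seed + 1000L)
  assign_phenotypes(gm, penetrance_model(2, baseline = 0.5), c(1, 2),
                    seed = seed + 2000L)
}
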