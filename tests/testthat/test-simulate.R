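test_that("panels and cohorts replay exactly under a fixed seed", {
  p1 <- generate_panel(20, 30, seed = 1)
  p2 <- generate_panel(20, 30, seed = 1)
  expect_identical(p1, p2)
  g1 <- simulate_genotypes(p1, 50, seed = 2, missing_rate = 0.05)
  g2 <- simulate_genotypes(p1, 50, seed = 2, missing_rate = 0.05)
  expect_identical(g1, g2)
  expect_false(identical(
    g1$genotypes, simulate_genotypes(p1, 50, seed = 3)$genotypes))
  a1 <- assign_phenotypes(g1, penetrance_model(2, baseline = 0.4), c(5, 2),
                          seed = 4)
  a2 <- assign_phenotypes(g1, penetrance_model(2, baseline = 0.4), c(5, 2),
                          seed = 4)
  expect_identical(a1, a2)
})

test_that("panel allele frequencies track their targets", {
  p <- generate_panel(2, 5, seed = 1)
  expect_equal(dim(p$alleles), c(2L, 5L))
  expect_true(all(p$alleles %in% 0:1))
  # degenerate range pins every site frequency at 0.5
  pd <- generate_panel(400, 50, maf_range = c(0.5, 0.5), seed = 2)
  expect_true(all(abs(colMeans(pd$alleles) - 0.5) < 0.1))
  # per-site frequencies inside binomial 99% bounds of their drawn targets
  p9 <- generate_panel(100, 200, maf_range = c(0.05, 0.5), seed = 9)
  obs <- colMeans(p9$alleles)
  half_width <- qnorm(0.995) * sqrt(p9$freqs * (1 - p9$freqs) / 100)
  expect_gt(mean(abs(obs - p9$freqs) <= half_width + 1e-9), 0.95)
  expect_error(generate_panel(10, 5, maf_range = c(0, 0.6)), "interval")
})

test_that("zero recombination copies whole template haplotypes", {
  p <- generate_panel(2, 40, recomb_rate = 0, seed = 3)
  gm <- simulate_genotypes(p, 30, seed = 4)
  combos <- rbind(p$alleles[1, ] + p$alleles[1, ],
                  p$alleles[1, ] + p$alleles[2, ],
                  p$alleles[2, ] + p$alleles[2, ])
  for (j in seq_len(30)) {
    hit <- apply(combos, 1, function(cb) all(cb == gm$genotypes[, j]))
    expect_true(any(hit))
  }
})

test_that("mosaic resampling produces decaying linkage disequilibrium", {
  p <- generate_panel(30, 100, maf_range = c(0.1, 0.5),
                      recomb_rate = 0.01, seed = 5)
  gm <- simulate_genotypes(p, 800, seed = 6)
  g <- gm$genotypes
  r2 <- function(a, b) suppressWarnings(cor(g[a, ], g[b, ]))^2
  adj <- vapply(seq_len(99), function(a) r2(a, a + 1), numeric(1))
  far_pairs <- cbind(1:50, 51:100)
  far <- vapply(seq_len(50), function(i) r2(far_pairs[i, 1],
                                            far_pairs[i, 2]), numeric(1))
  expect_gt(mean(adj, na.rm = TRUE), mean(far, na.rm = TRUE))
  # full per-site reshuffling leaves adjacent sites essentially uncorrelated
  p1 <- generate_panel(200, 100, maf_range = c(0.1, 0.5),
                       recomb_rate = 1, seed = 7)
  g1 <- simulate_genotypes(p1, 800, seed = 8)$genotypes
  adj1 <- vapply(seq_len(99), function(a)
    suppressWarnings(cor(g1[a, ], g1[a + 1, ]))^2, numeric(1))
  expect_lt(mean(adj1, na.rm = TRUE), 0.01)
})

test_that("genotypes stay in 0/1/2 and missingness only appears on request", {
  p <- generate_panel(10, 20, seed = 1)
  gm <- simulate_genotypes(p, 100, seed = 2)
  expect_true(all(gm$genotypes %in% 0:2))
  gmm <- simulate_genotypes(p, 100, seed = 2, missing_rate = 0.2)
  frac <- mean(is.na(gmm$genotypes))
  expect_gt(frac, 0.1); expect_lt(frac, 0.3)
})

test_that("deterministic penetrance makes every case carry the risk combo", {
  p <- generate_panel(50, 10, maf_range = c(0.4, 0.5), seed = 11)
  gm <- simulate_genotypes(p, 600, seed = 12)
  tab <- rep(0, 9); tab[9] <- 1   # only combination (2,2) can become a case
  gm2 <- assign_phenotypes(gm, penetrance_model(2, table = tab), c(3, 7),
                           seed = 13)
  cases <- gm2$phenotypes == 1L
  expect_gt(sum(cases), 0)
  expect_true(all(gm2$genotypes[3, cases] == 2L &
                  gm2$genotypes[7, cases] == 2L))
})

test_that("ascertainment hits the requested cohort composition or errors", {
  p <- generate_panel(50, 8, seed = 14)
  gm <- simulate_genotypes(p, 500, seed = 15)
  bal <- assign_phenotypes(gm, penetrance_model(2, baseline = 0.5), c(1, 2),
                           target_cases = 100, seed = 16)
  expect_equal(sum(bal$phenotypes == 1L), 100L)
  expect_equal(sum(bal$phenotypes == 0L), 100L)
  expect_error(
    assign_phenotypes(gm, penetrance_model(2, baseline = 0.01), c(1, 2),
                      target_cases = 400, seed = 17),
    "simulate more samples")
})

test_that("null labelling gives centred p-values in a keep-all scan", {
  gm <- null_cohort(30, 1000, seed = 23)
  sc <- run_scan(gm, k = 2)
  expect_gt(median(sc$results$p_value), 0.35)
  expect_lt(median(sc$results$p_value), 0.65)
})

test_that("simulate_gwas assembles a balanced labelled cohort in one call", {
  gm <- simulate_gwas(m = 15, n = 200, seed = 5)
  expect_equal(dim(gm), c(15L, 200L))
  expect_equal(sum(gm$phenotypes == 1L), 100L)
})
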