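test_that("a keep-all pairwise scan evaluates exactly C(m,2) tuples in order", {
  gm <- random_gm(10, 60, seed = 1)
  sc <- run_scan(gm, k = 2, threshold = -Inf)
  expect_equal(sc$n_evaluated, 45)
  expect_equal(sc$n_kept, 45L)
  expect_equal(sc$results$linear_index, as.numeric(0:44))
  # tuples stored descending and consistent with their linear index
  for (i in seq_len(45))
    expect_equal(rank_tuple(sc$tuples[i, ]), sc$results$linear_index[i])
})

test_that("an unreachable score threshold keeps nothing", {
  gm <- random_gm(10, 60, seed = 1)
  sc <- run_scan(gm, k = 2, threshold = Inf)
  expect_equal(sc$n_kept, 0L)
  expect_equal(sc$n_evaluated, 45)
  expect_equal(nrow(as.data.frame(sc)), 0L)
})

test_that("scan output is bit-identical for any worker count", {
  gm <- random_gm(30, 150, seed = 9, missing_rate = 0.02)
  base <- run_scan(gm, k = 2, n_workers = 1)
  for (np in c(2, 3, 8)) {
    sc <- run_scan(gm, k = 2, n_workers = np)
    expect_identical(sc$results, base$results)
    expect_identical(sc$tuples, base$tuples)
  }
})

test_that("the scan keeps ties at the threshold (score >= t)", {
  gm <- random_gm(12, 80, seed = 4)
  all_ <- run_scan(gm, k = 2)
  t <- sort(all_$results$score, decreasing = TRUE)[5]
  kept <- run_scan(gm, k = 2, threshold = t)
  expect_equal(kept$n_kept, sum(all_$results$score >= t))
  expect_true(t %in% kept$results$score)
})

test_that("p-value thresholding selects the complementary tail", {
  gm <- random_gm(12, 80, seed = 4)
  all_ <- run_scan(gm, k = 2)
  sc <- run_scan(gm, k = 2, threshold = 0.05,
                 threshold_space = "p_value")
  expect_equal(sort(sc$results$linear_index),
               sort(all_$results$linear_index[all_$results$p_value <= 0.05]))
  # threshold 1 in p space keeps everything
  expect_equal(run_scan(gm, k = 2, threshold = 1,
                        threshold_space = "p_value")$n_kept, 66L)
})

test_that("scans at k = 1 and k = 3 agree with direct evaluation", {
  gm <- random_gm(8, 100, seed = 12, missing_rate = 0.03)
  ds <- binarise(gm)
  for (k in c(1, 3)) {
    sc <- run_scan(gm, k = k)
    expect_equal(sc$n_evaluated, count_interactions(8, k))
    for (i in seq_len(sc$n_kept)) {
      tuple <- sc$tuples[i, ]
      r <- chi_squared(build_contingency_table(ds, tuple))
      expect_equal(sc$results$score[i], r$score, tolerance = 1e-12)
      expect_equal(sc$results$p_value[i], r$p_value, tolerance = 1e-12)
      expect_equal(sc$results$df[i], r$df)
    }
  }
})

test_that("a registered custom statistic drives the scan identically", {
  gm <- random_gm(9, 70, seed = 6)
  register_statistic("neg_chi2", function(ct) {
    r <- chi_squared(ct)
    list(score = -r$score, df = r$df, p_value = r$p_value)
  })
  sc <- run_scan(gm, k = 2, statistic = "neg_chi2", threshold = -Inf)
  ref <- run_scan(gm, k = 2)
  expect_equal(sc$results$score, -ref$results$score)
  expect_error(run_scan(gm, k = 2, statistic = "missing_stat"),
               "unknown statistic")
})

test_that("statistic failures name the offending tuple", {
  gm <- random_gm(5, 30, seed = 2)
  register_statistic("bomb", function(ct) stop("boom"))
  expect_error(run_scan(gm, k = 2, statistic = "bomb"),
               "\"bomb\" failed on tuple \\(2,1\\): boom")
})

test_that("an embedded pairwise effect tops the exhaustive scan", {
  panel <- generate_panel(100, 50, maf_range = c(0.1, 0.5),
                          recomb_rate = 0.01, seed = 17)
  gm <- simulate_genotypes(panel, 1600, seed = 117)
  gm <- assign_phenotypes(gm, xor_penetrance(), c(30, 10),
                          target_cases = 200, seed = 217)
  expect_equal(n_samples(gm), 400)
  sc <- run_scan(gm, k = 2)
  expect_equal(sc$n_evaluated, 1225)
  top <- sc$tuples[which.max(sc$results$score), ]
  expect_setequal(top, c(30, 10))
})

test_that("results files round-trip and follow linear-index order", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "res.tsv")
  gm <- random_gm(10, 60, seed = 1)

  sc0 <- run_scan(gm, k = 2, threshold = Inf)
  write_results(sc0, path = path)
  expect_equal(readLines(path),
               "snp_ids\tsnp_indices\tlinear_index\tscore\tdf\tp_value")

  sc <- run_scan(gm, k = 2)
  write_results(sc, path = path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 45L)
  expect_equal(tab$linear_index, 0:44)
  expect_equal(tab$score, sc$results$score, tolerance = 1e-9)
  expect_equal(tab$p_value, sc$results$p_value, tolerance = 1e-9)
  expect_equal(tab$snp_ids[1], paste(gm$snp_ids[2:1], collapse = ","))
})

test_that("the kept-result cap guards keep-all scans", {
  gm <- random_gm(12, 40, seed = 3)
  cfg <- scan_config(k = 2, max_results = 10)
  expect_error(run_scan(gm, cfg), "cap exceeded")
})

test_that("scan objects print and summarise without error", {
  gm <- random_gm(10, 60, seed = 1)
  sc <- run_scan(gm, k = 2)
  expect_output(print(sc), "epi_scan: order k=2")
  expect_output(print(summary(sc)), "strongest interactions")
  expect_silent(grDevices::pdf(NULL))
  plot(sc)
  grDevices::dev.off()
})
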