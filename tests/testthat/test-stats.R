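test_that("identical case and control rows give score 0 and p 1", {
  row <- c(10, 20, 30, 5, 5, 5, 10, 10, 5)
  ct <- episcan:::new_contingency_table(rbind(row, row), 2)
  r <- chi_squared(ct)
  expect_equal(r$score, 0)
  expect_equal(r$p_value, 1)
})

test_that("degrees of freedom follow the table size |V| - 1", {
  expect_equal(chi_squared(random_table(2, 1))$df, 8)
  expect_equal(chi_squared(random_table(3, 1))$df, 26)
})

test_that("chi-squared matches independently coded references to 1e-10", {
  counts <- rbind(c(10, 5, 5, 20, 10, 0, 5, 3, 2),
                  c(5, 10, 10, 10, 15, 5, 3, 2, 0))
  ct <- episcan:::new_contingency_table(counts, 2)
  r <- chi_squared(ct)
  ref <- reference_chi2(counts)
  expect_equal(r$score, ref$score, tolerance = 1e-10)
  expect_equal(r$p_value, ref$p_value, tolerance = 1e-10)

  err_ref <- err_chisq <- 0
  n_chisq <- 0L
  for (seed in 1:200) {
    for (k in 2:3) {
      ct <- random_table(k, seed * 10 + k)
      r <- chi_squared(ct)
      ref <- reference_chi2(ct$counts)
      err_ref <- max(err_ref, abs(r$score - ref$score),
                     abs(r$p_value - ref$p_value))
      # stats::chisq.test agrees whenever no column is empty
      if (all(ct$col_marginals > 0)) {
        ref2 <- suppressWarnings(stats::chisq.test(ct$counts,
                                                   correct = FALSE))
        err_chisq <- max(err_chisq,
                         abs(r$score - unname(ref2$statistic)),
                         abs(r$p_value - ref2$p.value))
        n_chisq <- n_chisq + 1L
      }
    }
  }
  expect_lt(err_ref, 1e-10)
  expect_lt(err_chisq, 1e-10)
  expect_gt(n_chisq, 50)
})

test_that("empty columns are skipped but df keeps the nominal table size", {
  counts <- rbind(c(10, 0, 5, 0, 0, 0, 0, 0, 0),
                  c(2, 0, 9, 0, 0, 0, 0, 0, 0))
  ct <- episcan:::new_contingency_table(counts, 2)
  r <- chi_squared(ct)
  expect_equal(r$df, 8)
  expect_true(is.finite(r$score))
  r2 <- chi_squared(ct, df_observed = TRUE)
  expect_equal(r2$df, 1)
  expect_equal(r2$score, r$score)
  expect_lt(r2$p_value, r$p_value)  # fewer df: same score is more extreme
})

test_that("score scales exactly linearly when every cell is multiplied", {
  ct <- random_table(2, 77)
  r1 <- chi_squared(ct)
  for (c_ in c(2L, 5L)) {
    cts <- episcan:::new_contingency_table(ct$counts * c_, 2)
    expect_equal(chi_squared(cts)$score, c_ * r1$score, tolerance = 1e-12)
  }
})

test_that("score is invariant to column permutation and row swap", {
  ct <- random_table(2, 31)
  r <- chi_squared(ct)
  set.seed(2)
  perm <- sample(9)
  ctp <- episcan:::new_contingency_table(ct$counts[, perm], 2)
  expect_equal(chi_squared(ctp)$score, r$score, tolerance = 1e-12)
  expect_equal(chi_squared(ctp)$p_value, r$p_value, tolerance = 1e-12)
  cts <- episcan:::new_contingency_table(ct$counts[2:1, ], 2)
  expect_equal(chi_squared(cts)$score, r$score, tolerance = 1e-12)
})

test_that("degenerate tables are rejected", {
  empty_row <- episcan:::new_contingency_table(
    rbind(c(3, 2, 1, rep(0, 6)), rep(0, 9)), 2)
  expect_error(chi_squared(empty_row), "phenotype row is empty")
  all_zero <- episcan:::new_contingency_table(matrix(0, 2, 9), 2)
  expect_error(chi_squared(all_zero), "n = 0")
})

test_that("tables with small expected counts are flagged", {
  big <- episcan:::new_contingency_table(matrix(100, 2, 9), 2)
  expect_false(chi_squared(big)$low_expected)
  sparse <- episcan:::new_contingency_table(
    rbind(c(100, rep(1, 8)), c(100, rep(2, 8))), 2)
  expect_true(chi_squared(sparse)$low_expected)
})

test_that("the statistic registry dispatches, extends and reports unknowns", {
  ct <- random_table(2, 5)
  r <- evaluate_statistic(ct, "chi2")
  expect_equal(r$score, chi_squared(ct)$score)
  expect_error(evaluate_statistic(ct, "nope"),
               "unknown statistic \"nope\".*chi2")

  register_statistic("const7", function(ct)
    list(score = 7, df = 1, p_value = 0.5))
  expect_equal(evaluate_statistic(ct, "const7")$score, 7)

  # log-likelihood-ratio G statistic: asymptotically equivalent to chi2,
  # both near 0 on a near-independent table
  register_statistic("gtest", function(ct) {
    o <- ct$counts; nz <- ct$col_marginals > 0
    e <- outer(ct$row_marginals, ct$col_marginals[nz]) / ct$total
    o <- o[, nz, drop = FALSE]
    g <- 2 * sum(ifelse(o > 0, o * log(o / e), 0))
    episcan:::new_statistic_result(g, ncol(ct$counts) - 1)
  })
  near_ind <- episcan:::new_contingency_table(
    rbind(c(50, 40, 30, 20, 10, 9, 8, 7, 6),
          c(49, 41, 30, 21, 10, 9, 8, 7, 5)), 2)
  g <- evaluate_statistic(near_ind, "gtest")$score
  x2 <- evaluate_statistic(near_ind, "chi2")$score
  expect_lt(abs(g - x2), 0.2)
  expect_lt(x2, 1)
})
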