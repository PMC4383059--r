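#' Pearson's chi-squared test on a phenotype-by-genotype contingency table
#'
#' Scores a 2 x `3^k` contingency table with the Pearson statistic
#' \deqn{\chi^2 = \sum_i \sum_j (n_{ij} - E_{ij})^2 / E_{ij}, \qquad
#'       E_{ij} = n_{i+} n_{+j} / n,}
#' the screening statistic of the exhaustive scan. Columns whose marginal
#' `n_+j` is zero (genotype combinations observed in no sample) contribute
#' nothing to the sum; by default the degrees of freedom nevertheless stay at
#' `|V| - 1 = 3^k - 1`, the nominal table size. Set `df_observed = TRUE` for
#' the conservative alternative that counts only non-empty columns. No
#' continuity correction and no minimum-expected-count guard are applied —
#' this is a fast screen — but tables containing any expected count below 5
#' are flagged in the `low_expected` field so callers can count them.
#'
#' @param ct a `"contingency_table"` (see [build_contingency_table()]).
#' @param df_observed use `(non-empty columns) - 1` degrees of freedom.
#' @return A `"statistic_result"`: list with `score`, `df`, `p_value`
#'   (upper tail) and `low_expected`.
#' @examples
#' gm <- genotype_matrix(matrix(c(0L, 1L, 2L, 1L, 1L, 0L, 2L, 0L), nrow = 2),
#'                       phenotypes = c(0L, 0L, 1L, 1L))
#' chi_squared(build_contingency_table(binarise(gm), c(1, 2)))
#' @export
chi_squared <- function(ct, df_observed = FALSE) {
  stopifnot(inherits(ct, "contingency_table"))
  o <- ct$counts
  n <- ct$total
  rm_ <- ct$row_marginals
  cm <- ct$col_marginals
  if (n <= 0) stop("degenerate contingency table: no observations (n = 0)")
  if (any(rm_ <= 0))
    stop("degenerate contingency table: a phenotype row is empty")

  nz <- cm > 0
  e <- outer(rm_, cm[nz]) / n
  score <- sum((o[, nz, drop = FALSE] - e)^2 / e)
  df <- if (df_observed) sum(nz) - 1L else ncol(o) - 1L
  new_statistic_result(score, df, low_expected = any(e < 5))
}

new_statistic_result <- function(score, df, p_value = NULL,
                                 low_expected = FALSE) {
  if (is.null(p_value))
    p_value <- stats::pchisq(score, df = df, lower.tail = FALSE)
  structure(list(score = score, df = df, p_value = p_value,
                 low_expected = isTRUE(low_expected)),
            class = "statistic_result")
}

#' @export
print.statistic_result <- function(x, ...) {
  cat(sprintf("score = %.6g, df = %d, p = %.4g%s\n", x$score, x$df, x$p_value,
              if (x$low_expected) " (expected count < 5 present)" else ""))
  invisible(x)
}

# Registry of contingency-table statistics, keyed by name.  "chi2" ships by
# default (registered in .onLoad); users may add any function mapping a
# contingency_table to a statistic_result-like list.
.stat_registry <- new.env(parent = emptyenv())

#' Register or list contingency-table statistics
#'
#' The scan accepts any statistic that maps a contingency table to a score:
#' register a function under a name and pass that name in [scan_config()].
#' The function receives a `"contingency_table"` and must return a list with
#' at least `score`, `df` and `p_value` elements (see [chi_squared()], which
#' is pre-registered as `"chi2"`).
#'
#' @param name statistic name.
#' @param fn function of one argument (the contingency table).
#' @return `register_statistic` returns `fn` invisibly; `list_statistics`
#'   the registered names.
#' @export
register_statistic <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.function(fn))
  assign(name, fn, envir = .stat_registry)
  invisible(fn)
}

#' @rdname register_statistic
#' @export
list_statistics <- function() sort(ls(.stat_registry))

get_statistic <- function(name) {
  if (!exists(name, envir = .stat_registry, inherits = FALSE))
    stop(sprintf("unknown statistic \"%s\"; registered statistics: %s",
                 name, paste(list_statistics(), collapse = ", ")))
  get(name, envir = .stat_registry, inherits = FALSE)
}

#' Evaluate a registered statistic on a contingency table
#'
#' @param ct a `"contingency_table"`.
#' @param statistic registered statistic name (default `"chi2"`).
#' @return The statistic's result (for `"chi2"`, a `"statistic_result"`).
#' @export
evaluate_statistic <- function(ct, statistic = "chi2") {
  get_statistic(statistic)(ct)
}
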