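#' Configuration for an exhaustive interaction scan
#'
#' @param k interaction order (2 = pairs, 3 = triples; 1 gives the univariate
#'   baseline).
#' @param threshold significance threshold `t`. With
#'   `threshold_space = "score"` a tuple is kept when `score >= t` (so
#'   `-Inf` keeps everything); with `"p_value"` when `p <= t`.
#' @param threshold_space `"score"` or `"p_value"`.
#' @param statistic registered statistic name (see [register_statistic()]).
#' @param n_workers number of parallel workers standing in for compute ranks.
#' @param chunk_size tuples evaluated per inner batch within a worker.
#' @param max_results cap on kept results, guarding keep-all scans at large m.
#' @param seed unused by the deterministic scan; reserved for statistics that
#'   may need randomness.
#' @return A `"scan_config"` list.
#' @export
scan_config <- function(k = 2, threshold = -Inf,
                        threshold_space = c("score", "p_value"),
                        statistic = "chi2", n_workers = 1,
                        chunk_size = 4096, max_results = 1e7, seed = NULL) {
  threshold_space <- match.arg(threshold_space)
  if (length(k) != 1L || is.na(k) || k < 1 || k != round(k))
    stop("`k` must be a positive integer")
  if (length(threshold) != 1L || is.na(threshold))
    stop("`threshold` must be a single number")
  if (threshold_space == "p_value" && !is.finite(threshold))
    stop("a p-value threshold must be finite")
  if (n_workers < 1 || n_workers != round(n_workers))
    stop("`n_workers` must be a positive integer")
  if (chunk_size < 1) stop("`chunk_size` must be positive")
  structure(list(k = as.integer(k), threshold = threshold,
                 threshold_space = threshold_space, statistic = statistic,
                 n_workers = as.integer(n_workers),
                 chunk_size = chunk_size, max_results = max_results,
                 seed = seed),
            class = "scan_config")
}

# Evaluate linear indices [start, end) against a bit-sliced dataset.
# Fast path: chi-squared fully inside compiled code.  Generic path: build the
# table, call the registered statistic from R.
scan_interval <- function(ds, cfg, start, end) {
  k <- cfg$k
  p_space <- cfg$threshold_space == "p_value"
  fast <- cfg$statistic == "chi2" &&
    identical(get_statistic("chi2"), chi_squared)
  acc <- list()           # per-chunk pieces, concatenated once at the end
  n_low <- 0
  n_kept <- 0
  at <- start
  while (at < end) {
    hi <- min(at + cfg$chunk_size, end)
    if (fast) {
      ch <- cpp_scan_chi2(ds$bits0, ds$bits1,
                          ds$words_per_class[1], ds$words_per_class[2],
                          ds$m, k, at, hi,
                          cfg$threshold, p_space, cfg$max_results - n_kept)
      n_low <- n_low + ch$n_low_expected
      n_kept <- n_kept + length(ch$score)
      acc[[length(acc) + 1L]] <-
        list(linear_index = ch$linear_index, score = ch$score,
             df = rep.int(3^k - 1, length(ch$score)),
             p_value = ch$p_value, snps = ch$snps + 1L)
    } else {
      fn <- get_statistic(cfg$statistic)
      for (i in at:(hi - 1)) {
        tuple <- unrank_index(i, k)
        ct <- build_contingency_table(ds, tuple)
        res <- tryCatch(fn(ct), error = function(e) {
          stop(sprintf("statistic \"%s\" failed on tuple (%s): %s",
                       cfg$statistic, paste(tuple, collapse = ","),
                       conditionMessage(e)), call. = FALSE)
        })
        if (isTRUE(res$low_expected)) n_low <- n_low + 1
        keep <- if (p_space) res$p_value <= cfg$threshold
                else res$score >= cfg$threshold
        if (keep) {
          n_kept <- n_kept + 1
          if (n_kept > cfg$max_results)
            stop("kept-result cap exceeded; raise the threshold or max_results")
          acc[[length(acc) + 1L]] <-
            list(linear_index = i, score = res$score, df = res$df,
                 p_value = res$p_value, snps = matrix(tuple, nrow = 1))
        }
      }
    }
    at <- hi
  }
  list(linear_index = as.numeric(unlist(lapply(acc, `[[`, "linear_index"))),
       score = as.numeric(unlist(lapply(acc, `[[`, "score"))),
       df = as.numeric(unlist(lapply(acc, `[[`, "df"))),
       p_value = as.numeric(unlist(lapply(acc, `[[`, "p_value"))),
       snps = do.call(rbind, c(list(matrix(integer(0), ncol = k)),
                               lapply(acc, `[[`, "snps"))),
       n_low_expected = n_low, n_evaluated = end - start)
}

#' Run an exhaustive k-way SNP interaction scan
#'
#' The scan executor: bit-slices the cohort once, partitions the
#' `choose(m, k)` tuple index space evenly across `n_workers` parallel
#' workers (each holding the shared read-only encoded data), and has each
#' worker unrank, tabulate and score its private interval, keeping tuples
#' that pass the threshold. Per-worker result lists are merged into a single
#' list ordered by linear index. The scan is deterministic: its output is
#' identical for any worker count.
#'
#' @param gm a [genotype_matrix()] with at least one case and one control.
#' @param config a [scan_config()]; further arguments to [scan_config()] may
#'   be given directly via `...` instead.
#' @param ... passed to [scan_config()] when `config` is `NULL`.
#' @return An object of class `"epi_scan"` with the kept interactions
#'   (`$results`: SNP indices, linear index, score, df, p-value), evaluation
#'   counters and timing. `as.data.frame()` extracts the result table with
#'   SNP ids attached.
#' @examples
#' gm <- simulate_genotypes(generate_panel(20, 12, seed = 1), 60, seed = 2)
#' gm$phenotypes <- rep(c(0L, 1L), 30)
#' scan <- run_scan(gm, k = 2)       # keep-all pairwise scan
#' head(as.data.frame(scan))
#' @export
run_scan <- function(gm, config = NULL, ...) {
  stopifnot(inherits(gm, "genotype_matrix"))
  cfg <- if (is.null(config)) scan_config(...) else config
  stopifnot(inherits(cfg, "scan_config"))
  m <- n_snps(gm)
  if (cfg$k > m)
    stop(sprintf("interaction order k=%d exceeds SNP count m=%d", cfg$k, m))
  get_statistic(cfg$statistic)   # fail early on unknown names

  t0 <- proc.time()[["elapsed"]]
  ds <- binarise(gm)
  np <- min(cfg$n_workers, count_interactions(m, cfg$k))
  worker <- function(rank) {
    part <- assign_interactions(rank, np, m, cfg$k)
    scan_interval(ds, cfg, part$start, part$end)
  }
  pieces <- if (np > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(0:(np - 1), worker, mc.cores = np)
  } else {
    lapply(0:(np - 1), worker)
  }
  err <- vapply(pieces, inherits, logical(1), "try-error")
  if (any(err)) stop(attr(pieces[[which(err)[1]]], "condition"))

  # rank-0 merge: partitions are contiguous and ascending, so concatenation
  # in rank order is already sorted by linear index
  res <- data.frame(
    linear_index = unlist(lapply(pieces, `[[`, "linear_index")),
    score = unlist(lapply(pieces, `[[`, "score")),
    df = unlist(lapply(pieces, `[[`, "df")),
    p_value = unlist(lapply(pieces, `[[`, "p_value")))
  tuples <- do.call(rbind, lapply(pieces, `[[`, "snps"))
  elapsed <- proc.time()[["elapsed"]] - t0

  structure(list(results = res, tuples = tuples,
                 k = cfg$k, m = m, n = n_samples(gm),
                 snp_ids = gm$snp_ids,
                 class_sizes = ds$class_sizes,
                 config = cfg,
                 n_evaluated = sum(vapply(pieces, `[[`, numeric(1),
                                          "n_evaluated")),
                 n_kept = nrow(res),
                 n_low_expected = sum(vapply(pieces, `[[`, numeric(1),
                                             "n_low_expected")),
                 elapsed_seconds = elapsed),
            class = "epi_scan")
}

#' @export
print.epi_scan <- function(x, ...) {
  cat(sprintf("epi_scan: order k=%d over %d SNPs x %d samples (%d cases / %d controls)\n",
              x$k, x$m, x$n, x$class_sizes[["case"]],
              x$class_sizes[["control"]]))
  cat(sprintf("  evaluated %g tuples, kept %d (%s %s %g), statistic \"%s\", %d worker(s), %.2f s\n",
              x$n_evaluated, x$n_kept,
              x$config$threshold_space,
              if (x$config$threshold_space == "score") ">=" else "<=",
              x$config$threshold, x$config$statistic,
              x$config$n_workers, x$elapsed_seconds))
  if (x$n_kept > 0) {
    cat("  top interactions by score:\n")
    df <- as.data.frame(x)
    print(utils::head(df[order(-df$score), ], 5), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.epi_scan <- function(object, ...) {
  s <- list(k = object$k, m = object$m, n = object$n,
            n_evaluated = object$n_evaluated, n_kept = object$n_kept,
            n_low_expected = object$n_low_expected,
            elapsed_seconds = object$elapsed_seconds,
            top = if (object$n_kept > 0) {
              df <- as.data.frame(object)
              utils::head(df[order(-df$score), ], 10)
            })
  class(s) <- "summary.epi_scan"
  s
}

#' @export
print.summary.epi_scan <- function(x, ...) {
  cat(sprintf("Exhaustive k=%d interaction scan: %g tuples over %d SNPs, %d samples\n",
              x$k, x$n_evaluated, x$m, x$n))
  cat(sprintf("  kept %d; %g tables had an expected count < 5 (chi-squared approximation weak)\n",
              x$n_kept, x$n_low_expected))
  if (!is.null(x$top)) { cat("  strongest interactions:\n"); print(x$top, row.names = FALSE) }
  invisible(x)
}

#' @export
as.data.frame.epi_scan <- function(x, ...) {
  if (x$n_kept == 0)
    return(cbind(data.frame(snp_ids = character(0),
                            snp_indices = character(0)), x$results))
  ids <- apply(x$tuples, 1L, function(t) paste(x$snp_ids[t], collapse = ","))
  idxs <- apply(x$tuples, 1L, paste, collapse = ",")
  cbind(data.frame(snp_ids = ids, snp_indices = idxs), x$results)
}

#' @export
plot.epi_scan <- function(x, ...) {
  if (x$n_kept == 0) stop("no kept interactions to plot")
  p <- pmax(x$results$p_value, .Machine$double.xmin)
  graphics::plot(x$results$linear_index, -log10(p),
                 xlab = "tuple linear index (combinadic)",
                 ylab = expression(-log[10](p)),
                 main = sprintf("k=%d interaction scan", x$k),
                 pch = 20, cex = 0.5, ...)
  invisible(x)
}

#' Write scan results as TSV
#'
#' One row per kept interaction, ordered by linear index: comma-joined SNP
#' ids (descending index order), 1-based SNP indices, combinadic linear
#' index, score, degrees of freedom and p-value. Numeric columns are printed
#' with 10 significant digits so output files are deterministic.
#'
#' @param results an `"epi_scan"` object, or a result data frame from one.
#' @param gm the scanned [genotype_matrix()]; only needed when `results` is a
#'   bare data frame (for SNP ids).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_results <- function(results, gm = NULL, path) {
  if (inherits(results, "epi_scan")) {
    df <- as.data.frame(results)
  } else {
    stopifnot(is.data.frame(results), inherits(gm, "genotype_matrix"))
    df <- results
  }
  header <- "snp_ids\tsnp_indices\tlinear_index\tscore\tdf\tp_value"
  lines <- if (nrow(df)) {
    sprintf("%s\t%s\t%.15g\t%.10g\t%d\t%.10g",
            df$snp_ids, df$snp_indices, df$linear_index, df$score,
            as.integer(df$df), df$p_value)
  } else character(0)
  writeLines(c(header, lines), path)
  invisible(path)
}
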