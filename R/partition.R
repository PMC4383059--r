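#' Total number of k-way interactions among m SNPs
#'
#' The exhaustive scan evaluates every unordered k-subset of the m SNPs, i.e.
#' `choose(m, k)` tuples. Counts are exact as long as they stay below 2^53
#' (double-precision integer range), which covers genome-scale pair and
#' triple counts comfortably.
#'
#' @param m number of SNPs (`m >= 1`).
#' @param k interaction order (`1 <= k <= m`).
#' @return The interaction count as a (whole) numeric.
#' @examples
#' count_interactions(4, 2)        # 6
#' count_interactions(10000, 2)    # ~50 million
#' @export
count_interactions <- function(m, k) {
  if (length(m) != 1L || length(k) != 1L || is.na(m) || is.na(k))
    stop("`m` and `k` must be single numbers")
  if (k < 1 || m < 1 || k != round(k) || m != round(m))
    stop("`m` and `k` must be positive integers")
  if (k > m) stop(sprintf("interaction order k=%d exceeds SNP count m=%d", k, m))
  total <- choose(m, k)
  if (total > 2^53)
    warning("interaction count exceeds 2^53; value is no longer exact")
  total
}

#' Combinadic rank of a SNP tuple
#'
#' Maps a strictly decreasing tuple of SNP indices to its 0-based linear
#' index in the combinatorial number system:
#' `index = sum_i choose(x_i - 1, i)` where `x_i` is the i-th smallest SNP of
#' the tuple (indices are 1-based at the R surface; the combinadic itself is
#' defined on the 0-based values `x_i - 1`). Enumeration is colexicographic,
#' so ranks run from 0 for tuple `(2, 1)` up to `choose(m, k) - 1`.
#'
#' @param tuple strictly decreasing 1-based SNP indices.
#' @return The 0-based linear index (numeric).
#' @examples
#' rank_tuple(c(2, 1))      # 0
#' rank_tuple(c(4, 2, 1))   # 1
#' @seealso [unrank_index()] for the inverse.
#' @export
rank_tuple <- function(tuple) {
  tuple <- as.numeric(tuple)
  k <- length(tuple)
  if (k < 1L) stop("tuple must contain at least one SNP index")
  if (anyNA(tuple) || any(tuple < 1) || any(tuple != round(tuple)))
    stop("SNP indices must be positive integers")
  if (k > 1L && any(diff(tuple) >= 0))
    stop("tuple must be strictly decreasing (x_k > ... > x_1); an unordered tuple would duplicate tests")
  x0 <- rev(tuple) - 1           # ascending, 0-based
  sum(choose(x0, seq_len(k)))
}

#' Combinadic unranking: linear index to SNP tuple
#'
#' Greedy decoding of the combinatorial number system: for `i = k` down to 1
#' pick the largest `x` with `choose(x, i) <=` the remaining index and
#' subtract. Inverse of [rank_tuple()] on `[0, choose(m, k))`.
#'
#' @param index 0-based linear index (`index >= 0`).
#' @param k interaction order.
#' @return Strictly decreasing 1-based SNP indices of length `k`.
#' @examples
#' unrank_index(0, 2)   # c(2, 1)
#' unrank_index(2, 3)   # c(4, 3, 1)
#' @export
unrank_index <- function(index, k) {
  if (length(index) != 1L || is.na(index) || index < 0 ||
      index != round(index))
    stop("`index` must be a single non-negative integer")
  if (length(k) != 1L || is.na(k) || k < 1 || k != round(k))
    stop("`k` must be a positive integer")
  rem <- as.numeric(index)
  out <- numeric(k)
  for (i in seq(k, 1L)) {
    x <- i - 1
    while (choose(x + 1, i) <= rem) x <- x + 1
    rem <- rem - choose(x, i)
    out[k - i + 1L] <- x
  }
  out + 1
}

#' Assign a contiguous block of interactions to a worker
#'
#' Static load balancing over the 0-based linear index space
#' `[0, choose(m, k))`: each of the `n_workers` ranks receives a contiguous
#' half-open interval of size `floor(total / n_workers)`, with the first
#' `total %% n_workers` ranks taking one extra. Intervals are disjoint, cover
#' the space, and differ in size by at most one, so each worker can derive
#' its bounds independently from its rank alone.
#'
#' @param rank 0-based worker id in `[0, n_workers)`.
#' @param n_workers number of parallel workers (`>= 1`).
#' @param m SNP count.
#' @param k interaction order.
#' @return A `"work_partition"`: list with `rank`, `n_workers`, `start`,
#'   `end` (0-based, half-open).
#' @examples
#' assign_interactions(0, 3, m = 5, k = 2)  # [0, 4)
#' @export
assign_interactions <- function(rank, n_workers, m, k) {
  if (length(n_workers) != 1L || is.na(n_workers) || n_workers < 1 ||
      n_workers != round(n_workers))
    stop("`n_workers` must be a positive integer")
  if (length(rank) != 1L || is.na(rank) || rank != round(rank) ||
      rank < 0 || rank >= n_workers)
    stop(sprintf("`rank` must lie in 0..%d", n_workers - 1))
  total <- count_interactions(m, k)
  base <- floor(total / n_workers)
  extra <- total - base * n_workers    # == total %% n_workers
  start <- rank * base + min(rank, extra)
  end <- start + base + (rank < extra)
  structure(list(rank = rank, n_workers = n_workers,
                 start = start, end = end),
            class = "work_partition")
}

#' @export
print.work_partition <- function(x, ...) {
  cat(sprintf("work_partition: rank %d of %d -> [%g, %g) (%g tuples)\n",
              x$rank, x$n_workers, x$start, x$end, x$end - x$start))
  invisible(x)
}
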