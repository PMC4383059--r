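#' Bit-slice a genotype matrix
#'
#' Converts a genotype matrix to the bit-sliced representation used by the
#' scan engine. Each SNP becomes three binary presence vectors, one per
#' genotype value, and each vector is split by phenotype class and packed into
#' 64-bit words, so that the count of samples of a class carrying a full
#' genotype combination at a k-SNP tuple is the popcount of the bitwise AND
#' of k words-long vectors. Missing genotypes set no bit in any slice and so
#' drop out of every table built from the tuple (complete-case counting).
#'
#' @param gm a [genotype_matrix()] with at least one case and one control.
#' @return An object of class `"bitsliced_dataset"`: the packed per-class
#'   buffers, word counts, class sizes, and the SNP/sample bookkeeping needed
#'   to interpret results.
#' @export
binarise <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (all(gm$phenotypes == 0L) || all(gm$phenotypes == 1L))
    stop("need at least one case and at least one control to bit-slice")
  enc <- cpp_binarise(gm$genotypes, gm$phenotypes)
  structure(list(m = enc$m,
                 bits0 = enc$bits0, bits1 = enc$bits1,
                 words_per_class = c(control = enc$words0, case = enc$words1),
                 class_sizes = c(control = enc$n0, case = enc$n1),
                 snp_ids = gm$snp_ids),
            class = "bitsliced_dataset")
}

#' @export
print.bitsliced_dataset <- function(x, ...) {
  cat(sprintf("bitsliced_dataset: %d SNPs; %d controls (%d words), %d cases (%d words)\n",
              x$m, x$class_sizes[1], x$words_per_class[1],
              x$class_sizes[2], x$words_per_class[2]))
  invisible(x)
}

combo_labels <- function(k) {
  digits <- expand.grid(rep(list(0:2), k))[, k:1, drop = FALSE]
  apply(digits, 1L, paste, collapse = "")
}

new_contingency_table <- function(counts, k) {
  counts <- matrix(as.numeric(counts), nrow = 2)
  rownames(counts) <- c("control", "case")
  colnames(counts) <- combo_labels(k)
  structure(list(counts = counts, k = k,
                 row_marginals = rowSums(counts),
                 col_marginals = colSums(counts),
                 total = sum(counts)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency_table: order k=%d, |V|=%d genotype combinations, n=%g\n",
              x$k, ncol(x$counts), x$total))
  print(x$counts)
  invisible(x)
}

check_tuple <- function(tuple, m) {
  tuple <- as.integer(tuple)
  if (length(tuple) < 1L) stop("tuple must contain at least one SNP index")
  if (anyNA(tuple) || any(tuple < 1L) || any(tuple > m))
    stop(sprintf("SNP indices must lie in 1..%d", m))
  if (anyDuplicated(tuple)) stop("SNP indices in a tuple must be distinct")
  tuple
}

#' Build a k-way contingency table from a bit-sliced dataset
#'
#' Cross-tabulates phenotype class (rows) against the `3^k` genotype
#' combinations (columns) of a k-SNP tuple. Every cell is a single
#' AND+popcount pass over the packed class vectors. Columns are enumerated in
#' mixed-radix base-3 order with the first SNP of the tuple as the most
#' significant digit.
#'
#' @param ds a [binarise()]d dataset.
#' @param tuple distinct 1-based SNP indices (length k).
#' @return A `"contingency_table"`: a 2 x `3^k` count matrix with marginals.
#' @seealso [naive_contingency_table()] for the per-sample counting oracle.
#' @export
build_contingency_table <- function(ds, tuple) {
  stopifnot(inherits(ds, "bitsliced_dataset"))
  tuple <- check_tuple(tuple, ds$m)
  counts <- cpp_contingency(ds$bits0, ds$bits1,
                            ds$words_per_class[1], ds$words_per_class[2],
                            tuple - 1L, ds$m)
  new_contingency_table(counts, length(tuple))
}

#' Reference contingency table by direct per-sample iteration
#'
#' Counting oracle for [build_contingency_table()]: walks the samples one by
#' one, skips any sample missing a genotype at any SNP of the tuple, and
#' tallies the same 2 x `3^k` table in the same column order. Used to verify
#' the bitwise path; far slower, never used by the scan.
#'
#' @param gm a [genotype_matrix()].
#' @param tuple distinct 1-based SNP indices.
#' @return A `"contingency_table"`.
#' @export
naive_contingency_table <- function(gm, tuple) {
  stopifnot(inherits(gm, "genotype_matrix"))
  tuple <- check_tuple(tuple, n_snps(gm))
  k <- length(tuple)
  g <- gm$genotypes[tuple, , drop = FALSE]
  complete <- colSums(is.na(g)) == 0L
  # column index: first tuple SNP is the most significant base-3 digit
  weights <- 3^((k - 1):0)
  combo <- as.vector(weights %*% g[, complete, drop = FALSE])
  cls <- gm$phenotypes[complete]
  counts <- matrix(0, nrow = 2, ncol = 3^k)
  for (i in seq_along(combo))
    counts[cls[i] + 1L, combo[i] + 1L] <- counts[cls[i] + 1L, combo[i] + 1L] + 1
  new_contingency_table(counts, k)
}
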