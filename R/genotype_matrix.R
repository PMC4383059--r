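#' Construct a case/control genotype matrix
#'
#' Container for a case/control GWAS cohort: an `m` SNP x `n` sample matrix of
#' allele-dosage codes together with a binary phenotype vector. Genotypes are
#' coded as the number of copies of the variant allele (0, 1 or 2) with `NA`
#' for missing calls; phenotypes are 0 for controls and 1 for cases.
#'
#' @param genotypes integer matrix, `m` SNPs (rows) x `n` samples (columns),
#'   values in `{0, 1, 2, NA}`.
#' @param phenotypes integer vector of length `n`, values in `{0, 1}`.
#' @param snp_ids character vector of `m` unique SNP identifiers. Defaults to
#'   the matrix rownames, or `"snp1"..."snpm"`.
#' @param sample_ids character vector of `n` unique sample identifiers.
#'   Defaults to the matrix colnames, or `"S1"..."Sn"`.
#' @param require_both_classes if `TRUE`, require at least one case and one
#'   control. Simulators produce unlabelled (all-control) cohorts, so the
#'   check is also re-applied by every consumer that needs both classes.
#' @return An object of class `"genotype_matrix"`.
#' @examples
#' gm <- genotype_matrix(matrix(c(0L, 1L, 2L, 1L, 1L, 0L), nrow = 2,
#'                              byrow = TRUE),
#'                       phenotypes = c(0L, 0L, 1L))
#' gm
#' @export
genotype_matrix <- function(genotypes, phenotypes, snp_ids = NULL,
                            sample_ids = NULL, require_both_classes = TRUE) {
  if (!is.matrix(genotypes)) stop("`genotypes` must be a matrix")
  storage.mode(genotypes) <- "integer"
  m <- nrow(genotypes)
  n <- ncol(genotypes)
  if (m < 1L || n < 1L) stop("need at least one SNP and one sample")

  bad <- which(!(is.na(genotypes) | genotypes %in% 0:2))
  if (length(bad)) {
    r <- ((bad[1] - 1L) %% m) + 1L
    c <- ((bad[1] - 1L) %/% m) + 1L
    stop(sprintf("invalid genotype code %s at SNP row %d, sample column %d (must be 0, 1, 2 or NA)",
                 genotypes[bad[1]], r, c))
  }

  phenotypes <- as.integer(phenotypes)
  if (length(phenotypes) != n)
    stop(sprintf("phenotype length (%d) does not match sample count (%d)",
                 length(phenotypes), n))
  if (anyNA(phenotypes) || !all(phenotypes %in% 0:1))
    stop("phenotypes must be 0 (control) or 1 (case)")
  if (require_both_classes && (all(phenotypes == 0L) || all(phenotypes == 1L)))
    stop("need at least one case and at least one control")

  if (is.null(snp_ids)) snp_ids <- rownames(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) != m || anyDuplicated(snp_ids))
    stop("`snp_ids` must be unique and match the number of SNP rows")

  if (is.null(sample_ids)) sample_ids <- colnames(genotypes)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n || anyDuplicated(sample_ids))
    stop("`sample_ids` must be unique and match the number of sample columns")

  dimnames(genotypes) <- NULL
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 snp_ids = snp_ids, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Number of SNPs / samples in a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return integer count.
#' @export
n_snps <- function(gm) nrow(gm$genotypes)

#' @rdname n_snps
#' @export
n_samples <- function(gm) ncol(gm$genotypes)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d samples (%d cases, %d controls, %d missing calls)\n",
              n_snps(x), n_samples(x), sum(x$phenotypes == 1L),
              sum(x$phenotypes == 0L), sum(is.na(x$genotypes))))
  invisible(x)
}

# Subset samples, keeping SNP set fixed.  Internal.
subset_samples <- function(gm, keep) {
  genotype_matrix(gm$genotypes[, keep, drop = FALSE],
                  gm$phenotypes[keep],
                  snp_ids = gm$snp_ids,
                  sample_ids = gm$sample_ids[keep],
                  require_both_classes = FALSE)
}
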