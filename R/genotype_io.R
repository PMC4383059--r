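#' Read a genotype matrix and phenotype file
#'
#' Two on-disk dialects are supported:
#'
#' * `"native_tsv"`: tab/whitespace-delimited, one row per SNP, first column
#'   the SNP id, remaining columns genotype codes `0/1/2` with `NA`, `.` or
#'   `-9` for missing. An optional header row whose first field is `snp_id`
#'   carries sample ids. The phenotype file holds one `0`/`1` label per line,
#'   aligned with the sample columns.
#' * `"plink_raw"`: the PLINK `.raw` additive export — header line
#'   `FID IID PAT MAT SEX PHENOTYPE <snp...>`, one row per sample, phenotypes
#'   coded 1 (control) / 2 (case) and recoded to 0/1 on load. The matrix is
#'   transposed to the SNP-major orientation. The phenotype column of the
#'   `.raw` file is used; `phenotype_path` may be `NULL`.
#'
#' @param genotype_path path to the genotype file.
#' @param phenotype_path path to the phenotype file (ignored for
#'   `"plink_raw"`).
#' @param format `"native_tsv"` or `"plink_raw"`.
#' @return A [genotype_matrix()].
#' @seealso [write_genotype_matrix()]
#' @export
read_genotype_matrix <- function(genotype_path, phenotype_path = NULL,
                                 format = c("native_tsv", "plink_raw")) {
  format <- match.arg(format)
  if (!file.exists(genotype_path))
    stop("genotype file not found: ", genotype_path)
  if (format == "native_tsv") {
    if (is.null(phenotype_path) || !file.exists(phenotype_path))
      stop("phenotype file not found: ", phenotype_path)
    read_native_tsv(genotype_path, phenotype_path)
  } else {
    read_plink_raw(genotype_path)
  }
}

MISSING_TOKENS <- c("NA", ".", "-9")

parse_genotype_tokens <- function(tok, file, row_label, col_offset = 0L) {
  g <- rep(NA_integer_, length(tok))
  known <- tok %in% c("0", "1", "2")
  g[known] <- as.integer(tok[known])
  bad <- !known & !(tok %in% MISSING_TOKENS)
  if (any(bad)) {
    j <- which(bad)[1]
    stop(sprintf("%s: invalid genotype token \"%s\" at row %s, column %d (expected 0/1/2 or %s)",
                 file, tok[j], row_label, j + col_offset,
                 paste(MISSING_TOKENS, collapse = "/")))
  }
  g
}

read_native_tsv <- function(genotype_path, phenotype_path) {
  lines <- readLines(genotype_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(genotype_path, ": empty genotype file")
  fields <- strsplit(trimws(lines), "[ \t]+")

  sample_ids <- NULL
  if (fields[[1]][1] == "snp_id") {
    sample_ids <- fields[[1]][-1]
    fields <- fields[-1]
    if (!length(fields)) stop(genotype_path, ": header but no SNP rows")
  }

  ncol_expect <- length(fields[[1]])
  snp_ids <- vapply(fields, `[`, character(1), 1L)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) != ncol_expect)
      stop(sprintf("%s: row %d (%s) has %d fields, expected %d",
                   genotype_path, i, f[1], length(f), ncol_expect))
    parse_genotype_tokens(f[-1], genotype_path, row_label = f[1],
                          col_offset = 1L)
  })
  geno <- do.call(rbind, rows)

  ph_tok <- trimws(readLines(phenotype_path))
  ph_tok <- ph_tok[nzchar(ph_tok)]
  if (length(ph_tok) != ncol(geno))
    stop(sprintf("%s: %d phenotype lines but %d sample columns",
                 phenotype_path, length(ph_tok), ncol(geno)))
  if (!all(ph_tok %in% c("0", "1")))
    stop(sprintf("%s: phenotype values must be 0 or 1 (found \"%s\")",
                 phenotype_path, ph_tok[which(!ph_tok %in% c("0", "1"))[1]]))

  genotype_matrix(geno, as.integer(ph_tok), snp_ids = snp_ids,
                  sample_ids = sample_ids)
}

read_plink_raw <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop(path, ": .raw file needs a header and data rows")
  fields <- strsplit(trimws(lines), "[ \t]+")
  header <- fields[[1]]
  if (length(header) < 7L ||
      !identical(header[1:6], c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")))
    stop(path, ": not a PLINK .raw header (expected FID IID PAT MAT SEX PHENOTYPE ...)")
  snp_ids <- header[-(1:6)]
  m <- length(snp_ids)

  rows <- fields[-1]
  n <- length(rows)
  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  pheno <- integer(n)
  sample_ids <- character(n)
  for (i in seq_len(n)) {
    f <- rows[[i]]
    if (length(f) != m + 6L)
      stop(sprintf("%s: sample row %d has %d fields, expected %d",
                   path, i, length(f), m + 6L))
    sample_ids[i] <- f[2]
    ph <- f[6]
    if (ph == "2") pheno[i] <- 1L
    else if (ph == "1") pheno[i] <- 0L
    else stop(sprintf("%s: sample row %d has phenotype \"%s\" (expected 1=control, 2=case)",
                      path, i, ph))
    geno[i, ] <- parse_genotype_tokens(f[-(1:6)], path, row_label = f[2],
                                       col_offset = 6L)
  }
  genotype_matrix(t(geno), pheno, snp_ids = snp_ids, sample_ids = sample_ids)
}

#' Write a genotype matrix in the native TSV dialect
#'
#' Emits a genotype TSV (header `snp_id` + sample ids, one SNP per row,
#' missing as `NA`) and a phenotype file with one 0/1 label per line.
#' `read_genotype_matrix()` on the written pair reproduces the input exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param genotype_path,phenotype_path output paths.
#' @return `gm`, invisibly.
#' @export
write_genotype_matrix <- function(gm, genotype_path, phenotype_path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$genotypes
  body <- vapply(seq_len(nrow(g)), function(i) {
    tok <- as.character(g[i, ])
    tok[is.na(tok)] <- "NA"
    paste(c(gm$snp_ids[i], tok), collapse = "\t")
  }, character(1))
  header <- paste(c("snp_id", gm$sample_ids), collapse = "\t")
  writeLines(c(header, body), genotype_path)
  writeLines(as.character(gm$phenotypes), phenotype_path)
  invisible(gm)
}
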