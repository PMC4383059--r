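# Synthetic case/control GWAS data via haplotype-mosaic resampling.  Each
# simulated haplotype copies alleles from a panel of template haplotypes,
# switching template with a fixed per-site probability, which preserves local
# LD (nearby sites tend to be copied from the same template) while keeping
# the generator simple and fully reproducible.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Generate a reference haplotype panel
#'
#' Builds a synthetic panel of `h` binary template haplotypes over `m` sites.
#' Each site's variant-allele frequency is drawn uniformly from `maf_range`
#' and the panel alleles are independent Bernoulli draws at that frequency.
#' The panel stands in for a population reference (as real scans would use a
#' sequenced reference cohort) and is the template pool for
#' [simulate_genotypes()].
#'
#' @param h number of template haplotypes (`>= 2`). Smaller panels give
#'   stronger background LD in the mosaic.
#' @param m number of SNP sites.
#' @param maf_range frequency interval, a sub-interval of (0, 0.5].
#' @param recomb_rate per-site probability that a mosaic haplotype switches
#'   template (0 = whole-template copies, 1 = site-wise independent choice).
#' @param seed RNG seed for reproducibility.
#' @return A `"haplotype_panel"`: `h`, `m`, binary `alleles` matrix
#'   (`h x m`), per-site `freqs` and `recomb_rate`.
#' @export
generate_panel <- function(h, m, maf_range = c(0.05, 0.5),
                           recomb_rate = 0.01, seed = NULL) {
  if (h < 2) stop("need at least two template haplotypes")
  if (m < 1) stop("need at least one SNP site")
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("`maf_range` must be an interval within (0, 0.5]")
  if (recomb_rate < 0 || recomb_rate > 1)
    stop("`recomb_rate` must lie in [0, 1]")
  with_seed(seed, {
    freqs <- stats::runif(m, maf_range[1], maf_range[2])
    alleles <- matrix(stats::rbinom(h * m, 1L, rep(freqs, each = h)),
                      nrow = h, ncol = m)
    structure(list(h = as.integer(h), m = as.integer(m), alleles = alleles,
                   freqs = freqs, recomb_rate = recomb_rate),
              class = "haplotype_panel")
  })
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d sites, recomb_rate = %g\n",
              x$h, x$m, x$recomb_rate))
  invisible(x)
}

#' Simulate diploid genotypes as imperfect haplotype mosaics
#'
#' Each individual receives two independent mosaic haplotypes: a template is
#' chosen uniformly at the first site and re-chosen with probability
#' `recomb_rate` at each subsequent site, mimicking recombination while
#' preserving the panel's local allele structure. The genotype is the allele
#' sum (0/1/2). Phenotypes are initialised to all-control; label them with
#' [assign_phenotypes()] or directly.
#'
#' @param panel a [generate_panel()] result.
#' @param n number of diploid individuals.
#' @param seed RNG seed.
#' @param missing_rate fraction of genotype calls independently masked to
#'   missing (default 0).
#' @return An (unlabelled) [genotype_matrix()], `m` SNPs x `n` samples.
#' @export
simulate_genotypes <- function(panel, n, seed = NULL, missing_rate = 0) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (n < 1) stop("need at least one sample")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("`missing_rate` must lie in [0, 1)")
  h <- panel$h; m <- panel$m; r <- panel$recomb_rate
  with_seed(seed, {
    nh <- 2L * n
    hap <- matrix(0L, nrow = nh, ncol = m)
    tmpl <- sample.int(h, nh, replace = TRUE)
    hap[, 1L] <- panel$alleles[cbind(tmpl, 1L)]
    for (j in seq_len(m)[-1L]) {
      switch_ <- stats::runif(nh) < r
      if (any(switch_))
        tmpl[switch_] <- sample.int(h, sum(switch_), replace = TRUE)
      hap[, j] <- panel$alleles[cbind(tmpl, j)]
    }
    geno <- t(hap[seq_len(n), , drop = FALSE] +
              hap[n + seq_len(n), , drop = FALSE])
    storage.mode(geno) <- "integer"
    if (missing_rate > 0) {
      mask <- stats::runif(length(geno)) < missing_rate
      geno[mask] <- NA_integer_
    }
    genotype_matrix(geno, rep(0L, n), require_both_classes = FALSE)
  })
}

#' Penetrance model for embedding interaction effects
#'
#' Disease probability for each of the `3^k` genotype combinations at a
#' causal k-SNP tuple. Combinations left `NA` in `table` fall back to
#' `baseline`, so a pure-epistasis effect can be specified by raising only a
#' few combinations. Combination order matches the contingency-table column
#' order: base-3 with the first tuple SNP as the most significant digit.
#'
#' @param k tuple size.
#' @param table numeric vector of length `3^k` of case probabilities
#'   (`NA` entries replaced by `baseline`), or `NULL` for all-baseline
#'   (a null model).
#' @param baseline disease probability for unspecified combinations.
#' @return A `"penetrance_model"`.
#' @export
penetrance_model <- function(k, table = NULL, baseline = 0.1) {
  if (k < 1 || k != round(k)) stop("`k` must be a positive integer")
  if (baseline < 0 || baseline > 1) stop("`baseline` must be in [0, 1]")
  full <- rep(baseline, 3^k)
  if (!is.null(table)) {
    if (length(table) != 3^k)
      stop(sprintf("`table` must have 3^%d = %d entries", k, 3^k))
    keep <- !is.na(table)
    if (any(table[keep] < 0 | table[keep] > 1))
      stop("penetrance probabilities must lie in [0, 1]")
    full[keep] <- table[keep]
  }
  names(full) <- combo_labels(k)
  structure(list(k = as.integer(k), table = full, baseline = baseline),
            class = "penetrance_model")
}

#' Label simulated samples with case/control status
#'
#' Each sample becomes a case with the probability its genotype combination
#' at `tuple` receives under the penetrance model (samples missing a
#' genotype at the tuple use the baseline probability). When `target_cases`
#' is given, the labelled cohort is then down-sampled to exactly
#' `target_cases` cases and `target_controls` controls — the usual
#' case/control ascertainment — which requires simulating more samples than
#' the final cohort holds; an informative error is raised otherwise.
#'
#' @param gm a [genotype_matrix()] (typically from [simulate_genotypes()]).
#' @param model a [penetrance_model()] with `model$k == length(tuple)`.
#' @param tuple 1-based indices of the causal SNPs.
#' @param target_cases,target_controls cohort composition after
#'   down-sampling; `NULL` (default) keeps every sample with its Bernoulli
#'   label. `target_controls` defaults to `target_cases` (balanced design).
#' @param seed RNG seed.
#' @return A [genotype_matrix()] with phenotypes assigned (and fewer samples
#'   when down-sampling was requested).
#' @export
assign_phenotypes <- function(gm, model, tuple, target_cases = NULL,
                              target_controls = target_cases, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(model, "penetrance_model"))
  tuple <- check_tuple(tuple, n_snps(gm))
  if (length(tuple) != model$k)
    stop("tuple length must equal the penetrance model order k")
  k <- model$k
  g <- gm$genotypes[tuple, , drop = FALSE]
  weights <- 3^((k - 1):0)
  combo <- as.vector(weights %*% g) + 1L   # NA where any genotype missing
  p_case <- ifelse(is.na(combo), model$baseline, model$table[combo])

  with_seed(seed, {
    case <- stats::runif(n_samples(gm)) < p_case
    if (is.null(target_cases)) {
      out <- gm
      out$phenotypes <- as.integer(case)
      return(out)
    }
    if (sum(case) < target_cases || sum(!case) < target_controls)
      stop(sprintf(paste0("cannot assemble %d cases + %d controls from %d ",
                          "assigned cases and %d controls; simulate more ",
                          "samples (larger n)"),
                   target_cases, target_controls, sum(case), sum(!case)))
    sel <- sort(c(sample(which(case), target_cases),
                  sample(which(!case), target_controls)))
    out <- subset_samples(gm, sel)
    out$phenotypes <- as.integer(case[sel])
    out
  })
}

#' One-call synthetic GWAS cohort
#'
#' Convenience wrapper: panel, mosaic genotypes and (optionally) an embedded
#' k-way effect in one call. With no effect tuple, phenotypes are assigned
#' under the null (baseline probability for everyone), giving a calibration
#' dataset.
#'
#' @param m SNPs; @param n final sample count.
#' @param h panel haplotypes.
#' @param maf_range,recomb_rate,missing_rate see [generate_panel()] and
#'   [simulate_genotypes()].
#' @param effect_tuple optional causal SNP indices.
#' @param model [penetrance_model()] for the effect (or the null baseline).
#' @param balanced if `TRUE` (default) down-sample to n/2 cases and n/2
#'   controls, simulating `oversample` times more raw samples.
#' @param oversample raw-to-final sample ratio used before ascertainment.
#' @param seed RNG seed.
#' @return A labelled [genotype_matrix()].
#' @export
simulate_gwas <- function(m, n, h = 100, maf_range = c(0.05, 0.5),
                          recomb_rate = 0.01, missing_rate = 0,
                          effect_tuple = NULL,
                          model = penetrance_model(max(1L, length(effect_tuple)),
                                                   baseline = 0.5),
                          balanced = TRUE, oversample = 4, seed = 1) {
  panel <- generate_panel(h, m, maf_range, recomb_rate, seed = seed)
  n_raw <- if (balanced) ceiling(oversample * n) else n
  gm <- simulate_genotypes(panel, n_raw, seed = seed + 1L,
                           missing_rate = missing_rate)
  tuple <- if (is.null(effect_tuple)) seq_len(model$k) else effect_tuple
  assign_phenotypes(gm, model, tuple,
                    target_cases = if (balanced) floor(n / 2),
                    target_controls = if (balanced) ceiling(n / 2),
                    seed = seed + 2L)
}
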