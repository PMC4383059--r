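# Strong-scaling measurement of the scan and the runtime-projection
# arithmetic used to compare reported timings across hardware.

#' Speedup and efficiency from measured runtimes
#'
#' Strong-scaling bookkeeping: with `t_1` the single-worker runtime and
#' `t_N` the runtime on `N` workers on the same fixed problem, speedup is
#' `S = t_1 / t_N` and efficiency `E = S / N`.
#'
#' @param worker_counts worker counts, first entry 1 (the baseline).
#' @param runtimes wall times in seconds, same length.
#' @return A `"scaling_report"` data frame with columns `n_workers`,
#'   `runtime_seconds`, `speedup`, `efficiency`.
#' @examples
#' scaling_report(c(1, 4), c(120, 30))   # S = 4, E = 1
#' @export
scaling_report <- function(worker_counts, runtimes) {
  if (!length(worker_counts) || length(worker_counts) != length(runtimes))
    stop("`worker_counts` and `runtimes` must be nonempty and equal length")
  if (worker_counts[1] != 1)
    stop("the first worker count must be 1 (serial baseline)")
  if (any(runtimes <= 0)) stop("runtimes must be positive")
  s <- runtimes[1] / runtimes
  out <- data.frame(n_workers = worker_counts, runtime_seconds = runtimes,
                    speedup = s, efficiency = s / worker_counts)
  class(out) <- c("scaling_report", "data.frame")
  out
}

#' Measure strong scaling of the exhaustive scan
#'
#' Runs the identical scan (fixed data, fixed configuration — strong scaling)
#' at each worker count, repeating each measurement `reps` times and keeping
#' the minimum wall time to damp scheduler noise. Timing covers the full
#' in-memory pipeline — bit-slicing, scanning and the merge — but no file
#' I/O.
#'
#' @param gm the fixed input cohort.
#' @param config base [scan_config()]; its `n_workers` is overridden per run.
#' @param worker_counts counts to measure; first entry must be 1.
#' @param reps repetitions per count (minimum kept).
#' @return A [scaling_report()].
#' @export
measure_strong_scaling <- function(gm, config = scan_config(),
                                   worker_counts = c(1, 2, 4), reps = 3) {
  stopifnot(inherits(config, "scan_config"))
  if (!length(worker_counts) || worker_counts[1] != 1 ||
      any(worker_counts < 1))
    stop("`worker_counts` must start with 1 and be positive")
  avail <- parallel::detectCores()
  if (!is.na(avail) && any(worker_counts > avail))
    warning(sprintf("worker counts above the %d available cores; efficiency will be deflated",
                    avail))
  times <- vapply(worker_counts, function(np) {
    cfg <- config
    cfg$n_workers <- as.integer(np)
    min(vapply(seq_len(reps), function(r) {
      t0 <- proc.time()[["elapsed"]]
      invisible(run_scan(gm, cfg))
      proc.time()[["elapsed"]] - t0
    }, numeric(1)))
  }, numeric(1))
  scaling_report(worker_counts, times)
}

#' @export
print.scaling_report <- function(x, ...) {
  cat("strong scaling (fixed problem size):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# Reference configurations the projection formulas normalise to: a 1.1
# million SNP x 2000 sample pairwise scan on 262,144 CPU threads at 1.6 GHz,
# or 448 GPU threads at 1.22 GHz.
SCALING_REFERENCE <- list(
  cpu = list(n_snp = 1.1e6, n_sample = 2000, n_cores = 262144, f_clock = 1.6),
  gpu = list(n_snp = 1.1e6, n_sample = 2000, n_cores = 448, f_clock = 1.22))

#' Project a reported runtime onto the reference hardware and dataset
#'
#' Rescales a pairwise-scan runtime reported for one hardware/dataset
#' configuration to the common reference configuration, assuming runtime
#' proportional to the number of SNP pairs (quadratic in SNP count), linear
#' in sample count, and inversely proportional to core count and clock:
#' \deqn{t = t_{orig} \left(\frac{1.1\times10^6}{n_{SNP}}\right)^2
#'       \frac{2000}{n_{sample}} \frac{n_{cores}}{N^{ref}_{cores}}
#'       \frac{f_{clock}}{f^{ref}_{clock}}.}
#' The CPU reference is 262,144 threads at 1.6 GHz; the GPU reference 448
#' threads at 1.22 GHz.
#'
#' @param t_orig reported runtime, minutes.
#' @param n_snp,n_sample dataset size of the original study.
#' @param n_cores,f_clock threads and clock (GHz) of the original study.
#' @param platform `"cpu"` or `"gpu"` (selects the reference denominators).
#' @return Projected minutes (full precision; round only for presentation).
#' @examples
#' scale_reported_runtime(538, 5e5, 2000, 172, 2.40, "cpu")    # ~2.6 -> 3
#' @export
scale_reported_runtime <- function(t_orig, n_snp, n_sample, n_cores, f_clock,
                                   platform = c("cpu", "gpu")) {
  platform <- match.arg(tolower(platform), c("cpu", "gpu"))
  vals <- c(t_orig, n_snp, n_sample, n_cores, f_clock)
  if (anyNA(vals) || any(vals <= 0))
    stop("all scaling parameters must be positive")
  ref <- SCALING_REFERENCE[[platform]]
  t_orig * (ref$n_snp / n_snp)^2 * (ref$n_sample / n_sample) *
    (n_cores / ref$n_cores) * (f_clock / ref$f_clock)
}

#' Extrapolate a measured runtime to a higher interaction order
#'
#' Assuming perfectly linear scaling of runtime with the number of evaluated
#' tuples, a runtime measured at order `k_from` projects to order `k_to` by
#' the ratio `choose(m, k_to) / choose(m, k_from)`, computed as the exact
#' telescoping product `prod((m - j + 1) / j)` for `j` in
#' `(k_from+1)..k_to` to avoid forming astronomically large binomials.
#'
#' @param t_measured measured minutes at order `k_from`.
#' @param m SNP count.
#' @param k_from,k_to orders with `k_from < k_to <= m`.
#' @return Projected minutes.
#' @examples
#' extrapolate_higher_order(10, m = 4, k_from = 2, k_to = 3)   # 10 * 4/6
#' @export
extrapolate_higher_order <- function(t_measured, m, k_from, k_to) {
  if (t_measured <= 0) stop("`t_measured` must be positive")
  if (k_from != round(k_from) || k_to != round(k_to) || k_from < 1)
    stop("orders must be positive integers")
  if (k_from >= k_to)
    stop("`k_from` must be strictly smaller than `k_to`")
  if (k_to > m) stop(sprintf("interaction order k=%d exceeds SNP count m=%d",
                             k_to, m))
  j <- seq(k_from + 1, k_to)
  t_measured * prod((m - j + 1) / j)
}
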