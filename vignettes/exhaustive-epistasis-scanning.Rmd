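---
title: "Exhaustive bitwise scanning for SNP interactions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive bitwise scanning for SNP interactions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcan)
```

## The problem

Univariate association tests miss genetic effects that only appear jointly:
a pair (or triple) of SNPs whose combined genotype distribution differs
between cases and controls even though each SNP alone looks null. Testing
for such epistasis exhaustively means scoring every k-subset of the m SNPs —
`choose(m, k)` tuples, about 605 billion pairs for a 1.1-million-SNP study —
so the engineering problem is to make each test extremely cheap and to
spread the tests over parallel hardware with no coordination. episcan
implements that engine at desk scale: the same representation, statistic and
decomposition, exercised on cohorts a laptop can hold.

## Scoring one tuple

For a k-tuple of SNPs the data reduce to a 2 × 3^k contingency table: rows
are phenotype classes (control/case), columns the `|V| = 3^k` genotype
combinations. The table is scored with Pearson's chi-squared statistic

$$\chi^2 = \sum_{i}\sum_{j} \frac{(n_{ij} - E_{ij})^2}{E_{ij}},
\qquad E_{ij} = \frac{n_{i+}\, n_{+j}}{n},$$

with p-values from the upper tail of the chi-squared distribution with
`df = |V| − 1`. Two deliberate choices:

* **Empty columns.** For k = 3 and a few thousand samples, many of the 27
  genotype combinations are observed in no sample. Such columns contribute
  nothing to the sum (their expected counts are 0), but the degrees of
  freedom stay at `|V| − 1` — the nominal rule stated with the statistic.
  `chi_squared(ct, df_observed = TRUE)` exposes the conservative alternative
  (non-empty columns − 1); it is off by default.
* **No small-sample guards.** This is a *screening* statistic: no continuity
  correction and no minimum-expected-count rule. Tables containing any
  expected count below 5 are counted (`n_low_expected` on the scan object)
  so users can judge how often the asymptotic approximation is strained.

The statistic is pluggable: any function from a contingency table to a
score can be registered (`register_statistic()`) and named in the scan
configuration, so likelihood-ratio or heuristic screens drop in without
touching the engine. Thresholding applies to the score (`score >= t`, ties
kept) or to the p-value (`p <= t`), selectable in `scan_config()`.

## Bit-sliced counting

Each SNP is stored as three binary presence vectors, one per genotype
value, split by phenotype class and packed into 64-bit words (six vectors
per SNP). A cell of the contingency table — "how many controls carry
genotype combination (g₁…g_k)" — is then the popcount of the bitwise AND of
k packed vectors, a couple of hardware instructions per 64 samples. Cost
per table scales with `n/64` words, which is what makes the exhaustive scan
feasible; the kernel lives in compiled code (`src/bitscan.cpp`).

Missing genotypes set no bit in any of the three slices, so a sample
missing any genotype of the tuple silently drops out of every cell — i.e.
tuple-wise complete-case analysis. Consequently the table total `n` equals
the number of samples fully observed at the tuple, and the per-class
popcount sums equal the class size minus that class's missing count (both
are asserted by the test suite, cell-by-cell, against a per-sample counting
oracle, `naive_contingency_table()`).

Column order is fixed: mixed-radix base 3 with the first SNP of the tuple
as the most significant digit. The chi-squared value is invariant to that
choice, but reproducible output files require fixing one.

## Enumerating and partitioning the work

Tuples are addressed through the combinatorial number system: the strictly
decreasing tuple `(x_k > … > x_1)` (1-based at the R surface) has 0-based
linear index `sum_i choose(x_i − 1, i)`, a bijection onto
`[0, choose(m, k))` in colexicographic order. `rank_tuple()` /
`unrank_index()` implement the map and its greedy inverse; counts stay
exact in double precision below 2^53, far beyond any genome-scale pair or
triple count.

Work is split statically: worker `r` of `N` takes a contiguous interval of
the linear index space, `floor(total/N)` tuples plus one extra for the
first `total mod N` ranks, derivable from the rank alone. Each worker
unranks the start of its interval once and steps through successors —
no communication until a single merge of the kept results, which
concatenates per-rank output in rank order and is therefore already sorted
by linear index. The scan involves no randomness, so output is
bit-identical for any worker count; the suite asserts this for 1, 2, 3 and
8 workers. Workers are forked processes sharing the read-only encoded
dataset; within a worker, the interval is consumed in chunks (default 4096
tuples) to bound allocation.

## The synthetic cohort generator

The simulator emulates reference-panel mosaic resampling at toy scale.
`generate_panel()` draws per-site allele frequencies uniformly from a MAF
range and fills an `h × m` binary template panel; `simulate_genotypes()`
builds each haplotype by copying from a uniformly chosen template,
re-choosing the template at every site with probability `recomb_rate`, and
sums two haplotypes into a diploid genotype. Template runs of expected
length `1/recomb_rate` sites give correlated nearby sites (local LD) that
decays with distance — the one property of real panels the engine's tests
need. What it does **not** reproduce: empirical human LD block structure
and recombination hotspots, allele-frequency spectra, population
stratification, genotyping error correlated with plate or batch. Passing
detection tests on these cohorts therefore demonstrates the engine ranks a
strong embedded signal correctly, not that any real locus would reach
significance.

Effects are embedded through explicit penetrance tables
(`penetrance_model()`): the probability of disease for each of the 3^k
genotype combinations at a causal tuple, with a baseline for the rest.
This is an extension of the simulated-null setting — needed because
detection tests require signal — and `assign_phenotypes()` then performs
case/control ascertainment: label by the penetrance probabilities, then
down-sample to the requested numbers of cases and controls (the spec of a
fixed cohort with exactly the target composition requires simulating more
raw samples than the final cohort; `simulate_gwas(oversample =)` automates
the usual 4× margin).

Default study conditions mirror the 2000-sample cohorts typical of the
scanning literature; the test fixtures use 30–2000 SNPs so each suite run
stays in seconds to a couple of minutes.

## Null calibration and what it can show

On null cohorts (phenotype independent of all genotypes) each tuple's
p-value is marginally uniform — verified directly: on truly independent
tables the empirical distribution matches the uniform to KS distance ~0.01
at 4000 draws. But within one exhaustive scan, p-values of tuples *sharing
a SNP* are strongly dependent: a chance marginal association of one SNP
moves all m−1 pairs containing it. A one-sample Kolmogorov–Smirnov test,
which presumes independent draws, therefore rejects a single scan's pooled
p-values far above its nominal rate at any m — an intrinsic property of
overlapping tests, not a miscalibration. The calibration test in this
package accordingly applies KS per seed to the p-values of the scan's
*non-overlapping* tuples (pairs (1,2), (3,4), …), which are independent
draws, and additionally checks that the median of all pairwise p-values
sits near 0.5. Fixture: m = 60 SNPs, n = 2000 samples, recombination 0.5
(short template runs, so disjoint pairs are effectively independent of one
another).

## Benchmarking and runtime projection

Strong scaling fixes the problem and grows the worker count: speedup
`S = t₁/t_N`, efficiency `E = S/N`. `measure_strong_scaling()` repeats each
measurement (default 3×, minimum kept, damping scheduler noise) and times
the full in-memory pipeline — encoding, scan, merge — excluding file I/O.
The benchmark fixture is a 2000 SNP × 2000 sample keep-all pairwise scan
(~2 million tuples, a few seconds serial), and efficiency is judged at the
parallelism the host actually has (up to 4 workers): forked workers on
fewer physical cores cannot speed up a CPU-bound scan, so measuring
4-worker efficiency on a 1-core host would quantify oversubscription, not
the decomposition.

Published runtimes from other hardware are compared through a projection
that assumes runtime proportional to the number of pairs (quadratic in SNP
count), linear in samples, and inversely proportional to thread count and
clock: `scale_reported_runtime()` normalises to the common reference
configuration (262,144 CPU threads at 1.6 GHz, or 448 GPU threads at
1.22 GHz, both at 1.1 M SNPs × 2000 samples). `extrapolate_higher_order()`
projects a measured runtime from order k to k' by the tuple-count ratio
`choose(m, k')/choose(m, k)`, evaluated as the exact telescoping product
`prod((m − j + 1)/j)` — for pairs to triples, exactly `t (m − 2)/3`. These
are order-of-magnitude planning numbers; they ignore memory systems,
vector widths and implementation quality, and the package makes no claim
for them beyond the arithmetic.

## Numerical and interface choices

* SNP indices are 1-based in every user-facing structure (R convention);
  only the combinadic arithmetic is 0-based internally, and linear indices
  (which *are* combinadic values) are 0-based everywhere.
* Tuples are stored and printed in decreasing index order, matching the
  ranking condition `x_k > … > x_1`.
* Result files print scores and p-values with 10 significant digits;
  re-reading a results TSV reproduces the scan's values to that precision.
* A keep-all scan at large m can exhaust memory; `max_results` (default
  10⁷) aborts with a clear error rather than thrashing.
* Degenerate tables (an empty phenotype row after missingness) abort the
  scan naming the offending tuple — silent NA scores would poison a merge.

## Known limitations

Only the exhaustive screening stage is implemented: no second-stage robust
filter, no multiple-testing correction (the screen's threshold is a triage
knob, not an error-rate guarantee), no covariates, no X-chromosome or
haploid coding, no VCF/BGEN input (dosage-to-code conversion is ambiguous;
the native TSV and PLINK `.raw` dialects are exact). Workers are local
forked processes standing in for distributed ranks; the decomposition
contract (shared read-only data, private contiguous intervals, single
merge) is the same, but nothing here measures network communication.
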