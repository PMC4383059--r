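#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bit-sliced genotype storage: for each SNP, each genotype value in {0,1,2}
// and each phenotype class, a packed vector of 64-bit words over the samples
// of that class.  Layout inside the per-class raw buffer is SNP-major:
//   word index ((snp * 3 + genotype) * words + w)
// Padding bits beyond the class size are always zero, so popcounts over the
// whole buffer are exact sample counts.

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

static inline const uint64_t* slice_ptr(const uint64_t* base, int snp, int g,
                                        int words) {
  return base + (static_cast<size_t>(snp) * 3 + g) * words;
}

// [[Rcpp::export]]
List cpp_binarise(IntegerMatrix geno, IntegerVector pheno) {
  const int m = geno.nrow();
  const int n = geno.ncol();
  if (pheno.size() != n) stop("phenotype length does not match sample count");

  std::vector<int> idx0, idx1;
  idx0.reserve(n); idx1.reserve(n);
  for (int j = 0; j < n; ++j) {
    if (pheno[j] == 0) idx0.push_back(j);
    else if (pheno[j] == 1) idx1.push_back(j);
    else stop("phenotype values must be 0 or 1");
  }
  const int n0 = (int)idx0.size(), n1 = (int)idx1.size();
  const int w0 = (n0 + 63) / 64, w1 = (n1 + 63) / 64;

  RawVector b0((size_t)m * 3 * w0 * 8);  // zero-initialised
  RawVector b1((size_t)m * 3 * w1 * 8);
  uint64_t* p0 = reinterpret_cast<uint64_t*>(RAW(b0));
  uint64_t* p1 = reinterpret_cast<uint64_t*>(RAW(b1));

  for (int s = 0; s < m; ++s) {
    for (int p = 0; p < n0; ++p) {
      int g = geno(s, idx0[p]);
      if (g == NA_INTEGER) continue;  // missing: no bit set in any slice
      if (g < 0 || g > 2) stop("genotype codes must be 0, 1, 2 or NA");
      p0[((size_t)s * 3 + g) * w0 + p / 64] |= (uint64_t)1 << (p % 64);
    }
    for (int p = 0; p < n1; ++p) {
      int g = geno(s, idx1[p]);
      if (g == NA_INTEGER) continue;
      if (g < 0 || g > 2) stop("genotype codes must be 0, 1, 2 or NA");
      p1[((size_t)s * 3 + g) * w1 + p / 64] |= (uint64_t)1 << (p % 64);
    }
  }

  return List::create(_["bits0"] = b0, _["bits1"] = b1,
                      _["words0"] = w0, _["words1"] = w1,
                      _["n0"] = n0, _["n1"] = n1, _["m"] = m);
}

// Count samples of one class carrying a full genotype combination: AND the k
// relevant slices word by word and popcount the result.
static inline double count_combo(const uint64_t* base, int words,
                                 const int* tuple, const int* digits, int k) {
  double cnt = 0;
  for (int w = 0; w < words; ++w) {
    uint64_t acc = slice_ptr(base, tuple[0], digits[0], words)[w];
    for (int i = 1; i < k && acc; ++i)
      acc &= slice_ptr(base, tuple[i], digits[i], words)[w];
    cnt += popcount64(acc);
  }
  return cnt;
}

// Fill a 2 x 3^k table; column j decodes base-3 with the FIRST tuple entry as
// the most significant digit.
static void fill_table(const uint64_t* p0, const uint64_t* p1, int w0, int w1,
                       const int* tuple, int k, int ncomb, double* counts) {
  std::vector<int> digits(k);
  std::vector<int> pow3(k);
  pow3[k - 1] = 1;
  for (int i = k - 2; i >= 0; --i) pow3[i] = pow3[i + 1] * 3;
  for (int j = 0; j < ncomb; ++j) {
    for (int i = 0; i < k; ++i) digits[i] = (j / pow3[i]) % 3;
    counts[2 * j]     = count_combo(p0, w0, tuple, digits.data(), k);
    counts[2 * j + 1] = count_combo(p1, w1, tuple, digits.data(), k);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_contingency(RawVector bits0, RawVector bits1,
                              int words0, int words1,
                              IntegerVector tuple, int m) {
  const int k = tuple.size();
  if (k < 1) stop("tuple must have at least one SNP");
  int ncomb = 1;
  for (int i = 0; i < k; ++i) {
    if (tuple[i] < 0 || tuple[i] >= m) stop("SNP index out of range");
    ncomb *= 3;
  }
  const uint64_t* p0 = reinterpret_cast<const uint64_t*>(RAW(bits0));
  const uint64_t* p1 = reinterpret_cast<const uint64_t*>(RAW(bits1));
  NumericMatrix out(2, ncomb);
  fill_table(p0, p1, words0, words1, tuple.begin(), k, ncomb, out.begin());
  return out;
}

// ---- combinadic helpers (0-based SNP indices, colexicographic order) ----

static double binom_d(int x, int i) {
  if (x < i) return 0.0;
  double r = 1.0;
  for (int j = 1; j <= i; ++j) r = r * (x - i + j) / j;
  return std::floor(r + 0.5);
}

// Greedy decode: ascending combination a[0] < a[1] < ... < a[k-1].
static void unrank_asc(double index, int k, int* a) {
  double rem = index;
  for (int i = k; i >= 1; --i) {
    int x = i - 1;
    while (binom_d(x + 1, i) <= rem) ++x;
    rem -= binom_d(x, i);
    a[i - 1] = x;
  }
}

// Colex successor of an ascending combination.
static inline void next_asc(int* a, int k) {
  int i = 0;
  while (i + 1 < k && a[i] + 1 == a[i + 1]) ++i;
  ++a[i];
  for (int j = 0; j < i; ++j) a[j] = j;
}

// Scan tuples with linear index in [start, end): build each contingency
// table by AND+popcount, score with Pearson's chi-squared (columns with a
// zero marginal are skipped; df stays 3^k - 1), keep tuples passing the
// threshold.  Deterministic: depends only on the data and the interval.
// [[Rcpp::export]]
List cpp_scan_chi2(RawVector bits0, RawVector bits1, int words0, int words1,
                   int m, int k, double start, double end,
                   double threshold, bool p_space, double max_keep) {
  const uint64_t* p0 = reinterpret_cast<const uint64_t*>(RAW(bits0));
  const uint64_t* p1 = reinterpret_cast<const uint64_t*>(RAW(bits1));
  int ncomb = 1;
  for (int i = 0; i < k; ++i) ncomb *= 3;
  const int df = ncomb - 1;

  std::vector<int> a(k);          // ascending combination
  std::vector<int> tuple(k);      // descending (first = most significant)
  std::vector<double> counts(2 * ncomb);
  unrank_asc(start, k, a.data());

  std::vector<double> keep_idx, keep_score, keep_p;
  std::vector<int> keep_snps;
  double n_low_expected = 0;

  for (double idx = start; idx < end; ++idx) {
    for (int i = 0; i < k; ++i) tuple[i] = a[k - 1 - i];
    fill_table(p0, p1, words0, words1, tuple.data(), k, ncomb, counts.data());

    double r0 = 0, r1 = 0;
    for (int j = 0; j < ncomb; ++j) { r0 += counts[2 * j]; r1 += counts[2 * j + 1]; }
    double n = r0 + r1;
    if (n <= 0 || r0 <= 0 || r1 <= 0) {
      std::string t = "";
      for (int i = 0; i < k; ++i)
        t += (i ? "," : "") + std::to_string(tuple[i] + 1);
      stop("degenerate contingency table (empty phenotype row) for tuple (%s)",
           t.c_str());
    }

    double score = 0;
    bool low = false;
    for (int j = 0; j < ncomb; ++j) {
      double cs = counts[2 * j] + counts[2 * j + 1];
      if (cs <= 0) continue;
      double e0 = r0 * cs / n, e1 = r1 * cs / n;
      if (e0 < 5 || e1 < 5) low = true;
      double d0 = counts[2 * j] - e0, d1 = counts[2 * j + 1] - e1;
      score += d0 * d0 / e0 + d1 * d1 / e1;
    }
    if (low) n_low_expected += 1;

    bool keep;
    double pval = NA_REAL;
    if (p_space) {
      pval = R::pchisq(score, (double)df, 0, 0);
      keep = (pval <= threshold);
    } else {
      keep = (score >= threshold);
    }
    if (keep) {
      if ((double)keep_idx.size() >= max_keep)
        stop("kept-result cap exceeded (%g results); raise the threshold or max_results",
             max_keep);
      if (!p_space) pval = R::pchisq(score, (double)df, 0, 0);
      keep_idx.push_back(idx);
      keep_score.push_back(score);
      keep_p.push_back(pval);
      for (int i = 0; i < k; ++i) keep_snps.push_back(tuple[i]);
    }
    next_asc(a.data(), k);
  }

  const int nk = (int)keep_idx.size();
  IntegerMatrix snps(nk, k);
  for (int r = 0; r < nk; ++r)
    for (int i = 0; i < k; ++i) snps(r, i) = keep_snps[(size_t)r * k + i];

  return List::create(_["linear_index"] = NumericVector(keep_idx.begin(), keep_idx.end()),
                      _["score"] = NumericVector(keep_score.begin(), keep_score.end()),
                      _["p_value"] = NumericVector(keep_p.begin(), keep_p.end()),
                      _["snps"] = snps,
                      _["n_evaluated"] = end - start,
                      _["n_low_expected"] = n_low_expected);
}
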