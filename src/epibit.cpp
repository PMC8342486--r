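#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const int POW3[5] = {1, 3, 9, 27, 81};

// Combine the tuple's per-SNV byte vectors (pre-shifted by 2*(slot-1) bits)
// into one byte per sample with bitwise OR.  shifts[j] is the s x n_snv raw
// matrix at shift 2*j; tuple slot j reads column tup[j] of shifts[j].
static void combine_bytes(const List& shifts, const IntegerVector& tup,
                          std::vector<unsigned char>& comb) {
  const int m = tup.size();
  RawMatrix s0 = shifts[0];
  const int s = s0.nrow();
  comb.assign(s, 0);
  for (int j = 0; j < m; ++j) {
    RawMatrix sm = shifts[j];
    const Rbyte* col = &sm(0, tup[j]);
    for (int i = 0; i < s; ++i) comb[i] |= col[i];
  }
}

// Byte value of contingency-table row r: genotype digit of slot j sits at
// bits 2j..2j+1, row index is little-endian base 3 over the tuple slots.
static inline int row_to_byte(int r, int m) {
  int b = 0;
  for (int j = 0; j < m; ++j) {
    b |= (r % 3) << (2 * j);
    r /= 3;
  }
  return b;
}

// Histogram a combined byte vector and pick out the 3^m legal patterns.
// Any occupied bin outside the legal set is a corrupt encoding.
static void hist_to_column(const std::vector<unsigned char>& comb, int m,
                           std::vector<int>& col) {
  int hist[256] = {0};
  for (size_t i = 0; i < comb.size(); ++i) ++hist[comb[i]];
  const int rows = POW3[m];
  std::vector<char> legal(256, 0);
  col.assign(rows, 0);
  long tot = 0;
  for (int r = 0; r < rows; ++r) {
    const int b = row_to_byte(r, m);
    legal[b] = 1;
    col[r] = hist[b];
    tot += hist[b];
  }
  if (tot != (long)comb.size()) {
    for (int b = 0; b < 256; ++b)
      if (hist[b] > 0 && !legal[b])
        stop("invalid combined genotype byte: 0x%02x", b);
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_count_1v(List caseShifts, List ctrlShifts,
                           IntegerVector tuple0) {
  const int m = tuple0.size();
  const int rows = POW3[m];
  std::vector<unsigned char> comb;
  std::vector<int> colCase, colCtrl;
  combine_bytes(caseShifts, tuple0, comb);
  hist_to_column(comb, m, colCase);
  combine_bytes(ctrlShifts, tuple0, comb);
  hist_to_column(comb, m, colCtrl);
  IntegerMatrix out(rows, 2);
  for (int r = 0; r < rows; ++r) {
    out(r, 0) = colCase[r];
    out(r, 1) = colCtrl[r];
  }
  return out;
}

// 3-Vector reference method: per SNV, three 1-bit-per-sample indicator
// vectors packed in 64-bit words; each genotype combination is counted by
// AND-ing the m indicators and popcounting the result.
static void count_3v_cohort(const IntegerMatrix& g, std::vector<int>& out) {
  const int s = g.nrow(), m = g.ncol();
  const int W = (s + 63) / 64;
  std::vector<std::vector<std::vector<uint64_t> > > v(
      m, std::vector<std::vector<uint64_t> >(3, std::vector<uint64_t>(W, 0)));
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < s; ++i) {
      const int gt = g(i, j);
      if (gt < 0 || gt > 2) stop("genotype code outside {0,1,2}");
      v[j][gt][i >> 6] |= (uint64_t)1 << (i & 63);
    }
  const int rows = POW3[m];
  out.assign(rows, 0);
  std::vector<int> digit(m);
  for (int r = 0; r < rows; ++r) {
    int t = r;
    for (int j = 0; j < m; ++j) { digit[j] = t % 3; t /= 3; }
    long cnt = 0;
    for (int w = 0; w < W; ++w) {
      uint64_t x = v[0][digit[0]][w];
      for (int j = 1; j < m; ++j) x &= v[j][digit[j]][w];
      cnt += __builtin_popcountll(x);
    }
    out[r] = (int)cnt;
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_count_3v(IntegerMatrix genoCase, IntegerMatrix genoCtrl) {
  const int m = genoCase.ncol();
  const int rows = POW3[m];
  std::vector<int> colCase, colCtrl;
  count_3v_cohort(genoCase, colCase);
  count_3v_cohort(genoCtrl, colCtrl);
  IntegerMatrix out(rows, 2);
  for (int r = 0; r < rows; ++r) {
    out(r, 0) = colCase[r];
    out(r, 1) = colCtrl[r];
  }
  return out;
}

static inline double set_purity(double x, double y) {
  const double t = x + y;
  if (t <= 0) return 0.0;
  return (x * x + y * y) / (t * t);
}

// Exhaustive scan over `count` m-combinations in colex order starting at
// `startCombo` (0-based, strictly increasing).  Emits per tuple the SNV
// indices (1-based), beta, and (optionally) alpha looked up against the
// dense (m-1)-order beta cache.
// [[Rcpp::export]]
NumericMatrix cpp_search(List caseShifts, List ctrlShifts, int n,
                         IntegerVector startCombo, double count,
                         NumericVector betaCache, double beta0,
                         bool computeAlpha) {
  const int m = startCombo.size();
  const int rows = POW3[m];
  RawMatrix c0 = caseShifts[0];
  RawMatrix t0 = ctrlShifts[0];
  const int sCase = c0.nrow(), sCtrl = t0.nrow();
  const double nTot = (double)sCase + (double)sCtrl;
  const R_xlen_t nOut = (R_xlen_t)count;
  NumericMatrix out(nOut, m + 2);

  std::vector<int> a(startCombo.begin(), startCombo.end());
  std::vector<unsigned char> comb;
  std::vector<int> colCase, colCtrl;
  IntegerVector tup(m);

  // strides for dense cache indexing: sorted (m-1)-subset (i0<...) maps to
  // sum_k subset[k] * n^k
  std::vector<double> stride(m > 1 ? m - 1 : 1, 1.0);
  for (int k = 1; k < m - 1; ++k) stride[k] = stride[k - 1] * (double)n;

  for (R_xlen_t it = 0; it < nOut; ++it) {
    for (int j = 0; j < m; ++j) tup[j] = a[j];
    combine_bytes(caseShifts, tup, comb);
    hist_to_column(comb, m, colCase);
    combine_bytes(ctrlShifts, tup, comb);
    hist_to_column(comb, m, colCtrl);

    double beta = 0.0;
    for (int r = 0; r < rows; ++r) {
      const double x = colCase[r], y = colCtrl[r];
      if (x + y > 0) beta += ((x + y) / nTot) * set_purity(x, y);
    }

    double alpha = NA_REAL;
    if (computeAlpha) {
      double best = -1.0;
      if (m == 1) {
        best = beta0;
      } else {
        for (int drop = 0; drop < m; ++drop) {
          double idx = 0.0; int k = 0;
          for (int j = 0; j < m; ++j) {
            if (j == drop) continue;
            idx += (double)a[j] * stride[k];
            ++k;
          }
          const double sb = betaCache[(R_xlen_t)idx];
          if (sb > best) best = sb;
        }
      }
      alpha = beta - best;
      if (alpha < 0) {
        if (alpha > -1e-12) alpha = 0.0;
        else stop("internal consistency error: beta below best subset beta");
      }
    }

    for (int j = 0; j < m; ++j) out(it, j) = a[j] + 1;
    out(it, m) = beta;
    out(it, m + 1) = alpha;

    // colex successor
    if (it + 1 < nOut) {
      int i = 0;
      while (i < m) {
        const int lim = (i + 1 < m) ? a[i + 1] : n;
        if (a[i] + 1 < lim) break;
        ++i;
      }
      if (i == m) stop("ran past the last combination");
      ++a[i];
      for (int k = 0; k < i; ++k) a[k] = k;
    }
  }
  return out;
}
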