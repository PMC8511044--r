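#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Knight's O(n log n) Kendall tau-b between two numeric vectors.
// Returns NA when either vector is constant (denominator zero).
//
// Counting follows the standard decomposition:
//   tot  = n(n-1)/2 pairs
//   xtie = tied pairs in x, ytie = tied pairs in y, xytie = jointly tied
//   dis  = inversions of y after a stable sort by (x, y)
//   C - D = tot - xtie - ytie + xytie - 2*dis
//   tau_b = (C - D) / sqrt((tot - xtie) * (tot - ytie))

static long long merge_count(std::vector<double>& y, std::vector<double>& buf,
                             size_t lo, size_t hi) {
  if (hi - lo < 2) return 0;
  size_t mid = lo + (hi - lo) / 2;
  long long inv = merge_count(y, buf, lo, mid) + merge_count(y, buf, mid, hi);
  size_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[j] < y[i]) {           // strict: ties are not inversions
      inv += (long long)(mid - i);
      buf[k++] = y[j++];
    } else {
      buf[k++] = y[i++];
    }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi)  buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
  return inv;
}

static double tau_b_core(const double* x, const double* y, int n) {
  if (n < 2) return NA_REAL;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  long long tot = (long long)n * (n - 1) / 2;
  long long xtie = 0, xytie = 0;
  {
    long long run = 1, runxy = 1;
    for (int i = 1; i < n; ++i) {
      if (x[idx[i]] == x[idx[i - 1]]) {
        ++run;
        if (y[idx[i]] == y[idx[i - 1]]) ++runxy;
        else { xytie += runxy * (runxy - 1) / 2; runxy = 1; }
      } else {
        xtie += run * (run - 1) / 2; run = 1;
        xytie += runxy * (runxy - 1) / 2; runxy = 1;
      }
    }
    xtie += run * (run - 1) / 2;
    xytie += runxy * (runxy - 1) / 2;
  }

  std::vector<double> ys(n), buf(n);
  for (int i = 0; i < n; ++i) ys[i] = y[idx[i]];
  long long dis = merge_count(ys, buf, 0, n);  // ys now sorted

  long long ytie = 0;
  {
    long long run = 1;
    for (int i = 1; i < n; ++i) {
      if (ys[i] == ys[i - 1]) ++run;
      else { ytie += run * (run - 1) / 2; run = 1; }
    }
    ytie += run * (run - 1) / 2;
  }

  double den = std::sqrt((double)(tot - xtie)) * std::sqrt((double)(tot - ytie));
  if (den == 0.0) return NA_REAL;
  double num = (double)(tot - xtie - ytie + xytie) - 2.0 * (double)dis;
  return num / den;
}

// [[Rcpp::export(name = ".tau_b")]]
double tau_b(NumericVector x, NumericVector y) {
  if (x.size() != y.size()) stop("x and y must have equal length");
  return tau_b_core(REAL(x), REAL(y), x.size());
}

// Pairwise tau-b over the columns of m (features x observations).
// Each column's sort order and tie-pair count are precomputed once; per
// pair only the O(w log w) inversion count remains.
// [[Rcpp::export(name = ".tau_b_matrix")]]
NumericMatrix tau_b_matrix(NumericMatrix m) {
  int w = m.nrow(), n = m.ncol();
  NumericMatrix out(n, n);
  long long tot = (long long)w * (w - 1) / 2;

  std::vector<std::vector<int> > order(n, std::vector<int>(w));
  std::vector<long long> tie(n, 0);
  for (int c = 0; c < n; ++c) {
    const double* x = &m(0, c);
    std::vector<int>& o = order[c];
    for (int i = 0; i < w; ++i) o[i] = i;
    std::stable_sort(o.begin(), o.end(),
                     [&](int a, int b) { return x[a] < x[b]; });
    long long run = 1;
    for (int i = 1; i < w; ++i) {
      if (x[o[i]] == x[o[i - 1]]) ++run;
      else { tie[c] += run * (run - 1) / 2; run = 1; }
    }
    tie[c] += run * (run - 1) / 2;
  }

  std::vector<double> ys(w), buf(w);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    const double* x = &m(0, i);
    const std::vector<int>& o = order[i];
    for (int j = i + 1; j < n; ++j) {
      const double* y = &m(0, j);
      for (int k = 0; k < w; ++k) ys[k] = y[o[k]];
      // within runs of tied x, sort y ascending: removes spurious
      // inversions and exposes joint ties
      long long xytie = 0;
      int s = 0;
      while (s < w) {
        int e = s + 1;
        while (e < w && x[o[e]] == x[o[s]]) ++e;
        if (e - s > 1) {
          std::sort(ys.begin() + s, ys.begin() + e);
          long long run = 1;
          for (int k = s + 1; k < e; ++k) {
            if (ys[k] == ys[k - 1]) ++run;
            else { xytie += run * (run - 1) / 2; run = 1; }
          }
          xytie += run * (run - 1) / 2;
        }
        s = e;
      }
      long long dis = merge_count(ys, buf, 0, w);
      double den = std::sqrt((double)(tot - tie[i])) *
                   std::sqrt((double)(tot - tie[j]));
      double t;
      if (den == 0.0) t = NA_REAL;
      else t = ((double)(tot - tie[i] - tie[j] + xytie) - 2.0 * (double)dis) / den;
      out(i, j) = t;
      out(j, i) = t;
    }
  }
  return out;
}

// tau-b of each column of m against a single reference vector v.
// [[Rcpp::export(name = ".tau_b_vs_vector")]]
NumericVector tau_b_vs_vector(NumericMatrix m, NumericVector v) {
  if (m.nrow() != v.size()) stop("nrow(m) must equal length(v)");
  int n = m.ncol(), w = m.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tau_b_core(&m(0, i), REAL(v), w);
  return out;
}

// Trimmed window means: for each window (a list of 1-based row indices into
// expr) and each cell (column), drop the n_top largest values and average the
// rest. Ties among equal values cannot change the trimmed mean because
// exactly n_top values are dropped and equal values contribute equal sums.
// [[Rcpp::export(name = ".trimmed_window_means")]]
NumericMatrix trimmed_window_means(NumericMatrix expr, List windows, int n_top) {
  int n_cells = expr.ncol(), n_win = windows.size();
  NumericMatrix out(n_win, n_cells);
  std::vector<double> buf;
  for (int wi = 0; wi < n_win; ++wi) {
    IntegerVector members = windows[wi];
    int w = members.size();
    if (w <= n_top)
      stop("window smaller than n_top_exclude + 1");
    buf.resize(w);
    for (int ci = 0; ci < n_cells; ++ci) {
      double tot = 0.0;
      for (int g = 0; g < w; ++g) {
        buf[g] = expr(members[g] - 1, ci);
        tot += buf[g];
      }
      std::nth_element(buf.begin(), buf.begin() + n_top, buf.end(),
                       std::greater<double>());
      double toptot = 0.0;
      for (int g = 0; g < n_top; ++g) toptot += buf[g];
      out(wi, ci) = (tot - toptot) / (double)(w - n_top);
    }
  }
  return out;
}
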