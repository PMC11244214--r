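#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Zonal statistics over circular buffers on a regular grid.
// Cell (i, j) (1-based from R) has its center at
//   x = xmin + (j - 0.5) * res,  y = ymin + (i - 0.5) * res.
// A cell belongs to the buffer when the Euclidean distance from its center
// to the buffer center is <= radius (ties inclusive).

// [[Rcpp::export]]
NumericMatrix cpp_buffer_continuous(NumericMatrix grid,
                                    NumericVector cx, NumericVector cy,
                                    double radius,
                                    double xmin, double ymin, double res) {
  int n = cx.size();
  int ny = grid.nrow(), nx = grid.ncol();
  const double *g = REAL(grid);
  NumericMatrix out(n, 3);  // max, min, mean
  double r2 = radius * radius;
  for (int k = 0; k < n; ++k) {
    int j0 = (int)std::floor((cx[k] - radius - xmin) / res);
    int j1 = (int)std::floor((cx[k] + radius - xmin) / res);
    int i0 = (int)std::floor((cy[k] - radius - ymin) / res);
    int i1 = (int)std::floor((cy[k] + radius - ymin) / res);
    if (j0 < 0) j0 = 0; if (i0 < 0) i0 = 0;
    if (j1 > nx - 1) j1 = nx - 1; if (i1 > ny - 1) i1 = ny - 1;
    double vmax = R_NegInf, vmin = R_PosInf, sum = 0.0;
    long cnt = 0;
    for (int j = j0; j <= j1; ++j) {
      double dx = xmin + (j + 0.5) * res - cx[k];
      double rem = r2 - dx * dx;
      if (rem < 0) continue;
      const double *col = g + (size_t)j * ny;
      // cells of column j within the chord: |dy| <= sqrt(rem)
      double half = std::sqrt(rem);
      int ia = (int)std::ceil((cy[k] - half - ymin) / res - 0.5);
      int ib = (int)std::floor((cy[k] + half - ymin) / res - 0.5);
      if (ia < i0) ia = i0;
      if (ib > i1) ib = i1;
      for (int i = ia; i <= ib; ++i) {
        double v = col[i];
        if (ISNAN(v)) continue;
        if (v > vmax) vmax = v;
        if (v < vmin) vmin = v;
        sum += v;
        ++cnt;
      }
    }
    if (cnt == 0) {
      out(k, 0) = NA_REAL; out(k, 1) = NA_REAL; out(k, 2) = NA_REAL;
    } else {
      out(k, 0) = vmax; out(k, 1) = vmin; out(k, 2) = sum / cnt;
    }
  }
  return out;
}

// Modal (cat_max) and least-frequent (cat_min) code in the buffer.
// Only codes present in the buffer compete for cat_min; frequency ties are
// broken towards the smaller code for both statistics.

// [[Rcpp::export]]
NumericMatrix cpp_buffer_categorical(NumericMatrix grid,
                                     NumericVector cx, NumericVector cy,
                                     double radius,
                                     double xmin, double ymin, double res) {
  int n = cx.size();
  int ny = grid.nrow(), nx = grid.ncol();
  const double *g = REAL(grid);
  NumericMatrix out(n, 2);  // cat_max, cat_min
  double r2 = radius * radius;
  // code range from the grid (codes are small integers)
  int lo = 0, hi = -1;
  for (size_t t = 0; t < (size_t)ny * nx; ++t) {
    double v = g[t];
    if (ISNAN(v)) continue;
    int c = (int)std::lround(v);
    if (hi < lo) { lo = hi = c; }
    else { if (c < lo) lo = c; if (c > hi) hi = c; }
  }
  int span = (hi >= lo) ? hi - lo + 1 : 0;
  std::vector<long> freq(span > 0 ? span : 1);
  for (int k = 0; k < n; ++k) {
    int j0 = (int)std::floor((cx[k] - radius - xmin) / res);
    int j1 = (int)std::floor((cx[k] + radius - xmin) / res);
    int i0 = (int)std::floor((cy[k] - radius - ymin) / res);
    int i1 = (int)std::floor((cy[k] + radius - ymin) / res);
    if (j0 < 0) j0 = 0; if (i0 < 0) i0 = 0;
    if (j1 > nx - 1) j1 = nx - 1; if (i1 > ny - 1) i1 = ny - 1;
    std::fill(freq.begin(), freq.end(), 0L);
    long total = 0;
    for (int j = j0; j <= j1; ++j) {
      double dx = xmin + (j + 0.5) * res - cx[k];
      double rem = r2 - dx * dx;
      if (rem < 0) continue;
      const double *col = g + (size_t)j * ny;
      double half = std::sqrt(rem);
      int ia = (int)std::ceil((cy[k] - half - ymin) / res - 0.5);
      int ib = (int)std::floor((cy[k] + half - ymin) / res - 0.5);
      if (ia < i0) ia = i0;
      if (ib > i1) ib = i1;
      for (int i = ia; i <= ib; ++i) {
        double v = col[i];
        if (ISNAN(v)) continue;
        ++freq[(int)std::lround(v) - lo];
        ++total;
      }
    }
    if (total == 0) {
      out(k, 0) = NA_REAL; out(k, 1) = NA_REAL;
      continue;
    }
    int cmax = 0, cmin = 0;
    long fmax = -1, fmin = -1;
    for (int c = 0; c < span; ++c) {
      if (freq[c] == 0) continue;   // absent codes do not compete
      // ascending code order, strict comparisons keep the smaller code on ties
      if (freq[c] > fmax) { fmax = freq[c]; cmax = c + lo; }
      if (fmin < 0 || freq[c] < fmin) { fmin = freq[c]; cmin = c + lo; }
    }
    out(k, 0) = cmax;
    out(k, 1) = cmin;
  }
  return out;
}
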