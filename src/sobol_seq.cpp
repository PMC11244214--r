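#include <Rcpp.h>
using namespace Rcpp;

// Sobol' low-discrepancy sequence in base 2 with 30 output bits, built from
// primitive polynomials over GF(2) and initial direction numbers (Joe & Kuo
// 2008 tabulation, shipped as plain text with the package). Points follow the
// Gray-code ordering of Antonov & Saleev; an optional per-dimension digital
// shift (XOR with a random 30-bit integer) gives a seedable randomization
// that preserves the net structure.

static const int SOBOL_BITS = 30;

// [[Rcpp::export]]
NumericMatrix cpp_sobol_points(int n, int d,
                               IntegerVector poly, IntegerMatrix minit,
                               IntegerVector shift) {
  if (d > poly.size())
    stop("requested dimension exceeds the direction-number table");
  NumericMatrix out(n, d);
  double scale = 1.0 / (double)(1u << SOBOL_BITS);
  std::vector<unsigned int> v(SOBOL_BITS);
  for (int dim = 0; dim < d; ++dim) {
    unsigned int p = (unsigned int)poly[dim];
    if (p == 1u) {
      // first dimension: van der Corput in base 2
      for (int k = 0; k < SOBOL_BITS; ++k)
        v[k] = 1u << (SOBOL_BITS - 1 - k);
    } else {
      int s = 0;
      while ((p >> (s + 1)) != 0u) ++s;  // polynomial degree
      std::vector<unsigned int> m(SOBOL_BITS);
      for (int k = 0; k < s; ++k)
        m[k] = (unsigned int)minit(dim, k);
      for (int k = s; k < SOBOL_BITS; ++k) {
        unsigned int mk = m[k - s] ^ (m[k - s] << s);
        for (int i = 1; i < s; ++i) {
          unsigned int a = (p >> (s - i)) & 1u;  // coefficient of x^(s-i)
          if (a) mk ^= (m[k - i] << i);
        }
        m[k] = mk;
      }
      for (int k = 0; k < SOBOL_BITS; ++k)
        v[k] = m[k] << (SOBOL_BITS - 1 - k);
    }
    unsigned int x = 0u;
    unsigned int sh = (unsigned int)shift[dim];
    out(0, dim) = (double)(x ^ sh) * scale;
    for (int i = 1; i < n; ++i) {
      // index of the lowest set bit of i
      int c = 0;
      unsigned int ii = (unsigned int)i;
      while ((ii & 1u) == 0u) { ii >>= 1; ++c; }
      x ^= v[c];
      out(i, dim) = (double)(x ^ sh) * scale;
    }
  }
  return out;
}
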