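#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Average pairwise fuzzy membership grade of a set of delay vectors:
// phi = (1/V) * sum_i (1/(V-1)) * sum_{j != i} exp(-d_ij^2 / r)
// with d_ij the Chebyshev distance between rows i and j. The kernel is
// symmetric, so the double sum is twice the upper triangle.
// [[Rcpp::export]]
double cpp_membership_grade(NumericMatrix z, double r) {
  const int V = z.nrow();
  const int m = z.ncol();
  if (V < 2) return NA_REAL;
  // column-major copy for contiguous row access
  std::vector<double> buf((size_t)V * m);
  for (int l = 0; l < m; ++l)
    for (int i = 0; i < V; ++i)
      buf[(size_t)i * m + l] = z(i, l);
  long double acc = 0.0L;
  for (int i = 0; i < V - 1; ++i) {
    const double* zi = &buf[(size_t)i * m];
    for (int j = i + 1; j < V; ++j) {
      const double* zj = &buf[(size_t)j * m];
      double d = 0.0;
      for (int l = 0; l < m; ++l) {
        double a = std::fabs(zi[l] - zj[l]);
        if (a > d) d = a;
      }
      acc += std::exp(-(d * d) / r);
    }
  }
  long double denom = (long double)V * (V - 1);
  return (double)(2.0L * acc / denom);
}

// Grade of the pooled dimension-(m+1) set: rows are ordered in `p` channel
// blocks of `v_block` vectors each, row (c-1)*v_block + i extending base
// vector i by one sample of channel c. Pairs whose rows share the same base
// index i are self-pairs (their base distance is zero) and are excluded, so
// the grade is provably bounded above by the base-set grade.
// [[Rcpp::export]]
double cpp_membership_grade_grouped(NumericMatrix z, double r, int v_block) {
  const int V = z.nrow();
  const int m = z.ncol();
  if (V < 2 || v_block < 2) return NA_REAL;
  std::vector<double> buf((size_t)V * m);
  for (int l = 0; l < m; ++l)
    for (int i = 0; i < V; ++i)
      buf[(size_t)i * m + l] = z(i, l);
  long double acc = 0.0L;
  long long n_pairs = 0;
  for (int i = 0; i < V - 1; ++i) {
    const double* zi = &buf[(size_t)i * m];
    const int bi = i % v_block;
    for (int j = i + 1; j < V; ++j) {
      if (j % v_block == bi) continue;
      const double* zj = &buf[(size_t)j * m];
      double d = 0.0;
      for (int l = 0; l < m; ++l) {
        double a = std::fabs(zi[l] - zj[l]);
        if (a > d) d = a;
      }
      acc += std::exp(-(d * d) / r);
      ++n_pairs;
    }
  }
  if (n_pairs == 0) return NA_REAL;
  return (double)(acc / (long double)n_pairs);
}
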