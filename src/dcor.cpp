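#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Sample distance correlation, double-centered V-statistic form:
//   a_kl = |x_k - x_l|, ahat = a - rowmean - colmean + grandmean,
//   dcov^2 = mean(ahat * bhat), dvar^2 = mean(ahat^2),
//   dcorr = dcov / sqrt(dvar_a * dvar_b).
// Computed in two O(n^2) passes without materialising the matrices.

namespace {

void dist_row_sums(const double* x, int n, std::vector<double>& rs, double& total) {
  rs.assign(n, 0.0);
  total = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double d = std::fabs(x[i] - x[j]);
      rs[i] += d;
      rs[j] += d;
      total += 2.0 * d;
    }
  }
}

// accumulate sums of centered products for the pair (a, b)
void centered_products(const double* a, const double* b, int n,
                       const std::vector<double>& ra, double ga,
                       const std::vector<double>& rb, double gb,
                       double& sab, double& saa, double& sbb) {
  const double inv = 1.0 / n, inv2 = 1.0 / (static_cast<double>(n) * n);
  sab = saa = sbb = 0.0;
  for (int i = 0; i < n; ++i) {
    const double rai = ra[i] * inv, rbi = rb[i] * inv;
    for (int j = 0; j < n; ++j) {
      const double ah = std::fabs(a[i] - a[j]) - rai - ra[j] * inv + ga * inv2;
      const double bh = std::fabs(b[i] - b[j]) - rbi - rb[j] * inv + gb * inv2;
      sab += ah * bh;
      saa += ah * ah;
      sbb += bh * bh;
    }
  }
}

double assemble(double sab, double saa, double sbb) {
  if (saa <= 0.0 || sbb <= 0.0) return 0.0; // a degenerate (constant) marginal
  if (sab < 0.0) sab = 0.0;                 // numerical guard
  return std::sqrt(sab) / std::pow(saa * sbb, 0.25);
}

} // namespace

// [[Rcpp::export]]
double cpp_dcor(NumericVector a, NumericVector b) {
  const int n = a.size();
  std::vector<double> ra, rb;
  double ga, gb, sab, saa, sbb;
  dist_row_sums(a.begin(), n, ra, ga);
  dist_row_sums(b.begin(), n, rb, gb);
  centered_products(a.begin(), b.begin(), n, ra, ga, rb, gb, sab, saa, sbb);
  return assemble(sab, saa, sbb);
}

// distance correlation of every column of X with y
// [[Rcpp::export]]
NumericVector cpp_dcor_columns(NumericMatrix X, NumericVector y) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector out(p);
  std::vector<double> ry, ra, col(n);
  double gy;
  dist_row_sums(y.begin(), n, ry, gy);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) col[i] = X(i, j);
    double ga, sab, saa, sbb;
    dist_row_sums(&col[0], n, ra, ga);
    centered_products(&col[0], y.begin(), n, ra, ga, ry, gy, sab, saa, sbb);
    out[j] = assemble(sab, saa, sbb);
  }
  return out;
}
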