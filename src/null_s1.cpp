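#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of buf[0..n), destroys buffer order
static double med_inplace(std::vector<double>& buf) {
  const size_t n = buf.size();
  const size_t h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.end());
  double m = buf[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(buf.begin(), buf.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

static double mad_scaled(const std::vector<double>& v, double center,
                         double b, std::vector<double>& scratch) {
  scratch.resize(v.size());
  for (size_t i = 0; i < v.size(); ++i)
    scratch[i] = std::fabs(v[i] - center);
  return b * med_inplace(scratch);
}

// [[Rcpp::export(name = ".null_s1_cpp")]]
NumericVector null_s1_cpp(NumericVector pool, int n_iter, int n_x, int n_y,
                          double b) {
  const int np = pool.size();
  NumericVector out(n_iter);
  std::vector<double> x(n_x), y(n_y), bx, by, scratch;
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < n_x; ++i) {
      int j = (int)(unif_rand() * np); if (j == np) j = np - 1;
      x[i] = pool[j];
    }
    for (int i = 0; i < n_y; ++i) {
      int j = (int)(unif_rand() * np); if (j == np) j = np - 1;
      y[i] = pool[j];
    }
    bx = x; by = y;
    double mx = med_inplace(bx), my = med_inplace(by);
    double den = mad_scaled(x, mx, b, scratch) + mad_scaled(y, my, b, scratch);
    if (den == 0.0)
      out[it] = (mx == my) ? 0.0 : NA_REAL;  // degenerate scale
    else
      out[it] = std::fabs((mx - my) / den);
  }
  return out;
}
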