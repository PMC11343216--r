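#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Direct-form II transposed filtering through cascaded second-order sections.
// sos: n_sections x 6 matrix, rows (b0, b1, b2, a0, a1, a2) with a0 == 1.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x,
                          bool dc_init = false) {
  int ns = sos.nrow();
  int n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = 0.0, z2 = 0.0;
    if (dc_init && n > 0) {
      // steady state for constant input y[0]: removes the start-up transient
      double den = 1.0 + a1 + a2;
      if (den != 0.0) {
        double gdc = (b0 + b1 + b2) / den;
        double u = y[0], yo = gdc * u;
        z2 = b2 * u - a2 * yo;
        z1 = b1 * u - a1 * yo + z2;
      }
    }
    for (int i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}

// Centered moving maximum over a window of w samples (monotonic deque).
// [[Rcpp::export]]
NumericVector moving_max_cpp(NumericVector x, int w) {
  int n = x.size();
  NumericVector out(n);
  int half_l = (w - 1) / 2, half_r = w / 2;
  std::deque<int> dq;
  int hi = -1;
  for (int i = 0; i < n; ++i) {
    int want_hi = std::min(n - 1, i + half_r);
    while (hi < want_hi) {
      ++hi;
      while (!dq.empty() && x[dq.back()] <= x[hi]) dq.pop_back();
      dq.push_back(hi);
    }
    int lo = std::max(0, i - half_l);
    while (!dq.empty() && dq.front() < lo) dq.pop_front();
    out[i] = x[dq.front()];
  }
  return out;
}

// Centered moving average; window shrinks symmetrically near the edges.
// [[Rcpp::export]]
NumericVector moving_avg_cpp(NumericVector x, int w) {
  int n = x.size();
  NumericVector out(n);
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
  int half_l = (w - 1) / 2, half_r = w / 2;
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half_l);
    int hi = std::min(n - 1, i + half_r);
    out[i] = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
  }
  return out;
}

// Normalized cross-correlation of two equal-length, mean-subtracted traces at
// integer lags -max_lag..max_lag. Positive lag means y lags x. The
// normalization is lag-dependent (energies of the overlapping segments), so
// the peak location is not biased toward zero lag by overlap shrinkage.
// [[Rcpp::export]]
NumericVector xcorr_norm_cpp(NumericVector x, NumericVector y, int max_lag) {
  int n = x.size();
  std::vector<double> cx(n + 1, 0.0), cy(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cx[i + 1] = cx[i] + x[i] * x[i];
    cy[i + 1] = cy[i] + y[i] * y[i];
  }
  NumericVector out(2 * max_lag + 1);
  for (int l = -max_lag; l <= max_lag; ++l) {
    double acc = 0.0;
    int lo = std::max(0, l), hi = std::min(n, n + l);
    for (int i = lo; i < hi; ++i) acc += x[i - l] * y[i];
    double ex = cx[hi - l] - cx[lo - l];  // energy of x over the overlap
    double ey = cy[hi] - cy[lo];
    double norm = std::sqrt(ex * ey);
    out[l + max_lag] = norm > 0 ? acc / norm : 0.0;
  }
  return out;
}
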