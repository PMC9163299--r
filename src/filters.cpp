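// Sliding-window Hampel filter and topographic peak prominence.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static double median_of(std::vector<double> &w) {
  const size_t n = w.size();
  std::nth_element(w.begin(), w.begin() + n / 2, w.end());
  double hi = w[n / 2];
  if (n % 2 == 1) return hi;
  std::nth_element(w.begin(), w.begin() + n / 2 - 1, w.end());
  return 0.5 * (hi + w[n / 2 - 1]);
}

// Centered window of half-width h (truncated at the edges).  A sample is
// flagged when it deviates from the window median by more than
// nsigma * 1.4826 * MAD; flagged samples are replaced by the window median
// computed from the ORIGINAL samples (no in-place propagation).
// [[Rcpp::export(name = ".hampel_cpp")]]
List hampel_cpp(NumericVector x, int h, double nsigma) {
  const int n = x.size();
  NumericVector y = clone(x);
  std::vector<int> flagged;
  std::vector<double> w, dev;
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - h), hi = std::min(n - 1, i + h);
    w.assign(x.begin() + lo, x.begin() + hi + 1);
    double med = median_of(w);
    dev.resize(w.size());
    for (size_t j = 0; j < w.size(); ++j)
      dev[j] = std::fabs(x[lo + (int)j] - med);
    double mad = median_of(dev);
    // mad == 0 (locally near-constant window): any nonzero deviation from
    // the median is an artifact; a truly constant window flags nothing
    if (std::fabs(x[i] - med) > nsigma * 1.4826 * mad) {
      y[i] = med;
      flagged.push_back(i + 1);  // 1-based for R
    }
  }
  return List::create(_["y"] = y, _["flagged"] = wrap(flagged));
}

// Local maxima and their topographic prominence: height above the higher of
// the two bracketing minima, where each bracket extends to the nearest
// strictly higher sample (or the signal end).  Plateau maxima are reported at
// their first sample.
// [[Rcpp::export(name = ".peaks_cpp")]]
DataFrame peaks_cpp(NumericVector x) {
  const int n = x.size();
  std::vector<int> idx;
  std::vector<double> prom, height;
  for (int i = 1; i < n - 1; ++i) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) {
      // skip plateau continuation
      int j = i + 1;
      while (j < n && x[j] == x[i]) ++j;
      if (j < n && x[j] > x[i]) { i = j - 1; continue; }  // rising plateau
      // left base
      double lmin = x[i];
      for (int k = i - 1; k >= 0; --k) {
        if (x[k] > x[i]) break;
        lmin = std::min(lmin, x[k]);
      }
      double rmin = x[i];
      for (int k = j; k < n; ++k) {
        if (x[k] > x[i]) break;
        rmin = std::min(rmin, x[k]);
      }
      idx.push_back(i + 1);
      height.push_back(x[i]);
      prom.push_back(x[i] - std::max(lmin, rmin));
      i = j - 1;
    }
  }
  return DataFrame::create(_["index"] = wrap(idx), _["height"] = wrap(height),
                           _["prominence"] = wrap(prom));
}
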