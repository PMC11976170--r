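#include <Rcpp.h>
using namespace Rcpp;

// Local maxima filtered by topographic prominence.
//
// A candidate is a sample strictly greater than both neighbours; flat-topped
// plateaus contribute their (left-biased) middle sample. Prominence of a peak
// is its height minus the higher of the two interval minima found by scanning
// left/right until a strictly higher sample or the signal edge is reached.
// Returns 1-based indices of peaks with prominence >= min_prominence, sorted.
//
// [[Rcpp::export]]
IntegerVector cpp_find_peaks(NumericVector x, double min_prominence) {
  int n = x.size();
  std::vector<int> keep;
  if (n < 3) return wrap(keep);

  std::vector<int> cand;
  int i = 1;
  while (i < n - 1) {
    if (x[i - 1] < x[i]) {
      int ahead = i + 1;
      while (ahead < n - 1 && x[ahead] == x[i]) ahead++;
      if (x[ahead] < x[i]) {
        cand.push_back((i + (ahead - 1)) / 2);
        i = ahead;
        continue;
      }
      i = ahead;
      continue;
    }
    i++;
  }

  for (size_t c = 0; c < cand.size(); c++) {
    int p = cand[c];
    double peak = x[p];
    double lmin = peak, rmin = peak;
    for (int j = p - 1; j >= 0; j--) {
      if (x[j] > peak) break;
      if (x[j] < lmin) lmin = x[j];
    }
    for (int j = p + 1; j < n; j++) {
      if (x[j] > peak) break;
      if (x[j] < rmin) rmin = x[j];
    }
    double prom = peak - std::max(lmin, rmin);
    if (prom >= min_prominence) keep.push_back(p + 1);
  }
  return wrap(keep);
}
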