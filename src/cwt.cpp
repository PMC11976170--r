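#include <Rcpp.h>
using namespace Rcpp;

// Mexican-hat (Ricker) mother wavelet, unit sigma, L2-normalised at scale a:
//   psi_a[k] = psi(k / a) / sqrt(a),  psi(t) = 2/(sqrt(3) pi^{1/4}) (1 - t^2) exp(-t^2/2)
// Support truncated at |t| <= 5 sigma.
static std::vector<double> ricker_at_scale(double a) {
  int h = (int)std::ceil(5.0 * a);
  std::vector<double> w(2 * h + 1);
  double norm = 2.0 / (std::sqrt(3.0) * std::pow(M_PI, 0.25)) / std::sqrt(a);
  for (int k = -h; k <= h; k++) {
    double t = k / a;
    w[k + h] = norm * (1.0 - t * t) * std::exp(-t * t / 2.0);
  }
  return w;
}

// |CWT| of each row of X at the given scales, evaluated only at the time
// columns tidx (0-based sample indices; zero padding at the edges), then
// optionally averaged over pool x pool blocks. Returns an array of dimension
// (nrow(X), n_scales / pool, n_tidx / pool); pool = 1 keeps full resolution.
//
// [[Rcpp::export]]
NumericVector cpp_cwt_stack(NumericMatrix X, NumericVector scales,
                            IntegerVector tidx, int pool) {
  int n = X.nrow(), L = X.ncol();
  int S = scales.size(), T = tidx.size();
  if (pool < 1) stop("pool must be >= 1");
  if (S % pool != 0 || T % pool != 0)
    stop("scale and time dimensions must be divisible by pool");
  int So = S / pool, To = T / pool;

  std::vector<std::vector<double> > wav(S);
  for (int s = 0; s < S; s++) wav[s] = ricker_at_scale(scales[s]);

  NumericVector out(double(n) * So * To);
  out.attr("dim") = IntegerVector::create(n, So, To);
  std::vector<double> row(S * T);

  for (int r = 0; r < n; r++) {
    const double* x = &X(r, 0); // column-major: X(r, j) = x[j * n]
    for (int s = 0; s < S; s++) {
      const std::vector<double>& w = wav[s];
      int h = ((int)w.size() - 1) / 2;
      for (int j = 0; j < T; j++) {
        int c = tidx[j];
        int k0 = std::max(-h, -c), k1 = std::min(h, L - 1 - c);
        double acc = 0.0;
        const double* wp = &w[h];
        for (int k = k0; k <= k1; k++) acc += x[(size_t)(c + k) * n] * wp[k];
        row[s * T + j] = std::fabs(acc);
      }
    }
    // block-average into the output
    for (int so = 0; so < So; so++) {
      for (int to = 0; to < To; to++) {
        double acc = 0.0;
        for (int ps = 0; ps < pool; ps++)
          for (int pt = 0; pt < pool; pt++)
            acc += row[(so * pool + ps) * T + (to * pool + pt)];
        out[(size_t)r + (size_t)n * ((size_t)so + (size_t)So * to)] = acc / (pool * pool);
      }
    }
  }
  return out;
}
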