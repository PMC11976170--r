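#include <Rcpp.h>
using namespace Rcpp;

// Trees are passed as flat 0-based arrays: childL/childR (-1 at leaves),
// splitvar (0-based feature index, undefined at leaves), splitval with the
// rule x[splitvar] <= splitval -> left child.

// Route weighted observations down one tree, accumulating per-node total
// weight ("cover") and per-class weighted counts. Used to attach covers to
// ranger trees (from in-bag counts) and to recompute impurity decreases.
//
// [[Rcpp::export]]
List cpp_tree_route(IntegerVector childL, IntegerVector childR,
                    IntegerVector splitvar, NumericVector splitval,
                    NumericMatrix X, NumericVector w, IntegerVector y,
                    int nclass) {
  int nn = childL.size(), n = X.nrow();
  NumericVector cover(nn);
  NumericMatrix counts(nn, nclass);
  for (int i = 0; i < n; i++) {
    if (w[i] <= 0) continue;
    int node = 0;
    for (;;) {
      cover[node] += w[i];
      counts(node, y[i]) += w[i];
      if (childL[node] < 0) break;
      node = (X(i, splitvar[node]) <= splitval[node]) ? childL[node]
                                                      : childR[node];
    }
  }
  return List::create(_["cover"] = cover, _["counts"] = counts);
}

// ---------------------------------------------------------------------------
// Path-dependent tree Shapley attributions (the polynomial-time algorithm for
// tree ensembles). The path records, per encountered feature, the fraction of
// "zero" (feature missing, split followed by cover proportions) and "one"
// (feature present, split followed by x) paths, plus permutation weights.

struct PathEl {
  int d;      // feature index (-1 for the root dummy element)
  double z;   // zero fraction
  double o;   // one fraction
  double w;   // permutation weight
};

static void extend_path(std::vector<PathEl>& m, int& len, double pz, double po,
                        int pi) {
  m[len].d = pi;
  m[len].z = pz;
  m[len].o = po;
  m[len].w = (len == 0) ? 1.0 : 0.0;
  for (int i = len - 1; i >= 0; i--) {
    m[i + 1].w += po * m[i].w * (i + 1) / (double)(len + 1);
    m[i].w = pz * m[i].w * (len - i) / (double)(len + 1);
  }
  len++;
}

static void unwind_path(std::vector<PathEl>& m, int& len, int idx) {
  int D = len - 1;  // index of the last path element
  double o = m[idx].o, z = m[idx].z;
  double n = m[D].w;
  for (int i = D - 1; i >= 0; i--) {
    if (o != 0) {
      double t = m[i].w;
      m[i].w = n * (D + 1) / ((i + 1) * o);
      n = t - m[i].w * z * (D - i) / (double)(D + 1);
    } else {
      m[i].w = m[i].w * (D + 1) / (z * (D - i));
    }
  }
  for (int i = idx; i < D; i++) {
    m[i].d = m[i + 1].d;
    m[i].z = m[i + 1].z;
    m[i].o = m[i + 1].o;
  }
  len--;
}

// Sum of permutation weights after unwinding element idx (without mutating m).
static double unwound_sum(const std::vector<PathEl>& m, int len, int idx) {
  int D = len - 1;
  double o = m[idx].o, z = m[idx].z;
  double n = m[D].w, total = 0.0;
  if (o != 0) {
    for (int i = D - 1; i >= 0; i--) {
      double tmp = n / ((i + 1) * o);
      total += tmp;
      n = m[i].w - tmp * z * (D - i);
    }
  } else {
    for (int i = D - 1; i >= 0; i--)
      total += m[i].w / (z * (D - i));
  }
  return total * (D + 1);
}

struct TreeRef {
  const int *childL, *childR, *splitvar;
  const double *splitval, *cover;
  const NumericMatrix* leafval;  // nodes x nclass
  const NumericMatrix* X;
  double* phi;  // n x p x nclass
  int n, p, nclass, row;
};

static void recurse(TreeRef& T, int node, std::vector<PathEl> m, int len,
                    double pz, double po, int pi) {
  m.resize(len + 1);
  extend_path(m, len, pz, po, pi);
  if (T.childL[node] < 0) {
    for (int i = 1; i < len; i++) {
      double w = unwound_sum(m, len, i);
      double scale = w * (m[i].o - m[i].z);
      for (int k = 0; k < T.nclass; k++) {
        T.phi[(size_t)T.row + (size_t)T.n * ((size_t)m[i].d +
              (size_t)T.p * k)] += scale * (*T.leafval)(node, k);
      }
    }
    return;
  }
  int f = T.splitvar[node];
  int hot, cold;
  if ((*T.X)(T.row, f) <= T.splitval[node]) {
    hot = T.childL[node];
    cold = T.childR[node];
  } else {
    hot = T.childR[node];
    cold = T.childL[node];
  }
  double iz = 1.0, io = 1.0;
  for (int i = 1; i < len; i++) {
    if (m[i].d == f) {
      iz = m[i].z;
      io = m[i].o;
      unwind_path(m, len, i);
      break;
    }
  }
  double rj = T.cover[node];
  recurse(T, hot, m, len, iz * T.cover[hot] / rj, io, f);
  recurse(T, cold, m, len, iz * T.cover[cold] / rj, 0.0, f);
}

// Shapley attributions of one tree for all rows of X and all classes.
// leafval holds per-node outputs (rows aligned with the node arrays; only
// leaf rows are read). Returns list(phi = n x p x nclass array,
// base = per-class cover-weighted expectation of the tree output).
//
// [[Rcpp::export]]
List cpp_treeshap(IntegerVector childL, IntegerVector childR,
                  IntegerVector splitvar, NumericVector splitval,
                  NumericVector cover, NumericMatrix leafval,
                  NumericMatrix X) {
  int n = X.nrow(), p = X.ncol(), nn = childL.size();
  int nclass = leafval.ncol();
  NumericVector phi((size_t)n * p * nclass);
  phi.attr("dim") = IntegerVector::create(n, p, nclass);

  NumericVector base(nclass);
  double root = cover[0];
  for (int j = 0; j < nn; j++) {
    if (childL[j] < 0) {
      for (int k = 0; k < nclass; k++)
        base[k] += cover[j] / root * leafval(j, k);
    }
  }

  TreeRef T;
  T.childL = &childL[0];
  T.childR = &childR[0];
  T.splitvar = &splitvar[0];
  T.splitval = &splitval[0];
  T.cover = &cover[0];
  T.leafval = &leafval;
  T.X = &X;
  T.phi = &phi[0];
  T.n = n;
  T.p = p;
  T.nclass = nclass;

  std::vector<PathEl> m;
  for (int r = 0; r < n; r++) {
    T.row = r;
    recurse(T, 0, m, 0, 1.0, 1.0, -1);
  }
  return List::create(_["phi"] = phi, _["base"] = base);
}
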