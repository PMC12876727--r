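#include <Rcpp.h>
using namespace Rcpp;

// Small dense solvers for the per-cell weighted least squares: the design
// has ~10 columns, so an in-place Cholesky on the normal equations is both
// adequate and fast at mass-univariate scale (thousands of cells).

namespace {

bool chol_solve(std::vector<double> &A, std::vector<double> &b, int p) {
  // A is p x p symmetric positive definite (column-major), b length p.
  for (int j = 0; j < p; ++j) {
    double d = A[j + j * p];
    for (int k = 0; k < j; ++k) d -= A[j + k * p] * A[j + k * p];
    if (d <= 1e-12) return false;
    d = std::sqrt(d);
    A[j + j * p] = d;
    for (int i = j + 1; i < p; ++i) {
      double s = A[i + j * p];
      for (int k = 0; k < j; ++k) s -= A[i + k * p] * A[j + k * p];
      A[i + j * p] = s / d;
    }
  }
  for (int i = 0; i < p; ++i) {            // forward solve L y = b
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= A[i + k * p] * b[k];
    b[i] = s / A[i + i * p];
  }
  for (int i = p - 1; i >= 0; --i) {       // back solve L' x = y
    double s = b[i];
    for (int k = i + 1; k < p; ++k) s -= A[k + i * p] * b[k];
    b[i] = s / A[i + i * p];
  }
  return true;
}

void wls(const double *X, const double *y, const double *w, int n, int p,
         std::vector<double> &beta, std::vector<double> &A,
         std::vector<double> &b) {
  std::fill(A.begin(), A.end(), 0.0);
  std::fill(b.begin(), b.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    double wi = w ? w[i] : 1.0;
    for (int j = 0; j < p; ++j) {
      double xij = X[i + j * n] * wi;
      b[j] += xij * y[i];
      for (int k = j; k < p; ++k) A[k + j * p] += xij * X[i + k * n];
    }
  }
  for (int j = 0; j < p; ++j)
    for (int k = j + 1; k < p; ++k) A[j + k * p] = A[k + j * p];
  beta = b;
  chol_solve(A, beta, p);
}

double mad_scale(std::vector<double> &r) {
  std::vector<double> a(r.size());
  for (size_t i = 0; i < r.size(); ++i) a[i] = std::fabs(r[i]);
  size_t m = a.size() / 2;
  std::nth_element(a.begin(), a.begin() + m, a.end());
  double med = a[m];
  if (a.size() % 2 == 0) {
    std::nth_element(a.begin(), a.begin() + m - 1, a.begin() + m);
    med = 0.5 * (med + a[m - 1]);
  }
  return med / 0.6744898;  // consistent with the normal
}

} // namespace

// Iteratively reweighted least squares with Huber weights, fit
// independently at every cell (channel x timepoint). Y is n x ncells,
// X is n x p (intercept included by the caller). Cells that do not reach
// the coefficient tolerance within maxit fall back to ordinary least
// squares and are flagged.
// [[Rcpp::export]]
List huber_irls_cpp(NumericMatrix X, NumericMatrix Y, double tuning,
                    int maxit, double tol) {
  const int n = X.nrow(), p = X.ncol(), m = Y.ncol();
  NumericMatrix beta(p, m);
  IntegerVector iters(m);
  LogicalVector converged(m);
  std::vector<double> A(p * p), bvec(p), bcur(p), bprev(p), w(n), r(n);
  const double *Xp = X.begin();
  for (int c = 0; c < m; ++c) {
    const double *y = &Y(0, c);
    std::vector<double> ols;
    wls(Xp, y, nullptr, n, p, ols, A, bvec);
    bcur = ols;
    bool ok = false;
    int it = 0;
    for (; it < maxit; ++it) {
      for (int i = 0; i < n; ++i) {
        double fit = 0.0;
        for (int j = 0; j < p; ++j) fit += Xp[i + j * n] * bcur[j];
        r[i] = y[i] - fit;
      }
      double s = mad_scale(r);
      if (s < 1e-12) { ok = true; break; }  // (near-)exact fit
      double k = tuning * s;
      for (int i = 0; i < n; ++i) {
        double ar = std::fabs(r[i]);
        w[i] = ar <= k ? 1.0 : k / ar;
      }
      bprev = bcur;
      wls(Xp, y, w.data(), n, p, bcur, A, bvec);
      double delta = 0.0;
      for (int j = 0; j < p; ++j)
        delta = std::max(delta, std::fabs(bcur[j] - bprev[j]));
      if (delta < tol) { ok = true; ++it; break; }
    }
    if (!ok) bcur = ols;
    for (int j = 0; j < p; ++j) beta(j, c) = bcur[j];
    iters[c] = it;
    converged[c] = ok;
  }
  return List::create(_["beta"] = beta, _["iterations"] = iters,
                      _["converged"] = converged);
}

namespace {

// Connected components over suprathreshold cells. Cells are indexed
// ch + nch * t; neighbours are the same channel at t +/- 1 and spatially
// adjacent channels at the same t. Positive and negative exceedances
// cluster separately; mass is the sum of |t| within a cluster.
void find_clusters(const std::vector<double> &stat, double thr, int nch,
                   int nt, const LogicalMatrix &adj,
                   std::vector<int> &labels, std::vector<double> &masses) {
  const int m = nch * nt;
  labels.assign(m, 0);
  masses.clear();
  std::vector<int> stack;
  int next = 0;
  for (int c0 = 0; c0 < m; ++c0) {
    if (labels[c0] != 0 || std::fabs(stat[c0]) <= thr) continue;
    int sgn = stat[c0] > 0 ? 1 : -1;
    ++next;
    double mass = 0.0;
    stack.clear();
    stack.push_back(c0);
    labels[c0] = next;
    while (!stack.empty()) {
      int c = stack.back();
      stack.pop_back();
      mass += std::fabs(stat[c]);
      int ch = c % nch, t = c / nch;
      auto visit = [&](int cc) {
        if (labels[cc] == 0 && std::fabs(stat[cc]) > thr &&
            (stat[cc] > 0 ? 1 : -1) == sgn) {
          labels[cc] = next;
          stack.push_back(cc);
        }
      };
      if (t > 0) visit(c - nch);
      if (t < nt - 1) visit(c + nch);
      for (int ch2 = 0; ch2 < nch; ++ch2)
        if (ch2 != ch && adj(ch, ch2)) visit(ch2 + nch * t);
    }
    masses.push_back(mass);
  }
}

void tstat(const NumericMatrix &B, const std::vector<double> &flip,
           std::vector<double> &out) {
  const int ns = B.nrow(), m = B.ncol();
  for (int c = 0; c < m; ++c) {
    double s = 0.0, ss = 0.0;
    for (int i = 0; i < ns; ++i) {
      double v = flip[i] * B(i, c);
      s += v;
      ss += v * v;
    }
    double mean = s / ns;
    double var = (ss - ns * mean * mean) / (ns - 1);
    out[c] = var > 0 ? mean / std::sqrt(var / ns) : 0.0;
  }
}

} // namespace

// One-sample cluster test with a sign-flip permutation null. B holds one
// regressor's betas, subjects x (nch*nt) with cells indexed ch + nch*t.
// Returns the observed cluster labels, per-cluster signed masses and
// sign, and the permutation distribution of the maximum cluster mass.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List cluster_perm_cpp(NumericMatrix B, int nch, int nt, LogicalMatrix adj,
                      double t_thresh, int nperm) {
  const int ns = B.nrow(), m = B.ncol();
  std::vector<double> flip(ns, 1.0), stat(m);
  std::vector<int> labels;
  std::vector<double> masses;
  tstat(B, flip, stat);
  find_clusters(stat, t_thresh, nch, nt, adj, labels, masses);

  // cluster signs from the observed statistic
  int ncl = masses.size();
  std::vector<int> signs(ncl, 0);
  for (int c = 0; c < m; ++c)
    if (labels[c] > 0 && signs[labels[c] - 1] == 0)
      signs[labels[c] - 1] = stat[c] > 0 ? 1 : -1;

  NumericVector null_max(nperm);
  std::vector<int> plab;
  std::vector<double> pmass;
  RNGScope scope;
  for (int b = 0; b < nperm; ++b) {
    for (int i = 0; i < ns; ++i) flip[i] = unif_rand() < 0.5 ? -1.0 : 1.0;
    tstat(B, flip, stat);
    find_clusters(stat, t_thresh, nch, nt, adj, plab, pmass);
    double mx = 0.0;
    for (double v : pmass) mx = std::max(mx, v);
    null_max[b] = mx;
  }
  std::fill(flip.begin(), flip.end(), 1.0);
  tstat(B, flip, stat);  // restore the observed map after permuting
  return List::create(
      _["labels"] = IntegerVector(labels.begin(), labels.end()),
      _["masses"] = NumericVector(masses.begin(), masses.end()),
      _["signs"] = IntegerVector(signs.begin(), signs.end()),
      _["tmap"] = NumericVector(stat.begin(), stat.end()),
      _["null_max"] = null_max);
}
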