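#include <Rcpp.h>
using namespace Rcpp;

// Clipped dual coordinate descent for
//   min_u  0.5 * u'Qu - l'u   subject to  u >= lb  (elementwise)
// Q symmetric with strictly positive diagonal. Greedy coordinate selection:
// at each step pick the coordinate whose clipped exact line-search update
// decreases the objective most (lowest index wins ties), set
//   u_k <- max(lb_k, u_k - g_k / Q_kk),  g = Qu - l,
// and maintain the gradient incrementally. Convergence is declared when the
// largest projected-gradient magnitude (|g_i| off the bound, max(-g_i, 0)
// at the bound) falls below tol.
// [[Rcpp::export(name = ".clipdcd_cpp")]]
List clipdcd_cpp(const NumericMatrix& Q, const NumericVector& l,
                 const NumericVector& lb, const NumericVector& u0,
                 double tol, int max_iter) {
  const int m = Q.nrow();
  if (Q.ncol() != m || l.size() != m || lb.size() != m || u0.size() != m)
    stop("nonconforming dual problem");
  const double* q = REAL(Q);
  const double* lv = REAL(l);
  const double* lbv = REAL(lb);
  std::vector<double> diag(m), u(m), g(m);
  for (int i = 0; i < m; ++i) {
    diag[i] = q[(size_t)i * m + i];
    if (!(diag[i] > 0)) stop("ClipDCD requires a strictly positive diagonal");
    u[i] = u0[i] < lbv[i] ? lbv[i] : u0[i];
  }
  // gradient g = Qu - l (column-wise accumulation over the symmetric Q)
  for (int i = 0; i < m; ++i) g[i] = -lv[i];
  for (int j = 0; j < m; ++j) {
    const double uj = u[j];
    if (uj == 0.0) continue;
    const double* col = q + (size_t)j * m;
    for (int i = 0; i < m; ++i) g[i] += col[i] * uj;
  }

  int iter = 0;
  bool converged = false;
  for (iter = 0; iter < max_iter; ++iter) {
    int best = -1;
    double best_dec = 0.0, best_step = 0.0, pg_max = 0.0;
    for (int i = 0; i < m; ++i) {
      const double gi = g[i];
      const double slack = u[i] - lbv[i];
      const double pg = (slack <= 0.0) ? (gi < 0.0 ? -gi : 0.0)
                                       : (gi < 0.0 ? -gi : gi);
      if (pg > pg_max) pg_max = pg;
      double d = -gi / diag[i];
      if (d < -slack) d = -slack;
      if (d == 0.0) continue;
      const double dec = -(gi * d + 0.5 * diag[i] * d * d);
      if (dec > best_dec) { best_dec = dec; best = i; best_step = d; }
    }
    if (pg_max <= tol || best < 0) { converged = true; break; }
    u[best] += best_step;
    const double* col = q + (size_t)best * m;
    for (int j = 0; j < m; ++j) g[j] += col[j] * best_step;
  }

  // 0.5 u'Qu - l'u = 0.5 u'(g + l) - l'u = 0.5 u'(g - l)
  double obj = 0.0;
  for (int i = 0; i < m; ++i) obj += 0.5 * u[i] * (g[i] - lv[i]);

  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["iterations"] = iter,
                      _["converged"] = converged, _["objective"] = obj);
}

// Specialized ClipDCD for the EQSVR dual, never forming the 2n x 2n matrix.
// With K the n x n Gram matrix of the augmented design, the dual Hessian is
//   Q = [[ lam^2 K, -tau lam^2 K], [-tau lam^2 K, tau^2 lam^2 K]] + c R,
// c = 5/(2C), R = [[I, I], [I, I]]; a column of Q is a scaled K column plus
// two entries of c, so the gradient update costs O(n), not O(2n) dense.
// [[Rcpp::export(name = ".clipdcd_eqsvr_cpp")]]
List clipdcd_eqsvr_cpp(const NumericMatrix& K, double lam, double tau,
                       double cpen, const NumericVector& l,
                       const NumericVector& lb, const NumericVector& u0,
                       double tol, int max_iter) {
  const int n = K.nrow();
  const int m = 2 * n;
  if (K.ncol() != n || l.size() != m || lb.size() != m || u0.size() != m)
    stop("nonconforming dual problem");
  const double* k = REAL(K);
  const double* lv = REAL(l);
  const double* lbv = REAL(lb);
  const double c = 5.0 / (2.0 * cpen);
  const double lam2 = lam * lam;
  std::vector<double> diag(m), u(m), g(m);
  for (int i = 0; i < m; ++i) {
    const int ii = i < n ? i : i - n;
    const double scale = i < n ? lam2 : tau * tau * lam2;
    diag[i] = scale * k[(size_t)ii * n + ii] + c;
    if (!(diag[i] > 0)) stop("ClipDCD requires a strictly positive diagonal");
    u[i] = u0[i] < lbv[i] ? lbv[i] : u0[i];
  }
  // g = Qu - l: accumulate K (v1 - tau v2) block products
  std::vector<double> kv(n, 0.0);
  for (int j = 0; j < n; ++j) {
    const double w = u[j] - tau * u[j + n];
    if (w == 0.0) continue;
    const double* col = k + (size_t)j * n;
    for (int i = 0; i < n; ++i) kv[i] += col[i] * w;
  }
  for (int i = 0; i < n; ++i) {
    const double s = c * (u[i] + u[i + n]);
    g[i] = lam2 * kv[i] + s - lv[i];
    g[i + n] = -tau * lam2 * kv[i] + s - lv[i + n];
  }

  int iter = 0;
  bool converged = false;
  for (iter = 0; iter < max_iter; ++iter) {
    int best = -1;
    double best_dec = 0.0, best_step = 0.0, pg_max = 0.0;
    for (int i = 0; i < m; ++i) {
      const double gi = g[i];
      const double slack = u[i] - lbv[i];
      const double pg = (slack <= 0.0) ? (gi < 0.0 ? -gi : 0.0)
                                       : (gi < 0.0 ? -gi : gi);
      if (pg > pg_max) pg_max = pg;
      double d = -gi / diag[i];
      if (d < -slack) d = -slack;
      if (d == 0.0) continue;
      const double dec = -(gi * d + 0.5 * diag[i] * d * d);
      if (dec > best_dec) { best_dec = dec; best = i; best_step = d; }
    }
    if (pg_max <= tol || best < 0) { converged = true; break; }
    const int b = best;
    const int bi = b < n ? b : b - n;
    const double s1 = (b < n ? lam2 : -tau * lam2) * best_step;
    const double s2 = -tau * s1;
    u[b] += best_step;
    const double* col = k + (size_t)bi * n;
    for (int i = 0; i < n; ++i) {
      g[i] += col[i] * s1;
      g[i + n] += col[i] * s2;
    }
    g[bi] += c * best_step;
    g[bi + n] += c * best_step;
  }

  double obj = 0.0;
  for (int i = 0; i < m; ++i) obj += 0.5 * u[i] * (g[i] - lv[i]);

  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["iterations"] = iter,
                      _["converged"] = converged, _["objective"] = obj);
}
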