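#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Epsilon-insensitive support-vector regression solved by sequential
// minimal optimization on the standard 2n-variable dual:
//
//   min 0.5 u'Qu + p'u,  0 <= u <= C,  z'u = 0,
//
// with u = [alpha; alpha*], z = [1; -1], p = [eps - y; eps + y] and
// Q[s,t] = z_s z_t K[s mod n, t mod n]. The maximal-violating pair is
// selected each iteration; beta = alpha - alpha* and the prediction is
// f(x) = sum_k beta_k K(x_k, x) + b.
//
// [[Rcpp::export(name = ".svr_smo_cpp")]]
List svr_smo_cpp(NumericMatrix K, NumericVector y, double C, double eps,
                 double tol = 1e-3, int max_iter = 100000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n)
    stop("K must be n x n and y length n");
  const int N = 2 * n;
  std::vector<double> u(N, 0.0), G(N), z(N);
  for (int s = 0; s < n; ++s) {
    z[s] = 1.0;  G[s] = eps - y[s];
    z[s + n] = -1.0;  G[s + n] = eps + y[s];
  }
  double gap = R_PosInf;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    // maximal violating pair over -z_s G_s
    int i = -1, j = -1;
    double m_up = -R_PosInf, m_low = R_PosInf;
    for (int s = 0; s < N; ++s) {
      const double v = -z[s] * G[s];
      const bool up = (z[s] > 0) ? (u[s] < C) : (u[s] > 0);
      const bool low = (z[s] > 0) ? (u[s] > 0) : (u[s] < C);
      if (up && v > m_up) { m_up = v; i = s; }
      if (low && v < m_low) { m_low = v; j = s; }
    }
    gap = m_up - m_low;
    if (i < 0 || j < 0 || gap < tol) break;
    const int ib = i % n, jb = j % n;
    double a = K(ib, ib) + K(jb, jb) - 2.0 * K(ib, jb);
    if (a < 1e-12) a = 1e-12;
    double t = gap / a;
    // box limits along the feasible direction (d_i = z_i, d_j = -z_j)
    const double ti = (z[i] > 0) ? (C - u[i]) : u[i];
    const double tj = (z[j] > 0) ? u[j] : (C - u[j]);
    if (t > ti) t = ti;
    if (t > tj) t = tj;
    if (t <= 0) break;
    u[i] += z[i] * t;  // step t along the direction (d_i, d_j) = (z_i, -z_j)
    u[j] -= z[j] * t;
    for (int s = 0; s < N; ++s)
      G[s] += t * z[s] * (K(s % n, ib) - K(s % n, jb));
  }
  // beta and intercept
  NumericVector beta(n);
  for (int s = 0; s < n; ++s) beta[s] = u[s] - u[s + n];
  const double db = 1e-8 * (C > 0 ? C : 1.0);
  double bsum = 0.0; int bcount = 0;
  double lb = -R_PosInf, ub = R_PosInf;
  for (int s = 0; s < N; ++s) {
    const double zg = z[s] * G[s];
    if (u[s] > db && u[s] < C - db) { bsum += zg; ++bcount; }
    const bool at_zero = u[s] <= db, at_C = u[s] >= C - db;
    if ((z[s] < 0 && at_zero) || (z[s] > 0 && at_C)) { if (zg > lb) lb = zg; }
    if ((z[s] > 0 && at_zero) || (z[s] < 0 && at_C)) { if (zg < ub) ub = zg; }
  }
  double b;
  if (bcount > 0) b = -bsum / bcount;
  else b = -0.5 * (lb + ub);
  return List::create(_["beta"] = beta, _["b"] = b,
                      _["iterations"] = iter, _["gap"] = gap);
}
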