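// Adaptive Dormand-Prince RK45 integration of the sparse polynomial
// gene-network right-hand side
//   dx_i/dt = sum_{j->i} alpha_ij x_j + sum_{(j,k)->i} beta_ijk x_j x_k - k_i x_i
// The parameter vector theta is laid out [alpha..., beta..., k...] in the
// edge order of the companion network, so the same evaluator serves single
// simulations, GA fitness sweeps and robustness perturbation sweeps.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Structure {
  int m, na, nb;
  std::vector<int> a_src, a_dst;     // alpha edges: src -> dst (0-based)
  std::vector<int> b_j, b_k, b_i;    // beta edges: (j,k) -> i (0-based)
};

Structure parse_structure(const List& s) {
  Structure st;
  st.m = as<int>(s["m"]);
  IntegerVector as_ = s["a_src"], ad = s["a_dst"];
  IntegerVector bj = s["b_j"], bk = s["b_k"], bi = s["b_i"];
  st.na = as_.size();
  st.nb = bj.size();
  st.a_src.assign(as_.begin(), as_.end());
  st.a_dst.assign(ad.begin(), ad.end());
  st.b_j.assign(bj.begin(), bj.end());
  st.b_k.assign(bk.begin(), bk.end());
  st.b_i.assign(bi.begin(), bi.end());
  return st;
}

inline void rhs(const Structure& st, const double* th, const double* x,
                double* f) {
  const double* alpha = th;
  const double* beta = th + st.na;
  const double* kd = th + st.na + st.nb;
  for (int i = 0; i < st.m; ++i) f[i] = -kd[i] * x[i];
  for (int e = 0; e < st.na; ++e)
    f[st.a_dst[e]] += alpha[e] * x[st.a_src[e]];
  for (int e = 0; e < st.nb; ++e)
    f[st.b_i[e]] += beta[e] * x[st.b_j[e]] * x[st.b_k[e]];
}

// Dormand-Prince 5(4) coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
             a53 = 64448.0 / 6561, a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
             e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

// status: 0 ok, 1 diverged, 2 solver failure
int integrate_interval(const Structure& st, const double* th,
                       std::vector<double>& y, double t0, double t1,
                       double rtol, double atol, double bound,
                       long& steps_left) {
  const int m = st.m;
  std::vector<double> k1(m), k2(m), k3(m), k4(m), k5(m), k6(m), k7(m),
      ytmp(m), ynew(m);
  double t = t0;
  double h = (t1 - t0) / 10.0;
  const double hmin = 1e-12 * std::max(1.0, std::fabs(t1 - t0));
  while (t < t1) {
    if (--steps_left <= 0) return 2;
    if (h < hmin) return 2;
    if (t + h > t1) h = t1 - t;
    rhs(st, th, y.data(), k1.data());
    for (int i = 0; i < m; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    rhs(st, th, ytmp.data(), k2.data());
    for (int i = 0; i < m; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(st, th, ytmp.data(), k3.data());
    for (int i = 0; i < m; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(st, th, ytmp.data(), k4.data());
    for (int i = 0; i < m; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    rhs(st, th, ytmp.data(), k5.data());
    for (int i = 0; i < m; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    rhs(st, th, ytmp.data(), k6.data());
    for (int i = 0; i < m; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    rhs(st, th, ynew.data(), k7.data());
    // error estimate: 5th - embedded 4th
    double errnorm = 0.0;
    for (int i = 0; i < m; ++i) {
      double y4 = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                              e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double d = (ynew[i] - y4) / sc;
      errnorm += d * d;
    }
    errnorm = std::sqrt(errnorm / m);
    if (!std::isfinite(errnorm)) {
      // state blew past double range inside a trial step
      for (int i = 0; i < m; ++i)
        if (!std::isfinite(ynew[i]) || std::fabs(ynew[i]) > bound) return 1;
      return 2;
    }
    if (errnorm <= 1.0) {
      t += h;
      y = ynew;
      for (int i = 0; i < m; ++i)
        if (!std::isfinite(y[i]) || std::fabs(y[i]) > bound) return 1;
    }
    double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
  }
  return 0;
}

// full trajectory on a grid; returns status, fills cols of out (m x M)
int simulate_grid(const Structure& st, const double* th,
                  const double* x0, const double* times, int M,
                  double rtol, double atol, double bound, double* out) {
  std::vector<double> y(x0, x0 + st.m);
  long steps_left = 1000000L;
  for (int i = 0; i < st.m; ++i) out[i] = y[i];
  for (int j = 1; j < M; ++j) {
    int status = integrate_interval(st, th, y, times[j - 1], times[j], rtol,
                                    atol, bound, steps_left);
    if (status != 0) return status;
    for (int i = 0; i < st.m; ++i) out[i + (size_t)j * st.m] = y[i];
  }
  return 0;
}

}  // namespace

// [[Rcpp::export]]
List sim_cpp(List structure, NumericVector theta, NumericVector x0,
             NumericVector times, double rtol, double atol, double bound) {
  Structure st = parse_structure(structure);
  int M = times.size();
  NumericMatrix out(st.m, M);
  int status = simulate_grid(st, REAL(theta), REAL(x0), REAL(times), M, rtol,
                             atol, bound, REAL(out));
  return List::create(_["values"] = out, _["status"] = status);
}

// Fitness sweep: one simulation error per row of `thetas`, against `target`
// (m x M, same grid). Diverged or failed rows report Inf.
// [[Rcpp::export]]
NumericVector eval_population_cpp(NumericMatrix thetas, List structure,
                                  NumericMatrix target, NumericVector x0,
                                  NumericVector times, double rtol,
                                  double atol, double bound) {
  Structure st = parse_structure(structure);
  int M = times.size();
  int n_ind = thetas.nrow(), n_par = thetas.ncol();
  if (n_par != st.na + st.nb + st.m)
    stop("theta length does not match network structure");
  NumericVector E(n_ind);
  std::vector<double> th(n_par), traj((size_t)st.m * M);
  for (int r = 0; r < n_ind; ++r) {
    for (int p = 0; p < n_par; ++p) th[p] = thetas(r, p);
    int status = simulate_grid(st, th.data(), REAL(x0), REAL(times), M, rtol,
                               atol, bound, traj.data());
    if (status != 0) {
      E[r] = R_PosInf;
      continue;
    }
    double ss = 0.0;
    for (int j = 0; j < M; ++j)
      for (int i = 0; i < st.m; ++i) {
        double d = target(i, j) - traj[i + (size_t)j * st.m];
        ss += d * d;
      }
    E[r] = std::sqrt(ss);
  }
  return E;
}
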