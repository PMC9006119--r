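#include <Rcpp.h>
using namespace Rcpp;

// Evaluate xdot = Theta(x, u) Xi for a polynomial model over (states, input).
// Expo is D x (n + 1): monomial exponents, last column is the input degree.
static void model_rhs(const NumericMatrix &Xi, const IntegerMatrix &Expo,
                      const double *x, double u, double *dx, int n, int D) {
  for (int i = 0; i < n; ++i) dx[i] = 0.0;
  for (int d = 0; d < D; ++d) {
    double term = 1.0;
    for (int j = 0; j < n; ++j)
      for (int e = 0; e < Expo(d, j); ++e) term *= x[j];
    for (int e = 0; e < Expo(d, n); ++e) term *= u;
    for (int i = 0; i < n; ++i) dx[i] += Xi(d, i) * term;
  }
}

static void rk4_step(const NumericMatrix &Xi, const IntegerMatrix &Expo,
                     double *x, double u, double dt, int n, int D) {
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
  model_rhs(Xi, Expo, x, u, k1.data(), n, D);
  for (int i = 0; i < n; ++i) tmp[i] = x[i] + 0.5 * dt * k1[i];
  model_rhs(Xi, Expo, tmp.data(), u, k2.data(), n, D);
  for (int i = 0; i < n; ++i) tmp[i] = x[i] + 0.5 * dt * k2[i];
  model_rhs(Xi, Expo, tmp.data(), u, k3.data(), n, D);
  for (int i = 0; i < n; ++i) tmp[i] = x[i] + dt * k3[i];
  model_rhs(Xi, Expo, tmp.data(), u, k4.data(), n, D);
  for (int i = 0; i < n; ++i)
    x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// Single-shooting objective: forward-integrate the identified model under the
// candidate input sequence and accumulate the quadratic stage costs.
// [[Rcpp::export]]
double mpc_rollout_cost(NumericVector useq, NumericVector x0,
                        NumericMatrix Xi, IntegerMatrix Expo, double dt,
                        NumericVector qdiag, double r, double rdelta,
                        NumericVector xref, double uprev) {
  int n = x0.size(), D = Xi.nrow(), Nh = useq.size();
  std::vector<double> x(x0.begin(), x0.end());
  double cost = 0.0, ulast = uprev;
  for (int k = 0; k < Nh; ++k) {
    double u = useq[k];
    rk4_step(Xi, Expo, x.data(), u, dt, n, D);
    for (int i = 0; i < n; ++i) {
      double e = x[i] - xref[i];
      cost += qdiag[i] * e * e;
      if (!std::isfinite(x[i])) return 1e12;  // divergent rollout
    }
    cost += r * u * u + rdelta * (u - ulast) * (u - ulast);
    ulast = u;
  }
  return cost;
}

// Fixed-step RK4 trajectory of a polynomial model sampled on tgrid (each
// save interval split into nsub substeps). Integration stops at divergence
// (non-finite or |x| > 1e6); remaining rows are left NA.
// [[Rcpp::export]]
List poly_path(NumericVector x0, NumericMatrix Xi, IntegerMatrix Expo,
               NumericVector tgrid, int nsub) {
  int n = x0.size(), D = Xi.nrow(), m = tgrid.size();
  NumericMatrix out(m, n);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> x(x0.begin(), x0.end());
  for (int i = 0; i < n; ++i) out(0, i) = x[i];
  bool divergent = false;
  for (int j = 1; j < m && !divergent; ++j) {
    double h = (tgrid[j] - tgrid[j - 1]) / nsub;
    for (int s = 0; s < nsub; ++s) {
      rk4_step(Xi, Expo, x.data(), 0.0, h, n, D);
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e6) divergent = true;
      if (divergent) break;
    }
    if (!divergent)
      for (int i = 0; i < n; ++i) out(j, i) = x[i];
  }
  return List::create(Named("states") = out,
                      Named("divergent") = divergent);
}
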