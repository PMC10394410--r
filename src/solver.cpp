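#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Mean-field exclusion-process right-hand side with open boundaries.
//
// Bulk sites exchange particles with nearest neighbours under the
// exclusion rule (factorized second moments); the boundary sites couple
// to reservoirs through injection rates (p0 left, qN1 right) and exit
// rates (q1exit left, pNexit right).  At grid spacing 1 this is exactly
// the finite-volume discretization of the hydrodynamic density equation,
// so one core serves both the lattice model and the continuum solver.
static inline void mf_rhs_core(const double* phi, double* dphi, int n,
                               const double* p, const double* q,
                               double p0, double q1exit,
                               double pNexit, double qN1) {
  // left boundary (site 1)
  dphi[0] = p0 * (1.0 - phi[0])
          - p[0] * phi[0] * (1.0 - phi[1])
          + q[1] * phi[1] * (1.0 - phi[0])
          - q1exit * phi[0];
  // bulk
  for (int i = 1; i < n - 1; ++i) {
    dphi[i] = p[i - 1] * phi[i - 1] * (1.0 - phi[i])
            - p[i] * phi[i] * (1.0 - phi[i + 1])
            + q[i + 1] * phi[i + 1] * (1.0 - phi[i])
            - q[i] * phi[i] * (1.0 - phi[i - 1]);
  }
  // right boundary (site N)
  dphi[n - 1] = p[n - 2] * phi[n - 2] * (1.0 - phi[n - 1])
              - pNexit * phi[n - 1]
              + qN1 * (1.0 - phi[n - 1])
              - q[n - 1] * phi[n - 1] * (1.0 - phi[n - 2]);
}

// [[Rcpp::export(name = ".mf_rhs_cpp")]]
NumericVector mf_rhs_cpp(NumericVector phi, NumericVector p, NumericVector q,
                         double p0, double q1exit, double pNexit, double qN1) {
  int n = phi.size();
  NumericVector out(n);
  mf_rhs_core(phi.begin(), out.begin(), n, p.begin(), q.begin(),
              p0, q1exit, pNexit, qN1);
  return out;
}

// Cash-Karp embedded Runge-Kutta 4(5) coefficients
static const double b21 = 1.0 / 5.0;
static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0,
                    b54 = 35.0 / 27.0;
static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                    b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                    b65 = 253.0 / 4096.0;
static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                    c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
static const double dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
                    dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
                    dc6 = c6 - 1.0 / 4.0;

// Integrate the mean-field system from t = 0, writing the state at each
// requested output time.  Adaptive Cash-Karp RK45; any occupancy
// excursion beyond [-clip_tol, 1 + clip_tol] aborts (returned as an
// error flag so R can raise or map to -Inf likelihood).
//
// Returns a list(status, rho) where status 0 = ok, 1 = excursion,
// 2 = step underflow.
// [[Rcpp::export(name = ".mf_integrate_cpp")]]
List mf_integrate_cpp(NumericVector phi0, NumericVector p, NumericVector q,
                      double p0, double q1exit, double pNexit, double qN1,
                      NumericVector times, double rtol, double atol,
                      double clip_tol) {
  const int n = phi0.size();
  const int nt = times.size();
  NumericMatrix out(nt, n);

  std::vector<double> y(phi0.begin(), phi0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n),
      ytmp(n), yerr(n), y5(n);

  // CFL-style initial step: advective speed ~ max rate, diffusion ~ rates/2
  double rmax = 0.0;
  for (int i = 0; i < n; ++i)
    rmax = std::max(rmax, std::max(p[i], q[i]));
  rmax = std::max(rmax, std::max(p0, qN1));
  double h = (rmax > 0.0) ? 0.25 / rmax : 1.0;

  double t = 0.0;
  int it = 0;
  if (times[0] <= 0.0) {
    for (int i = 0; i < n; ++i) out(0, i) = y[i];
    it = 1;
  }

  const double hmin = 1e-12;
  int status = 0;
  long n_steps = 0, n_rej = 0;

  while (it < nt) {
    double tnext = times[it];
    while (t < tnext) {
      if (t + h > tnext) h = tnext - t;
      // Cash-Karp stages
      mf_rhs_core(y.data(), k1.data(), n, p.begin(), q.begin(), p0, q1exit, pNexit, qN1);
      for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * b21 * k1[i];
      mf_rhs_core(ytmp.data(), k2.data(), n, p.begin(), q.begin(), p0, q1exit, pNexit, qN1);
      for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
      mf_rhs_core(ytmp.data(), k3.data(), n, p.begin(), q.begin(), p0, q1exit, pNexit, qN1);
      for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
      mf_rhs_core(ytmp.data(), k4.data(), n, p.begin(), q.begin(), p0, q1exit, pNexit, qN1);
      for (int i = 0; i < n; ++i)
        ytmp[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
      mf_rhs_core(ytmp.data(), k5.data(), n, p.begin(), q.begin(), p0, q1exit, pNexit, qN1);
      for (int i = 0; i < n; ++i)
        ytmp[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] + b64 * k4[i] + b65 * k5[i]);
      mf_rhs_core(ytmp.data(), k6.data(), n, p.begin(), q.begin(), p0, q1exit, pNexit, qN1);

      double errmax = 0.0;
      for (int i = 0; i < n; ++i) {
        y5[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
        yerr[i] = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] + dc5 * k5[i] + dc6 * k6[i]);
        double sk = atol + rtol * std::fabs(y[i]);
        errmax = std::max(errmax, std::fabs(yerr[i]) / sk);
      }

      if (errmax <= 1.0) {
        // accept
        ++n_steps;
        t += h;
        bool bad = false;
        for (int i = 0; i < n; ++i) {
          double v = y5[i];
          if (v < -clip_tol || v > 1.0 + clip_tol) { bad = true; break; }
          y[i] = std::min(1.0, std::max(0.0, v));
        }
        if (bad) { status = 1; break; }
        double fac = 0.9 * std::pow(std::max(errmax, 1e-10), -0.2);
        h *= std::min(5.0, std::max(0.2, fac));
      } else {
        ++n_rej;
        double fac = 0.9 * std::pow(errmax, -0.25);
        h *= std::max(0.1, fac);
        if (h < hmin) { status = 2; break; }
      }
    }
    if (status != 0) break;
    for (int i = 0; i < n; ++i) out(it, i) = y[i];
    ++it;
  }

  return List::create(_["status"] = status, _["rho"] = out,
                      _["t_reached"] = t, _["n_steps"] = (double)n_steps,
                      _["n_rejected"] = (double)n_rej);
}

// Stochastic exclusion-process simulator (Gillespie / kinetic Monte Carlo).
// Uses R's RNG so set.seed() in R governs reproducibility.  Returns the
// occupancy averaged over replicas at each output time.
// [[Rcpp::export(name = ".gillespie_cpp")]]
NumericMatrix gillespie_cpp(IntegerVector init, NumericVector p, NumericVector q,
                            double p0, double q1exit, double pNexit, double qN1,
                            NumericVector times, int n_replicas) {
  const int n = init.size();
  const int nt = times.size();
  NumericMatrix acc(nt, n);
  RNGScope scope;

  std::vector<int> s(n);
  std::vector<double> rate(2 * n + 2);

  for (int rep = 0; rep < n_replicas; ++rep) {
    for (int i = 0; i < n; ++i) s[i] = init[i];
    double t = 0.0;
    int it = 0;
    while (it < nt && times[it] <= 0.0) {
      for (int i = 0; i < n; ++i) acc(it, i) += s[i];
      ++it;
    }
    while (it < nt) {
      // enumerate event rates: 0 = inject left, 1 = inject right,
      // 2..n+1 forward moves/exits from site i, n+2..2n+1 backward
      double total = 0.0;
      rate[0] = (s[0] == 0) ? p0 : 0.0;
      rate[1] = (s[n - 1] == 0) ? qN1 : 0.0;
      total += rate[0] + rate[1];
      for (int i = 0; i < n; ++i) {
        double rf = 0.0, rb = 0.0;
        if (s[i] == 1) {
          if (i == n - 1) rf = pNexit;
          else if (s[i + 1] == 0) rf = p[i];
          if (i == 0) rb = q1exit;
          else if (s[i - 1] == 0) rb = q[i];
        }
        rate[2 + i] = rf;
        rate[2 + n + i] = rb;
        total += rf + rb;
      }
      if (total <= 0.0) { t = R_PosInf; }
      else t += ::Rf_rexp(1.0 / total);
      while (it < nt && times[it] <= t) {
        for (int i = 0; i < n; ++i) acc(it, i) += s[i];
        ++it;
      }
      if (it >= nt || !R_FINITE(t)) break;
      double u = ::unif_rand() * total;
      double cum = 0.0;
      int ev = -1;
      for (int k = 0; k < 2 * n + 2; ++k) {
        cum += rate[k];
        if (u <= cum) { ev = k; break; }
      }
      if (ev < 0) ev = 2 * n + 1;
      if (ev == 0) s[0] = 1;
      else if (ev == 1) s[n - 1] = 1;
      else if (ev < 2 + n) {
        int i = ev - 2;
        s[i] = 0;
        if (i < n - 1) s[i + 1] = 1;
      } else {
        int i = ev - 2 - n;
        s[i] = 0;
        if (i > 0) s[i - 1] = 1;
      }
    }
  }
  for (int j = 0; j < nt; ++j)
    for (int i = 0; i < n; ++i) acc(j, i) /= n_replicas;
  return acc;
}
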