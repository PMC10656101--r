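#include <Rcpp.h>
#include "bound.h"
using namespace Rcpp;

// Euler simulation of first passage through logistic collapsing bounds.
// DV update per step: dDV = mu * dt + N(0, dt); unit diffusion variance per
// second. Crossing is checked at step ends (no sub-step interpolation).
// hit: +1 upper, -1 lower, 0 none (time = horizon).
// [[Rcpp::export]]
List cpp_sim_fp(int n, double mu, double dt, double horizon,
                double u, double a, double d) {
  int nstep = (int)std::ceil(horizon / dt);
  double sdt = std::sqrt(dt);
  std::vector<double> B(nstep);
  for (int k = 1; k <= nstep; ++k) B[k - 1] = bound_at(k * dt, u, a, d);
  IntegerVector hit(n);
  NumericVector time(n);
  for (int i = 0; i < n; ++i) {
    double dv = 0.0;
    int h = 0;
    double tm = horizon;
    for (int k = 1; k <= nstep; ++k) {
      dv += mu * dt + sdt * norm_rand();
      if (dv >= B[k - 1]) { h = 1; tm = k * dt; break; }
      if (dv <= -B[k - 1]) { h = -1; tm = k * dt; break; }
    }
    hit[i] = h;
    time[i] = tm;
  }
  return List::create(_["hit"] = hit, _["time"] = time);
}

// Forward propagation of the discrete-time Euler density on a uniform DV
// grid with absorbing collapsing bounds. Each step convolves the surviving
// density with the exactly-binned Gaussian step kernel (CDF differences,
// tails accumulated in the end taps), then absorbs all cells at or beyond
// +/- B(t). This is the density of the same process cpp_sim_fp simulates,
// up to the DV discretization.
// Returns defect densities (absorbed mass per step / dt) and survivor mass.
// [[Rcpp::export]]
List cpp_fp_propagate(double mu, double dt, double dv_step, double horizon,
                      double u, double a, double d) {
  int nstep = (int)std::ceil(horizon / dt);
  double sdt = std::sqrt(dt);

  // grid of cell centres, symmetric about 0
  double L = u + 5.0 * sdt + dv_step;
  int j0 = (int)std::ceil(L / dv_step);   // index of dv = 0
  int m = 2 * j0 + 1;

  // binned step kernel over offsets -K..K
  int K = (int)std::ceil((4.0 * sdt + std::fabs(mu) * dt) / dv_step) + 1;
  int nk = 2 * K + 1;
  std::vector<double> ker(nk);
  double acc = 0.0;
  for (int o = -K; o <= K; ++o) {
    double lob = (o - 0.5) * dv_step, hib = (o + 0.5) * dv_step;
    double w = R::pnorm(hib, mu * dt, sdt, 1, 0) - R::pnorm(lob, mu * dt, sdt, 1, 0);
    ker[o + K] = w;
    acc += w;
  }
  // push tail mass into the end taps so the kernel sums to exactly 1
  double lo_tail = R::pnorm((-K - 0.5) * dv_step, mu * dt, sdt, 1, 0);
  ker[0] += lo_tail;
  ker[nk - 1] += 1.0 - acc - lo_tail;

  std::vector<double> p(m, 0.0), q(m, 0.0);
  p[j0] = 1.0;

  NumericVector tgrid(nstep), up(nstep), lo(nstep);
  for (int k = 1; k <= nstep; ++k) tgrid[k - 1] = k * dt;
  double surv = 1.0;
  for (int k = 1; k <= nstep; ++k) {
    double t = k * dt;
    std::fill(q.begin(), q.end(), 0.0);
    for (int j = 0; j < m; ++j) {
      double pj = p[j];
      if (pj <= 0.0) continue;
      int lo_j = j - K, hi_j = j + K;
      int o0 = 0;
      if (lo_j < 0) {
        // off-grid taps land beyond the lower edge; fold into the edge cell
        for (int o = 0; o < -lo_j; ++o) q[0] += pj * ker[o];
        o0 = -lo_j; lo_j = 0;
      }
      if (hi_j > m - 1) {
        for (int o = nk - (hi_j - (m - 1)); o < nk; ++o) q[m - 1] += pj * ker[o];
        hi_j = m - 1;
      }
      const double* kk = &ker[o0];
      for (int jj = lo_j; jj <= hi_j; ++jj)
        q[jj] += pj * (*kk++);
    }
    double B = bound_at(t, u, a, d);
    int jup = j0 + (int)std::ceil(B / dv_step - 1e-12); // first absorbed cell above
    if (jup < 0) jup = 0;
    int jlo = j0 - (int)std::ceil(B / dv_step - 1e-12); // last absorbed cell below
    if (jlo > m - 1) jlo = m - 1;
    double mup = 0.0, mlo = 0.0;
    for (int j = jup; j < m; ++j) { mup += q[j]; q[j] = 0.0; }
    for (int j = 0; j <= jlo; ++j) { mlo += q[j]; q[j] = 0.0; }
    up[k - 1] = mup / dt;
    lo[k - 1] = mlo / dt;
    surv -= mup + mlo;
    p.swap(q);
    if (surv < 1e-12) {
      surv = 0.0;
      break;  // remaining entries stay 0
    }
  }
  return List::create(_["t"] = tgrid, _["up"] = up, _["lo"] = lo,
                      _["surviving"] = surv);
}
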