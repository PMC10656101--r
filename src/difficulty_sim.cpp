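#include <Rcpp.h>
#include <algorithm>
#include "bound.h"
#include "rng.h"
using namespace Rcpp;

// model codes shared with R/difficulty.R
// 1 race, 2 difference, 3 two_step, 4 absolute, 5 known,
// 6 confidence (unknown color), 7 confidence (known color)

template <class RNG>
inline int rsign(double x, RNG& rng) {
  if (x > 0.0) return 1;
  if (x < 0.0) return -1;
  return (rng.unif() < 0.5) ? 1 : -1;
}

// bilinear lookup of the signed log-odds map; rows index dv, cols index time
// (t = col * t_step). Out-of-range queries clamp to the nearest node.
inline double conf_lookup(const NumericMatrix& conf, double dv_min,
                          double dv_step, double t_step, double dv, double t) {
  int nr = conf.nrow(), nc = conf.ncol();
  double ri = (dv - dv_min) / dv_step;
  double ci = t / t_step;
  if (ri < 0) ri = 0;
  if (ri > nr - 1) ri = nr - 1;
  if (ci < 0) ci = 0;
  if (ci > nc - 1) ci = nc - 1;
  int r0 = (int)ri, c0 = (int)ci;
  int r1 = r0 < nr - 1 ? r0 + 1 : r0;
  int c1 = c0 < nc - 1 ? c0 + 1 : c0;
  double fr = ri - r0, fc = ci - c0;
  return (1 - fr) * ((1 - fc) * conf(r0, c0) + fc * conf(r0, c1)) +
         fr * ((1 - fc) * conf(r1, c0) + fc * conf(r1, c1));
}

struct TrialResult {
  int choice;        // 1 = S1, 2 = S2
  int terminated;    // 0 bound, 1 horizon
  double dtime;
  double tmini;      // NA unless two-step
};

// One serial (or parallel) RT-paradigm trial. B is the precomputed bound
// per step; bound/tie conventions as documented in simulate_difficulty().
template <class RNG>
TrialResult run_trial(int model, double c1, double c2, int s1, int s2,
                      double kappa, const std::vector<double>& B,
                      double bmini, double dt, double horizon, bool serial,
                      const NumericMatrix& conf, double conf_dv_min,
                      double conf_dv_step, double conf_t_step, RNG& rng) {
  int nstep = (int)B.size();
  double sdt = std::sqrt(dt);
  double mu1 = kappa * c1, mu2 = kappa * c2;
  double dv1 = 0.0, dv2 = 0.0, t1 = 0.0, t2 = 0.0;
  bool mini_done = false;
  int sg1 = 0, sg2 = 0;
  double tmn = NA_REAL;
  double S = 0.0;
  TrialResult out = {0, 1, horizon, NA_REAL};

  for (int k = 1; k <= nstep; ++k) {
    bool up1 = serial ? (k % 2 == 1) : true;
    bool up2 = serial ? (k % 2 == 0) : true;
    if (model == 4) {  // absolute momentary evidence: rectified increments
      if (up1) { dv1 += std::fabs(mu1 * dt + sdt * rng.norm()); t1 += dt; }
      if (up2) { dv2 += std::fabs(mu2 * dt + sdt * rng.norm()); t2 += dt; }
    } else {
      if (up1) { dv1 += mu1 * dt + sdt * rng.norm(); t1 += dt; }
      if (up2) { dv2 += mu2 * dt + sdt * rng.norm(); t2 += dt; }
    }
    double t = k * dt;
    double Bt = B[k - 1];

    if (model == 1) {  // race: first DV at its own +/-B wins
      bool x1 = std::fabs(dv1) >= Bt, x2 = std::fabs(dv2) >= Bt;
      if (x1 || x2) {
        out.choice = (x1 && x2) ? ((rng.unif() < 0.5) ? 1 : 2) : (x1 ? 1 : 2);
        out.terminated = 0; out.dtime = t;
        return out;
      }
      continue;
    }

    if (model == 3) {  // two-step: mini color decisions, then signed diff
      if (!mini_done) {
        bool x1 = std::fabs(dv1) >= bmini, x2 = std::fabs(dv2) >= bmini;
        if (x1 || x2 || t >= 2.0) {
          // Bmini flat for 2 s then collapses sharply; the crossing DV's
          // sign comes from its bound, the other from its value (random
          // on exact 0)
          sg1 = rsign(dv1, rng);
          sg2 = rsign(dv2, rng);
          mini_done = true;
          tmn = t;
          out.tmini = tmn;
        } else {
          continue;  // no difficulty choice before the mini-decision
        }
      }
      S = sg1 * dv1 - sg2 * dv2;
    } else if (model == 2) {
      S = std::fabs(dv1) - std::fabs(dv2);
    } else if (model == 4) {
      S = dv1 - dv2;
    } else if (model == 5) {
      S = s1 * dv1 - s2 * dv2;
    } else {
      double L1 = conf_lookup(conf, conf_dv_min, conf_dv_step, conf_t_step, dv1, t1);
      double L2 = conf_lookup(conf, conf_dv_min, conf_dv_step, conf_t_step, dv2, t2);
      S = (model == 6) ? (std::fabs(L1) - std::fabs(L2)) : (s1 * L1 - s2 * L2);
    }

    if (S >= Bt) { out.choice = 1; out.terminated = 0; out.dtime = t; return out; }
    if (S <= -Bt) { out.choice = 2; out.terminated = 0; out.dtime = t; return out; }
  }

  // horizon: resolve by the sign of the decision statistic
  if (model == 1) {
    double m1 = std::fabs(dv1), m2 = std::fabs(dv2);
    out.choice = (m1 == m2) ? ((rng.unif() < 0.5) ? 1 : 2) : (m1 > m2 ? 1 : 2);
  } else if (model == 3 && !mini_done) {
    out.choice = (rng.unif() < 0.5) ? 1 : 2;
  } else {
    out.choice = (S == 0.0) ? ((rng.unif() < 0.5) ? 1 : 2) : (S > 0 ? 1 : 2);
  }
  return out;
}

static std::vector<double> bound_table(double u, double a, double d,
                                       double dt, double horizon) {
  int nstep = (int)std::ceil(horizon / dt);
  std::vector<double> B(nstep);
  for (int k = 1; k <= nstep; ++k) B[k - 1] = bound_at(k * dt, u, a, d);
  return B;
}

// Serial, time-multiplexed 2D accumulator simulation for the difficulty
// models (RT paradigm); uses R's RNG stream. S1 is sampled on odd steps.
// terminated_by: 0 = bound crossing, 1 = horizon.
// [[Rcpp::export]]
List cpp_sim_difficulty(int model, NumericVector c1, NumericVector c2,
                        IntegerVector s1, IntegerVector s2,
                        double kappa, double u, double a, double d,
                        double bmini, double dt, double horizon, bool serial,
                        NumericMatrix conf, double conf_dv_min,
                        double conf_dv_step, double conf_t_step) {
  int n = c1.size();
  std::vector<double> B = bound_table(u, a, d, dt, horizon);
  IntegerVector choice(n), term(n);
  NumericVector dtime(n), tmini(n, NA_REAL);
  RRng rng;
  for (int i = 0; i < n; ++i) {
    TrialResult r = run_trial(model, c1[i], c2[i], s1[i], s2[i], kappa, B,
                              bmini, dt, horizon, serial, conf, conf_dv_min,
                              conf_dv_step, conf_t_step, rng);
    choice[i] = r.choice; term[i] = r.terminated;
    dtime[i] = r.dtime; tmini[i] = r.tmini;
  }
  return List::create(_["choice"] = choice, _["decision_time"] = dtime,
                      _["terminated_by"] = term, _["t_mini"] = tmini);
}

// Controlled-duration paradigm: both DVs advance on a shared sampled-time
// clock up to the (buffer-adjusted) effective duration; the collapsing
// bound is evaluated on that clock. No crossing by offset: choice is the
// sign of the statistic (ties random).
// terminated_by: 0 = bound crossing, 2 = stimulus offset.
// [[Rcpp::export]]
List cpp_sim_controlled(int model, NumericVector c1, NumericVector c2,
                        IntegerVector s1, IntegerVector s2,
                        double kappa, double u, double a, double d,
                        NumericVector tdur, double dt,
                        NumericMatrix conf, double conf_dv_min,
                        double conf_dv_step, double conf_t_step) {
  int n = c1.size();
  double sdt = std::sqrt(dt);
  double tmax = 0;
  for (int i = 0; i < n; ++i) tmax = std::max(tmax, tdur[i]);
  std::vector<double> B = bound_table(u, a, d, dt, tmax);
  IntegerVector choice(n), term(n);
  NumericVector dtime(n);
  RRng rng;
  for (int i = 0; i < n; ++i) {
    double mu1 = kappa * c1[i], mu2 = kappa * c2[i];
    int nstep = (int)std::ceil(tdur[i] / dt);
    double dv1 = 0.0, dv2 = 0.0;
    int ch = 0, tb = 2;
    double tdec = tdur[i];
    double S = 0.0;
    for (int k = 1; k <= nstep; ++k) {
      if (model == 4) {
        dv1 += std::fabs(mu1 * dt + sdt * rng.norm());
        dv2 += std::fabs(mu2 * dt + sdt * rng.norm());
      } else {
        dv1 += mu1 * dt + sdt * rng.norm();
        dv2 += mu2 * dt + sdt * rng.norm();
      }
      double t = k * dt;
      double Bt = B[k - 1];
      if (model == 2) S = std::fabs(dv1) - std::fabs(dv2);
      else if (model == 4) S = dv1 - dv2;
      else if (model == 5) S = s1[i] * dv1 - s2[i] * dv2;
      else {
        double L1 = conf_lookup(conf, conf_dv_min, conf_dv_step, conf_t_step, dv1, t);
        double L2 = conf_lookup(conf, conf_dv_min, conf_dv_step, conf_t_step, dv2, t);
        S = (model == 6) ? (std::fabs(L1) - std::fabs(L2)) : (s1[i] * L1 - s2[i] * L2);
      }
      if (S >= Bt) { ch = 1; tb = 0; tdec = t; break; }
      if (S <= -Bt) { ch = 2; tb = 0; tdec = t; break; }
    }
    if (ch == 0)
      ch = (S == 0.0) ? ((rng.unif() < 0.5) ? 1 : 2) : (S > 0 ? 1 : 2);
    choice[i] = ch; term[i] = tb; dtime[i] = tdec;
  }
  return List::create(_["choice"] = choice, _["decision_time"] = dtime,
                      _["terminated_by"] = term);
}

// Epanechnikov bandwidth: Silverman-style rule with a floor of 2*dt
static double epan_bw(std::vector<double>& x, double dt) {
  size_t n = x.size();
  if (n < 2) return 2 * dt;
  double m = 0, s2 = 0;
  for (double v : x) m += v;
  m /= n;
  for (double v : x) s2 += (v - m) * (v - m);
  double s = std::sqrt(s2 / (n - 1));
  std::sort(x.begin(), x.end());
  double q1 = x[(size_t)(0.25 * (n - 1))], q3 = x[(size_t)(0.75 * (n - 1))];
  double iqr = (q3 - q1) / 1.34;
  double sig = std::min(s, iqr > 0 ? iqr : s);
  if (!(sig > 0)) sig = dt;
  return std::max(2 * dt, 2.34 * sig * std::pow((double)n, -0.2));
}

// Simulation-based negative log-likelihood of difficulty (choice, RT)
// data: for each condition, n_sim trials are simulated with a stream
// pinned by `seed` (common random numbers), and each data trial is scored
// by choice probability x Epanechnikov-smoothed RT density, floored.
// The non-decision mean only shifts simulated RTs, so it is profiled out:
// the NLL is evaluated on `tnd_grid` (the Gaussian non-decision jitter
// with SD tnd_sd is drawn once per simulated trial) and the minimizing
// value is returned alongside. Mirrors simulate_likelihood_table() +
// negative_log_likelihood(); used by the fitters.
// [[Rcpp::export]]
List cpp_difficulty_nll(int model,
                        NumericVector cond_c1, NumericVector cond_c2,
                        IntegerVector cond_s1, IntegerVector cond_s2,
                        int n_sim,
                        IntegerVector data_cond, IntegerVector data_choice,
                        NumericVector data_rt,
                        double kappa, double u, double a, double d,
                        double bmini, NumericVector tnd_grid, double tnd_sd,
                        double dt, double horizon, double floor_dens,
                        int seed,
                        NumericMatrix conf, double conf_dv_min,
                        double conf_dv_step, double conf_t_step) {
  int ncond = cond_c1.size();
  int ndata = data_cond.size();
  int ntnd = tnd_grid.size();
  std::vector<double> B = bound_table(u, a, d, dt, horizon);
  Xoshiro rng((uint64_t)seed);

  // group data rows by (condition, choice)
  std::vector<std::vector<int> > rows1(ncond), rows2(ncond);
  for (int i = 0; i < ndata; ++i) {
    int c = data_cond[i];
    if (c < 0 || c >= ncond) stop("data condition index out of range");
    if (data_choice[i] == 1) rows1[c].push_back(i);
    else rows2[c].push_back(i);
  }

  std::vector<double> nll(ntnd, 0.0);
  std::vector<double> rt1, rt2;
  rt1.reserve(n_sim); rt2.reserve(n_sim);
  for (int c = 0; c < ncond; ++c) {
    rt1.clear(); rt2.clear();
    for (int j = 0; j < n_sim; ++j) {
      TrialResult r = run_trial(model, cond_c1[c], cond_c2[c], cond_s1[c],
                                cond_s2[c], kappa, B, bmini, dt, horizon,
                                true, conf, conf_dv_min, conf_dv_step,
                                conf_t_step, rng);
      // RT before adding the non-decision mean (jitter included)
      double rt = r.dtime + tnd_sd * rng.norm();
      if (r.choice == 1) rt1.push_back(rt); else rt2.push_back(rt);
    }
    for (int side = 0; side < 2; ++side) {
      std::vector<double>& rts = side == 0 ? rt1 : rt2;
      std::vector<int>& rows = side == 0 ? rows1[c] : rows2[c];
      if (rows.empty()) continue;
      if (rts.empty()) {
        for (int g = 0; g < ntnd; ++g)
          nll[g] -= rows.size() * std::log(floor_dens);
        continue;
      }
      double p = (double)rts.size() / n_sim;
      double h = epan_bw(rts, dt);  // sorts rts
      double inv_nh = 1.0 / (rts.size() * h);
      for (int i : rows) {
        for (int g = 0; g < ntnd; ++g) {
          double x = data_rt[i] - tnd_grid[g];
          // rts sorted: restrict to the kernel window by binary search
          std::vector<double>::iterator lo =
            std::lower_bound(rts.begin(), rts.end(), x - h);
          std::vector<double>::iterator hi =
            std::upper_bound(rts.begin(), rts.end(), x + h);
          double dens = 0.0;
          for (std::vector<double>::iterator it = lo; it != hi; ++it) {
            double z = (x - *it) / h;
            dens += 0.75 * (1 - z * z);
          }
          dens *= p * inv_nh;
          nll[g] -= std::log(std::max(dens, floor_dens));
        }
      }
    }
  }
  int gbest = 0;
  for (int g = 1; g < ntnd; ++g) if (nll[g] < nll[gbest]) gbest = g;
  return List::create(_["nll"] = nll[gbest], _["tnd"] = tnd_grid[gbest],
                      _["nll_grid"] = NumericVector(nll.begin(), nll.end()));
}

// Choice-only negative log-likelihood for the controlled-duration
// paradigm (binomial per condition x duration cell), same CRN contract.
// tdur is the buffer-adjusted effective per-stimulus sampling time.
// [[Rcpp::export]]
double cpp_controlled_nll(int model,
                          NumericVector cond_c1, NumericVector cond_c2,
                          IntegerVector cond_s1, IntegerVector cond_s2,
                          NumericVector cond_tdur, int n_sim,
                          IntegerVector data_cond, IntegerVector data_choice,
                          double kappa, double u, double a, double d,
                          double dt, int seed) {
  int ncond = cond_c1.size();
  int ndata = data_cond.size();
  double tmax = 0;
  for (int c = 0; c < ncond; ++c) tmax = std::max(tmax, cond_tdur[c]);
  std::vector<double> B = bound_table(u, a, d, dt, tmax);
  Xoshiro rng((uint64_t)seed);
  double sdt = std::sqrt(dt);
  double eps = 1e-4;

  std::vector<double> p1(ncond);
  for (int c = 0; c < ncond; ++c) {
    double mu1 = kappa * cond_c1[c], mu2 = kappa * cond_c2[c];
    int nstep = (int)std::ceil(cond_tdur[c] / dt);
    int n1 = 0;
    for (int j = 0; j < n_sim; ++j) {
      double dv1 = 0, dv2 = 0, S = 0;
      int ch = 0;
      for (int k = 1; k <= nstep; ++k) {
        if (model == 4) {
          dv1 += std::fabs(mu1 * dt + sdt * rng.norm());
          dv2 += std::fabs(mu2 * dt + sdt * rng.norm());
        } else {
          dv1 += mu1 * dt + sdt * rng.norm();
          dv2 += mu2 * dt + sdt * rng.norm();
        }
        double Bt = B[k - 1];
        if (model == 2) S = std::fabs(dv1) - std::fabs(dv2);
        else if (model == 4) S = dv1 - dv2;
        else S = cond_s1[c] * dv1 - cond_s2[c] * dv2;
        if (S >= Bt) { ch = 1; break; }
        if (S <= -Bt) { ch = 2; break; }
      }
      if (ch == 0) ch = (S == 0.0) ? ((rng.unif() < 0.5) ? 1 : 2)
                                   : (S > 0 ? 1 : 2);
      if (ch == 1) ++n1;
    }
    double p = (double)n1 / n_sim;
    p1[c] = std::min(std::max(p, eps), 1.0 - eps);
  }
  double nll = 0.0;
  for (int i = 0; i < ndata; ++i) {
    int c = data_cond[i];
    if (c < 0 || c >= ncond) stop("data condition index out of range");
    nll -= std::log(data_choice[i] == 1 ? p1[c] : 1.0 - p1[c]);
  }
  return nll;
}
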