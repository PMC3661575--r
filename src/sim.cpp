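#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Behavior kinds: 0 = null actuator (dF/dt = 0), 1..4 = the four controllers.
// Parameter vector layout by kind:
//   1: theta_F, k_F
//   2: theta_A, k_A
//   3: theta_D, k_D
//   4: theta_SF, k_SF, theta_SD, k_SD, k_sigma, k_r

static inline double metab(double A, double F,
                           double kf, double kb, double kd) {
  return kf * F * A * A - kb * A * A * A - kd * A;
}

static inline double behav(int kind, const double* bp, double rmax,
                           double A, double F, double dA) {
  switch (kind) {
  case 1: return rmax * std::tanh(bp[1] * (bp[0] - F));
  case 2: return rmax * std::tanh(bp[1] * (bp[0] - A));
  case 3: return rmax * std::tanh(bp[1] * (bp[0] - dA));
  case 4: {
    double sig = 1.0 / (1.0 + std::exp(-bp[5] * (A - bp[4])));
    double BF  = rmax * std::tanh(bp[1] * (bp[0] - F));
    double BD  = rmax * std::tanh(bp[3] * (bp[2] - dA));
    return sig * BF + (1.0 - sig) * BD;
  }
  default: return 0.0;
  }
}

static inline void deriv(double A, double F, int kind, const double* bp,
                         double rmax, double kf, double kb, double kd,
                         double& dA, double& dF) {
  if (A < 0.0) A = 0.0;
  if (F < 0.0) F = 0.0;
  dA = metab(A, F, kf, kb, kd);
  dF = behav(kind, bp, rmax, A, F, dA);
}

// One classical RK4 step of the coupled (A, F) system.
static inline void rk4_step(double& A, double& F, double dt, int kind,
                            const double* bp, double rmax,
                            double kf, double kb, double kd) {
  double k1A, k1F, k2A, k2F, k3A, k3F, k4A, k4F;
  deriv(A, F, kind, bp, rmax, kf, kb, kd, k1A, k1F);
  deriv(A + 0.5 * dt * k1A, F + 0.5 * dt * k1F, kind, bp, rmax, kf, kb, kd,
        k2A, k2F);
  deriv(A + 0.5 * dt * k2A, F + 0.5 * dt * k2F, kind, bp, rmax, kf, kb, kd,
        k3A, k3F);
  deriv(A + dt * k3A, F + dt * k3F, kind, bp, rmax, kf, kb, kd, k4A, k4F);
  A += dt / 6.0 * (k1A + 2.0 * k2A + 2.0 * k3A + k4A);
  F += dt / 6.0 * (k1F + 2.0 * k2F + 2.0 * k3F + k4F);
  if (A < 0.0) A = 0.0;
  if (F < 0.0) F = 0.0;
}

// Outcome codes: 0 survived, 1 dead_low, 2 dead_high.
struct TrajOut {
  int outcome;
  double t_death;     // NA when survived
  double final_A, final_F;
  bool reached_steady;
};

// Integrate a single trajectory. Death boundaries are closed sets: contact
// counts as death. Crossing time is localized by linear interpolation
// within the step that crossed.
static TrajOut run_one(double A0, double F0, int kind, const double* bp,
                       double rmax, double kf, double kb, double kd,
                       double Alow, double Ahigh, double dt, double t_end,
                       double steady_tol,
                       std::vector<double>* ts, std::vector<double>* As,
                       std::vector<double>* Fs, int save_every) {
  TrajOut out;
  out.outcome = 0;
  out.t_death = NA_REAL;
  out.reached_steady = false;
  double A = A0, F = F0, t = 0.0;
  if (ts) { ts->push_back(t); As->push_back(A); Fs->push_back(F); }
  if (A <= Alow)  { out.outcome = 1; out.t_death = 0.0; }
  else if (A >= Ahigh) { out.outcome = 2; out.t_death = 0.0; }
  long nstep = (long)std::ceil(t_end / dt - 1e-9);
  for (long i = 0; i < nstep && out.outcome == 0; ++i) {
    double Aprev = A, tprev = t;
    double h = std::min(dt, t_end - t);
    rk4_step(A, F, h, kind, bp, rmax, kf, kb, kd);
    t = tprev + h;
    if (A <= Alow) {
      out.outcome = 1;
      double frac = (Aprev > Alow) ? (Aprev - Alow) / (Aprev - A) : 0.0;
      out.t_death = tprev + frac * h;
      A = Alow;
    } else if (A >= Ahigh) {
      out.outcome = 2;
      double frac = (Aprev < Ahigh) ? (Ahigh - Aprev) / (A - Aprev) : 0.0;
      out.t_death = tprev + frac * h;
      A = Ahigh;
    } else {
      double dA, dF;
      deriv(A, F, kind, bp, rmax, kf, kb, kd, dA, dF);
      if (std::fabs(dA) <= steady_tol && std::fabs(dF) <= steady_tol) {
        out.reached_steady = true;
      }
    }
    if (ts && (out.outcome != 0 || out.reached_steady ||
               ((i + 1) % save_every == 0) || i == nstep - 1)) {
      ts->push_back(t); As->push_back(A); Fs->push_back(F);
    }
    if (out.reached_steady) break;
  }
  out.final_A = A;
  out.final_F = F;
  return out;
}

// [[Rcpp::export]]
List sim_trajectory_cpp(double A0, double F0, int kind,
                        NumericVector bpar, double rmax,
                        double kf, double kb, double kd,
                        double Alow, double Ahigh,
                        double dt, double t_end, double steady_tol,
                        int save_every) {
  std::vector<double> ts, As, Fs;
  TrajOut o = run_one(A0, F0, kind, bpar.begin(), rmax, kf, kb, kd,
                      Alow, Ahigh, dt, t_end, steady_tol,
                      &ts, &As, &Fs, save_every);
  return List::create(
    _["time"] = wrap(ts), _["A"] = wrap(As), _["F"] = wrap(Fs),
    _["outcome"] = o.outcome, _["time_of_death"] = o.t_death,
    _["final_A"] = o.final_A, _["final_F"] = o.final_F,
    _["reached_steady"] = o.reached_steady);
}

// [[Rcpp::export]]
List sim_grid_cpp(NumericVector A0, NumericVector F0, int kind,
                  NumericVector bpar, double rmax,
                  double kf, double kb, double kd,
                  double Alow, double Ahigh,
                  double dt, double t_end, double steady_tol) {
  int n = A0.size();
  IntegerVector outcome(n);
  NumericVector t_death(n), finalA(n), finalF(n);
  LogicalVector steady(n);
  for (int i = 0; i < n; ++i) {
    TrajOut o = run_one(A0[i], F0[i], kind, bpar.begin(), rmax, kf, kb, kd,
                        Alow, Ahigh, dt, t_end, steady_tol,
                        nullptr, nullptr, nullptr, 0);
    outcome[i] = o.outcome;
    t_death[i] = o.t_death;
    finalA[i] = o.final_A;
    finalF[i] = o.final_F;
    steady[i] = o.reached_steady;
  }
  return List::create(_["outcome"] = outcome, _["time_of_death"] = t_death,
                      _["final_A"] = finalA, _["final_F"] = finalF,
                      _["reached_steady"] = steady);
}

// Resource gradient along the 1-D environment. grad_kind 0 = linear,
// 1 = logistic in x; gp = (x_min, x_max, F_lo, F_hi, steepness, midpoint).
static inline double gradF(double x, int grad_kind, const double* gp) {
  double u;
  if (grad_kind == 1) {
    u = 1.0 / (1.0 + std::exp(-gp[4] * (x - gp[5])));
  } else {
    u = (x - gp[0]) / (gp[1] - gp[0]);
  }
  return gp[2] + (gp[3] - gp[2]) * u;
}

// [[Rcpp::export]]
double resource_at_cpp(double x, int grad_kind, NumericVector gp) {
  return gradF(x, grad_kind, gp.begin());
}

// Step a 1-D population of agents. Alive agents read the local resource,
// compute the behavioral rate plus their fixed error bias, move one step
// up-gradient when the biased rate is non-negative (down-gradient
// otherwise), are clamped to the walls, and update A by one RK4 step of
// the metabolism at the local (position-fixed) resource level. Dead agents
// are frozen. Returns final states, per-agent reversal counts and
// snapshots of (x, A, status) every snap_every steps.
// [[Rcpp::export]]
List run_population_cpp(NumericVector x0, NumericVector A0,
                        NumericVector eps, IntegerVector status0,
                        int kind, NumericVector bpar, double rmax,
                        double kf, double kb, double kd,
                        double Alow, double Ahigh,
                        int grad_kind, NumericVector gp,
                        double v, double dt, double t_end, int n_steps,
                        int snap_every) {
  int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> A(A0.begin(), A0.end());
  std::vector<int> status(status0.begin(), status0.end());
  std::vector<int> dir(n, 0), rev(n, 0);
  const double* g = gp.begin();
  double xmin = g[0], xmax = g[1];

  if (n_steps <= 0) n_steps = (int)std::ceil(t_end / dt - 1e-9);
  int n_snap = (snap_every > 0) ? (n_steps / snap_every + 1) : 0;
  NumericMatrix snapX(n_snap, n), snapA(n_snap, n);
  IntegerMatrix snapS(n_snap, n);
  NumericVector snapT(n_snap);
  int si = 0;

  // initial death check (boundaries are closed)
  for (int i = 0; i < n; ++i) {
    if (status[i] == 0) {
      if (A[i] <= Alow) status[i] = 1;
      else if (A[i] >= Ahigh) status[i] = 2;
    }
  }
  if (n_snap > 0) {
    snapT[si] = 0.0;
    for (int i = 0; i < n; ++i) {
      snapX(si, i) = x[i]; snapA(si, i) = A[i]; snapS(si, i) = status[i];
    }
    ++si;
  }

  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) {
      if (status[i] != 0) continue;
      double F = gradF(x[i], grad_kind, g);
      double dA = metab(A[i], F, kf, kb, kd);
      double B = behav(kind, bpar.begin(), rmax, A[i], F, dA);
      int d = (B + eps[i] >= 0.0) ? 1 : -1;
      if (dir[i] != 0 && d != dir[i]) ++rev[i];
      dir[i] = d;
      x[i] += d * v * dt;
      if (x[i] < xmin) x[i] = xmin;
      if (x[i] > xmax) x[i] = xmax;
      // metabolite update at the (fixed) local resource level
      double k1 = metab(A[i], F, kf, kb, kd);
      double k2 = metab(std::max(A[i] + 0.5 * dt * k1, 0.0), F, kf, kb, kd);
      double k3 = metab(std::max(A[i] + 0.5 * dt * k2, 0.0), F, kf, kb, kd);
      double k4 = metab(std::max(A[i] + dt * k3, 0.0), F, kf, kb, kd);
      A[i] += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      if (A[i] < 0.0) A[i] = 0.0;
      if (A[i] <= Alow) { status[i] = 1; A[i] = Alow; }
      else if (A[i] >= Ahigh) { status[i] = 2; A[i] = Ahigh; }
    }
    if (n_snap > 0 && si < n_snap && (s % snap_every == 0)) {
      snapT[si] = s * dt;
      for (int i = 0; i < n; ++i) {
        snapX(si, i) = x[i]; snapA(si, i) = A[i]; snapS(si, i) = status[i];
      }
      ++si;
    }
  }
  if (n_snap > 0 && si < n_snap) {
    // n_steps not a multiple of snap_every: trim by recording final state
    snapT[si] = n_steps * dt;
    for (int i = 0; i < n; ++i) {
      snapX(si, i) = x[i]; snapA(si, i) = A[i]; snapS(si, i) = status[i];
    }
    ++si;
  }
  return List::create(
    _["x"] = wrap(x), _["A"] = wrap(A), _["status"] = wrap(status),
    _["reversals"] = wrap(rev),
    _["snap_time"] = snapT, _["snap_x"] = snapX, _["snap_A"] = snapA,
    _["snap_status"] = snapS, _["n_steps"] = n_steps);
}
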