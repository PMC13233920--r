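// Fast numerical core: CTRNN integration, coupled slow homeostatic (ADHP)
// dynamics, rhythm analysis of output traces, and bias-grid scans.
//
// Neuron index convention throughout: 0 = LP, 1 = PY, 2 = PD.
// Weight matrix W(i, j) is the connection from neuron i to neuron j.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const int NN = 3; // network size is fixed at three neurons

// Logistic output function; split form avoids overflow for large |x|.
static inline double sig(double x) {
  if (x >= 0.0) {
    double z = std::exp(-x);
    return 1.0 / (1.0 + z);
  }
  double z = std::exp(x);
  return z / (1.0 + z);
}

struct Net {
  double tau[NN];
  double theta[NN];
  double W[NN][NN]; // W[i][j]: i -> j

  void deriv(const double *y, double *dy) const {
    double o[NN];
    for (int i = 0; i < NN; ++i) o[i] = sig(y[i] + theta[i]);
    for (int j = 0; j < NN; ++j) {
      double inp = 0.0;
      for (int i = 0; i < NN; ++i) inp += W[i][j] * o[i];
      dy[j] = (-y[j] + inp) / tau[j];
    }
  }

  // One fixed step of the fast subsystem with frozen parameters.
  // method: 0 = RK4, 1 = forward Euler.
  void step(double *y, double dt, int method) const {
    double k1[NN], k2[NN], k3[NN], k4[NN], tmp[NN];
    deriv(y, k1);
    if (method == 1) {
      for (int j = 0; j < NN; ++j) y[j] += dt * k1[j];
      return;
    }
    for (int j = 0; j < NN; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
    deriv(tmp, k2);
    for (int j = 0; j < NN; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
    deriv(tmp, k3);
    for (int j = 0; j < NN; ++j) tmp[j] = y[j] + dt * k3[j];
    deriv(tmp, k4);
    for (int j = 0; j < NN; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
  }
};

static Net make_net(const NumericVector &tau, const NumericVector &theta,
                    const NumericMatrix &w) {
  Net net;
  for (int i = 0; i < NN; ++i) {
    net.tau[i] = tau[i];
    net.theta[i] = theta[i];
    for (int j = 0; j < NN; ++j) net.W[i][j] = w(i, j);
  }
  return net;
}

static void check_finite(const double *y, long step, const char *what) {
  for (int i = 0; i < NN; ++i) {
    if (!std::isfinite(y[i]))
      stop("integration failure: non-finite %s for neuron %d at step %ld",
           what, i + 1, step);
  }
}

// Piecewise-linear homeostatic drive: positive below the target range,
// zero inside it, negative above.
static inline double rho_fun(double x, double lb, double ub) {
  if (x < lb) return lb - x;
  if (x > ub) return ub - x;
  return 0.0;
}

// [[Rcpp::export]]
List cpp_integrate(NumericVector tau, NumericVector theta, NumericMatrix w,
                   NumericVector y0, double dt, double transient,
                   double record, int method) {
  Net net = make_net(tau, theta, w);
  double y[NN];
  for (int i = 0; i < NN; ++i) y[i] = y0[i];

  long n_tr = (long)std::llround(transient / dt);
  long n_rec = (long)std::llround(record / dt);

  for (long k = 0; k < n_tr; ++k) {
    net.step(y, dt, method);
    if ((k & 1023) == 0) check_finite(y, k, "state");
  }
  check_finite(y, n_tr, "state");

  NumericVector tt(n_rec + 1);
  NumericMatrix ym(n_rec + 1, NN), om(n_rec + 1, NN);
  for (long k = 0; k <= n_rec; ++k) {
    tt[k] = transient + k * dt;
    for (int i = 0; i < NN; ++i) {
      ym(k, i) = y[i];
      om(k, i) = sig(y[i] + net.theta[i]);
    }
    if (k < n_rec) {
      net.step(y, dt, method);
      if ((k & 1023) == 0) check_finite(y, n_tr + k, "state");
    }
  }
  check_finite(y, n_tr + n_rec, "state");
  return List::create(_["time"] = tt, _["y"] = ym, _["o"] = om);
}

// ---------------------------------------------------------------------------
// Rhythm analysis of an output trace sampled on a uniform grid.
// ---------------------------------------------------------------------------

struct Analysis {
  int status[NN];    // 0 silent, 1 tonic, 2 bursting
  int n_bursting;
  double period;     // NA when undefined
  bool osc;
  bool one_per_cycle;
  bool tie;
  bool crit[3];      // gap, PY_S < LP_E, LP_E < PY_E
  bool pyloric;
  double duty[NN];
  double phase[NN];  // burst-start phase relative to PD burst start
  double obar[NN];
  double ev[2 * NN]; // event phases: LP_S, LP_E, PY_S, PY_E, PD_S, PD_E
  bool events_ok;
};

// All threshold comparisons are strict: a sample exactly at threshold
// counts as below (not bursting).
static void find_crossings(const double *t, const double *o, int n, int stride,
                           double thr, std::vector<double> &ups,
                           std::vector<double> &downs) {
  for (int k = 0; k + 1 < n; ++k) {
    double a = o[(size_t)k * stride], b = o[(size_t)(k + 1) * stride];
    if (a <= thr && b > thr)
      ups.push_back(t[k] + (t[k + 1] - t[k]) * (thr - a) / (b - a));
    else if (a > thr && b <= thr)
      downs.push_back(t[k] + (t[k + 1] - t[k]) * (thr - a) / (b - a));
  }
}

// Trapezoidal mean of a sampled series over [a, b] (sub-sample endpoints by
// linear interpolation).
static double trapz_mean(const double *t, const double *o, int n, int stride,
                         double a, double b) {
  if (b <= a) return NA_REAL;
  double dt = t[1] - t[0];
  double area = 0.0;
  int k0 = (int)std::floor((a - t[0]) / dt);
  int k1 = (int)std::floor((b - t[0]) / dt);
  if (k0 < 0) k0 = 0;
  if (k1 > n - 1) k1 = n - 1;
  auto val = [&](double tq) {
    int k = (int)std::floor((tq - t[0]) / dt);
    if (k < 0) k = 0;
    if (k >= n - 1) return o[(size_t)(n - 1) * stride];
    double f = (tq - t[k]) / dt;
    return o[(size_t)k * stride] * (1 - f) + o[(size_t)(k + 1) * stride] * f;
  };
  double prev_t = a, prev_v = val(a);
  for (int k = k0 + 1; k <= k1; ++k) {
    if (t[k] <= a || t[k] >= b) continue;
    area += 0.5 * (prev_v + o[(size_t)k * stride]) * (t[k] - prev_t);
    prev_t = t[k];
    prev_v = o[(size_t)k * stride];
  }
  area += 0.5 * (prev_v + val(b)) * (b - prev_t);
  return area / (b - a);
}

// Estimate the period from successive upward threshold crossings: at least
// three consecutive inter-crossing intervals must agree within rel_tol.
static double period_from_ups(const std::vector<double> &ups, double rel_tol) {
  int m = (int)ups.size();
  if (m < 4) return NA_REAL;
  // walk back from the last interval while intervals stay mutually consistent
  int used = 0;
  double sum = 0.0;
  double ref = ups[m - 1] - ups[m - 2];
  for (int k = m - 1; k >= 1; --k) {
    double d = ups[k] - ups[k - 1];
    double mean_so_far = (used > 0) ? sum / used : ref;
    if (std::fabs(d - mean_so_far) > rel_tol * mean_so_far) break;
    sum += d;
    ++used;
    if (used >= 5) break; // average at most the trailing five cycles
  }
  if (used < 3) return NA_REAL;
  return sum / used;
}

static Analysis analyze_core(const double *t, const double *o, int n,
                             double thr, double nonosc_window, double rel_tol,
                             double tie_tol, double min_gap) {
  Analysis A;
  A.period = NA_REAL;
  A.osc = false;
  A.one_per_cycle = false;
  A.tie = false;
  A.pyloric = false;
  A.events_ok = false;
  for (int i = 0; i < NN; ++i) {
    A.duty[i] = NA_REAL;
    A.phase[i] = NA_REAL;
    A.obar[i] = NA_REAL;
  }
  for (int e = 0; e < 2 * NN; ++e) A.ev[e] = NA_REAL;
  for (int c = 0; c < 3; ++c) A.crit[c] = false;

  std::vector<double> ups[NN], downs[NN];
  A.n_bursting = 0;
  for (int i = 0; i < NN; ++i) {
    find_crossings(t, o + i * (size_t)n, n, 1, thr, ups[i], downs[i]);
    bool above = false, below = false;
    for (int k = 0; k < n; ++k) {
      if (o[i * (size_t)n + k] > thr) above = true; else below = true;
      if (above && below) break;
    }
    if (above && below) A.status[i] = 2;
    else if (above) A.status[i] = 1;
    else A.status[i] = 0;
    if (!ups[i].empty() && !downs[i].empty()) ++A.n_bursting;
  }

  // period from a reference neuron: LP preferred, else any bursting neuron
  int ref = -1;
  const int pref[NN] = {0, 1, 2};
  for (int q = 0; q < NN; ++q) {
    int i = pref[q];
    double T = period_from_ups(ups[i], rel_tol);
    if (R_finite(T)) { ref = i; A.period = T; break; }
  }
  A.osc = R_finite(A.period);

  double t_end = t[n - 1];
  if (!A.osc) {
    double w0 = t_end - nonosc_window;
    if (w0 < t[0]) w0 = t[0];
    for (int i = 0; i < NN; ++i)
      A.obar[i] = trapz_mean(t, o + i * (size_t)n, n, 1, w0, t_end);
    return A;
  }

  double T = A.period;
  // the cycle is folded between two actual consecutive burst onsets of the
  // reference neuron (the estimated period only validates the pair), which
  // is robust to cycle-to-cycle jitter in the period estimate
  auto last_cycle = [&](const std::vector<double> &u, double &a,
                        double &b) -> bool {
    for (int k = (int)u.size() - 2; k >= 0; --k) {
      double Tc = u[k + 1] - u[k];
      if (std::fabs(Tc - T) <= 0.05 * T) {
        a = u[k];
        b = u[k + 1];
        return true;
      }
    }
    return false;
  };
  double anchor = NA_REAL, cyc_end = NA_REAL;
  bool have_lp_cycle = !ups[0].empty() && last_cycle(ups[0], anchor, cyc_end);
  double aa = NA_REAL, ab = NA_REAL;
  if (have_lp_cycle) {
    aa = anchor;
    ab = cyc_end;
  } else {
    last_cycle(ups[ref], aa, ab); // averaging fallback: any bursting neuron
  }
  if (R_finite(aa)) {
    for (int i = 0; i < NN; ++i)
      A.obar[i] = trapz_mean(t, o + i * (size_t)n, n, 1, aa, ab);
  } else {
    double w0 = t_end - nonosc_window;
    if (w0 < t[0]) w0 = t[0];
    for (int i = 0; i < NN; ++i)
      A.obar[i] = trapz_mean(t, o + i * (size_t)n, n, 1, w0, t_end);
  }

  if (!have_lp_cycle) return A; // no LP-anchored cycle: events undefined

  // fold one cycle [anchor, cyc_end) and locate each neuron's events
  double Tc = cyc_end - anchor;
  double up_ph[NN], down_ph[NN];
  bool ok = true;
  for (int i = 0; i < NN; ++i) {
    int cu = 0, cd = 0;
    for (double c : ups[i])
      if (c >= anchor - 1e-12 && c < cyc_end - 1e-12) {
        up_ph[i] = (c - anchor) / Tc;
        ++cu;
      }
    for (double c : downs[i])
      if (c >= anchor - 1e-12 && c < cyc_end - 1e-12) {
        down_ph[i] = (c - anchor) / Tc;
        ++cd;
      }
    if (cu != 1 || cd != 1) ok = false;
  }
  A.one_per_cycle = ok;
  if (!ok) return A;
  up_ph[0] = 0.0; // LP start is the anchor by construction
  T = Tc;         // event phases, ties and duties use the folded cycle

  A.ev[0] = up_ph[0];   // LP_S
  A.ev[1] = down_ph[0]; // LP_E
  A.ev[2] = up_ph[1];   // PY_S
  A.ev[3] = down_ph[1]; // PY_E
  A.ev[4] = up_ph[2];   // PD_S
  A.ev[5] = down_ph[2]; // PD_E
  A.events_ok = true;

  // simultaneous events within the time resolution make ordering undefined
  double tol_ph = tie_tol / T;
  for (int a = 0; a < 2 * NN; ++a)
    for (int b = a + 1; b < 2 * NN; ++b)
      if (std::fabs(A.ev[a] - A.ev[b]) < tol_ph) A.tie = true;

  // criteria on the folded cycle (left false on a tie: the ordering is
  // undefined, so the rhythm is conservatively non-pyloric):
  // gap: neither PY nor PD burst wraps phase 0 (both silent at LP onset),
  // with an optional minimum silent-gap duration before LP onset
  if (!A.tie) {
    bool gap = true;
    for (int i = 1; i < NN; ++i) {
      if (up_ph[i] >= down_ph[i]) gap = false;          // burst wraps onset
      else if (min_gap > 0.0 && (1.0 - down_ph[i]) * T < min_gap) gap = false;
    }
    A.crit[0] = gap;
    A.crit[1] = up_ph[1] < down_ph[0];  // PY_S before LP_E
    A.crit[2] = down_ph[0] < down_ph[1]; // LP_E before PY_E
  }

  for (int i = 0; i < NN; ++i) {
    double d = down_ph[i] - up_ph[i];
    if (d <= 0) d += 1.0;
    A.duty[i] = d;
    double ph = up_ph[i] - up_ph[2];
    if (ph < 0) ph += 1.0;
    A.phase[i] = ph;
  }

  A.pyloric = (A.n_bursting == 3) && A.one_per_cycle && !A.tie &&
              A.crit[0] && A.crit[1] && A.crit[2];
  return A;
}

static List analysis_to_list(const Analysis &A) {
  CharacterVector lab = CharacterVector::create("LP", "PY", "PD");
  IntegerVector status(NN);
  NumericVector duty(NN), phase(NN), obar(NN);
  for (int i = 0; i < NN; ++i) {
    status[i] = A.status[i];
    duty[i] = A.duty[i];
    phase[i] = A.phase[i];
    obar[i] = A.obar[i];
  }
  status.names() = lab;
  duty.names() = lab;
  phase.names() = lab;
  obar.names() = lab;
  NumericVector ev(2 * NN);
  for (int e = 0; e < 2 * NN; ++e) ev[e] = A.ev[e];
  ev.names() = CharacterVector::create("LP_S", "LP_E", "PY_S", "PY_E",
                                       "PD_S", "PD_E");
  LogicalVector crit = LogicalVector::create(
      _["gap"] = A.crit[0], _["PYS_before_LPE"] = A.crit[1],
      _["LPE_before_PYE"] = A.crit[2]);
  return List::create(
      _["status"] = status, _["n_bursting"] = A.n_bursting,
      _["period"] = A.period, _["oscillatory"] = A.osc,
      _["one_per_cycle"] = A.one_per_cycle, _["tie"] = A.tie,
      _["events"] = ev, _["criteria"] = crit, _["pyloric"] = A.pyloric,
      _["duty"] = duty, _["phase"] = phase, _["obar"] = obar);
}

// [[Rcpp::export]]
List cpp_analyze(NumericVector time, NumericMatrix o, double threshold,
                 double nonosc_window, double rel_tol, double tie_tol,
                 double min_gap) {
  int n = o.nrow();
  if (n < 2) stop("trajectory too short to analyze");
  std::vector<double> t(time.begin(), time.end());
  std::vector<double> oc((size_t)n * NN);
  for (int i = 0; i < NN; ++i)
    for (int k = 0; k < n; ++k) oc[(size_t)i * n + k] = o(k, i);
  Analysis A = analyze_core(t.data(), oc.data(), n, threshold, nonosc_window,
                            rel_tol, tie_tol, min_gap);
  return analysis_to_list(A);
}

// ---------------------------------------------------------------------------
// Coupled fast/slow simulation: ADHP on a subset of biases.
// ---------------------------------------------------------------------------

struct Window {
  std::vector<double> buf;
  size_t cap = 0, count = 0, head = 0;
  double sum = 0.0;

  void init(size_t capacity) {
    cap = capacity;
    buf.assign(cap > 0 ? cap : 1, 0.0);
    count = 0;
    head = 0;
    sum = 0.0;
  }
  // push a sample, return current average (over available samples while
  // the window is still warming up)
  double push(double x) {
    if (cap == 0) return x; // zero-length window: instantaneous detection
    if (count == cap) sum -= buf[head];
    else ++count;
    buf[head] = x;
    sum += x;
    head = (head + 1) % cap;
    return sum / count;
  }
};

struct AdhpSim {
  Net net;
  int nreg = 0;
  int reg[NN];
  double LB[NN], UB[NN], s[NN], tt[NN];
  Window win[NN];
  double bias_min = -16.0, bias_max = 16.0;
  double dt = 0.01;
  int method = 0;
  double y[NN];
  double t = 0.0;

  void setup(const Net &n0, const IntegerVector &regv, const NumericVector &lb,
             const NumericVector &ub, const NumericVector &sv,
             const NumericVector &ttv, const NumericVector &y0, double dt_,
             int method_, double bmin, double bmax) {
    net = n0;
    dt = dt_;
    method = method_;
    bias_min = bmin;
    bias_max = bmax;
    nreg = regv.size();
    for (int r = 0; r < nreg; ++r) {
      reg[r] = regv[r];
      LB[r] = lb[r];
      UB[r] = ub[r];
      s[r] = sv[r];
      tt[r] = ttv[r];
      win[r].init((size_t)std::llround(sv[r] / dt_));
    }
    for (int i = 0; i < NN; ++i) y[i] = y0[i];
    t = 0.0;
  }

  // advance one step; returns max |rho| drive across regulated dims
  double step_once(double *dy_out) {
    // slow update from the windowed average of the current outputs
    double drive = 0.0;
    for (int r = 0; r < nreg; ++r) {
      int i = reg[r];
      double oi = sig(y[i] + net.theta[i]);
      double avg = win[r].push(oi);
      double rho = rho_fun(avg, LB[r], UB[r]);
      double th = net.theta[i] + dt * rho / tt[r];
      if (th < bias_min) th = bias_min;
      if (th > bias_max) th = bias_max;
      net.theta[i] = th;
      double ad = std::fabs(rho);
      if (ad > drive) drive = ad;
    }
    // fast update with parameters frozen over the step
    if (dy_out) net.deriv(y, dy_out);
    net.step(y, dt, method);
    t += dt;
    return drive;
  }

  // true when nothing can change any more: fast states at a fixed point and
  // every regulated bias either undriven or pinned at a bound pushing out
  bool frozen() {
    double dy[NN];
    net.deriv(y, dy);
    for (int i = 0; i < NN; ++i)
      if (std::fabs(dy[i]) > 1e-9) return false;
    for (int r = 0; r < nreg; ++r) {
      int i = reg[r];
      double oi = sig(y[i] + net.theta[i]);
      double rho = rho_fun(oi, LB[r], UB[r]); // windows have equilibrated too
      if (rho == 0.0) continue;
      if (rho > 0.0 && net.theta[i] >= bias_max - 1e-12) continue;
      if (rho < 0.0 && net.theta[i] <= bias_min + 1e-12) continue;
      return false;
    }
    return true;
  }
};

// [[Rcpp::export]]
List cpp_adhp_simulate(NumericVector tau, NumericVector theta0,
                       NumericMatrix w, NumericVector y0, IntegerVector reg,
                       NumericVector lb, NumericVector ub, NumericVector s,
                       NumericVector tau_theta, double dt, double duration,
                       double record_every, double bias_min, double bias_max,
                       int method, bool early_exit) {
  Net net = make_net(tau, theta0, w);
  AdhpSim sim;
  sim.setup(net, reg, lb, ub, s, tau_theta, y0, dt, method, bias_min,
            bias_max);

  long n_steps = (long)std::llround(duration / dt);
  long rec_every = (long)std::llround(record_every / dt);
  if (rec_every < 1) rec_every = 1;
  long n_rec = n_steps / rec_every;

  NumericVector tt(n_rec + 1);
  NumericMatrix th(n_rec + 1, NN), om(n_rec + 1, NN);
  long ri = 0;
  auto record = [&](long k) {
    tt[ri] = k * dt;
    for (int i = 0; i < NN; ++i) {
      th(ri, i) = sim.net.theta[i];
      om(ri, i) = sig(sim.y[i] + sim.net.theta[i]);
    }
    ++ri;
  };
  record(0);

  bool stopped = false;
  long k = 0;
  long warm_steps = 0;
  for (int r = 0; r < sim.nreg; ++r) {
    long wsteps = (long)std::llround(s[r] / dt);
    if (wsteps > warm_steps) warm_steps = wsteps;
  }
  int frozen_checks = 0;
  for (k = 1; k <= n_steps; ++k) {
    sim.step_once(nullptr);
    if ((k & 2047) == 0) {
      check_finite(sim.y, k, "state");
      if (early_exit && k > warm_steps + 2048) {
        if (sim.frozen()) ++frozen_checks; else frozen_checks = 0;
        if (frozen_checks >= 2) { stopped = true; }
      }
    }
    if (k % rec_every == 0) record(k);
    if (stopped) break;
  }
  check_finite(sim.y, k, "state");
  if (stopped) {
    // system is exactly frozen: remaining samples equal the current one
    long k0 = (ri > 0) ? (long)std::llround(tt[ri - 1] / dt) : 0;
    for (long kk = k0 + rec_every; kk <= n_steps; kk += rec_every) record(kk);
  }

  NumericVector yfin(NN), thfin(NN);
  for (int i = 0; i < NN; ++i) {
    yfin[i] = sim.y[i];
    thfin[i] = sim.net.theta[i];
  }
  CharacterVector lab = CharacterVector::create("LP", "PY", "PD");
  yfin.names() = lab;
  thfin.names() = lab;
  return List::create(_["time"] = tt, _["theta"] = th, _["o"] = om,
                      _["y_final"] = yfin, _["theta_final"] = thfin,
                      _["terminated_early"] = stopped);
}

// ---------------------------------------------------------------------------
// ADHP recovery probe: equilibrate, regulate for `duration`, then freeze the
// parameters and analyze the resulting rhythm. Used in bulk by the
// prediction-versus-simulation comparisons.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_adhp_recover(NumericVector tau, NumericVector theta0,
                      NumericMatrix w, NumericVector y0, IntegerVector reg,
                      NumericVector lb, NumericVector ub, NumericVector s,
                      NumericVector tau_theta, double dt, double equil,
                      double duration, double bias_min, double bias_max,
                      int method, bool early_exit, double an_transient,
                      double an_record, double threshold,
                      double nonosc_window, double rel_tol, double tie_tol,
                      double min_gap) {
  Net net = make_net(tau, theta0, w);
  double y[NN];
  for (int i = 0; i < NN; ++i) y[i] = y0[i];
  long n_eq = (long)std::llround(equil / dt);
  for (long k = 0; k < n_eq; ++k) {
    net.step(y, dt, method);
    if ((k & 2047) == 0) check_finite(y, k, "state");
  }
  check_finite(y, n_eq, "state");

  AdhpSim sim;
  NumericVector yv(NN);
  for (int i = 0; i < NN; ++i) yv[i] = y[i];
  sim.setup(net, reg, lb, ub, s, tau_theta, yv, dt, method, bias_min,
            bias_max);
  long n_steps = (long)std::llround(duration / dt);
  long warm_steps = 0;
  for (int r = 0; r < sim.nreg; ++r) {
    long wsteps = (long)std::llround(s[r] / dt);
    if (wsteps > warm_steps) warm_steps = wsteps;
  }
  int frozen_checks = 0;
  for (long k = 1; k <= n_steps; ++k) {
    sim.step_once(nullptr);
    if ((k & 2047) == 0) {
      check_finite(sim.y, k, "state");
      if (early_exit && k > warm_steps + 2048) {
        if (sim.frozen()) ++frozen_checks; else frozen_checks = 0;
        if (frozen_checks >= 2) break;
      }
    }
  }

  // frozen-parameter rhythm at the post-regulation biases
  Net fnet = sim.net;
  double yy[NN];
  for (int i = 0; i < NN; ++i) yy[i] = sim.y[i];
  long n_tr = (long)std::llround(an_transient / dt);
  long n_rec = (long)std::llround(an_record / dt);
  for (long k = 0; k < n_tr; ++k) fnet.step(yy, dt, method);
  check_finite(yy, n_tr, "state");
  std::vector<double> t(n_rec + 1), oc((size_t)(n_rec + 1) * NN);
  for (long k = 0; k <= n_rec; ++k) {
    t[k] = k * dt;
    for (int i = 0; i < NN; ++i)
      oc[(size_t)i * (n_rec + 1) + k] = sig(yy[i] + fnet.theta[i]);
    if (k < n_rec) fnet.step(yy, dt, method);
  }
  check_finite(yy, n_tr + n_rec, "state");
  Analysis A = analyze_core(t.data(), oc.data(), (int)n_rec + 1, threshold,
                            nonosc_window, rel_tol, tie_tol, min_gap);
  NumericVector thfin(NN);
  for (int i = 0; i < NN; ++i) thfin[i] = fnet.theta[i];
  thfin.names() = CharacterVector::create("LP", "PY", "PD");
  List out = analysis_to_list(A);
  out["theta_final"] = thfin;
  return out;
}

// ---------------------------------------------------------------------------
// Grid scan over a bias subspace: per cell, equilibrate, record, analyze.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_scan(NumericVector tau, NumericVector theta_base, NumericMatrix w,
              IntegerVector axes, List grid_values, NumericVector y0,
              double dt, double transient, double record, double threshold,
              double nonosc_window, double rel_tol, double tie_tol,
              double min_gap, int method) {
  int nd = axes.size();
  std::vector<std::vector<double>> vals(nd);
  long ncell = 1;
  for (int d = 0; d < nd; ++d) {
    NumericVector v = grid_values[d];
    vals[d].assign(v.begin(), v.end());
    ncell *= (long)vals[d].size();
  }

  NumericMatrix obar(ncell, NN);
  NumericVector period(ncell);
  LogicalVector osc(ncell), pyl(ncell), opc(ncell), tie(ncell);
  IntegerVector nb(ncell);
  IntegerVector dyn(ncell); // 0 fixed, 1 oscillatory, 2 unclassified

  long n_tr = (long)std::llround(transient / dt);
  long n_rec = (long)std::llround(record / dt);
  std::vector<double> t(n_rec + 1), oc((size_t)(n_rec + 1) * NN);
  for (long k = 0; k <= n_rec; ++k) t[k] = k * dt;

  std::vector<long> idx(nd, 0);
  for (long c = 0; c < ncell; ++c) {
    Net net = make_net(tau, theta_base, w);
    for (int d = 0; d < nd; ++d) net.theta[axes[d]] = vals[d][idx[d]];
    double y[NN];
    for (int i = 0; i < NN; ++i) y[i] = y0[i];
    bool bad = false;
    for (long k = 0; k < n_tr; ++k) {
      net.step(y, dt, method);
      if ((k & 2047) == 0) {
        for (int i = 0; i < NN; ++i)
          if (!std::isfinite(y[i])) { bad = true; break; }
        if (bad) break;
      }
    }
    for (int i = 0; i < NN; ++i)
      if (!std::isfinite(y[i])) bad = true;
    if (bad) {
      for (int i = 0; i < NN; ++i) obar(c, i) = NA_REAL;
      period[c] = NA_REAL;
      osc[c] = NA_LOGICAL;
      pyl[c] = NA_LOGICAL;
      opc[c] = NA_LOGICAL;
      tie[c] = NA_LOGICAL;
      nb[c] = NA_INTEGER;
      dyn[c] = NA_INTEGER;
    } else {
      // fixed-point shortcut: skip recording when the state has settled
      double dy[NN];
      net.deriv(y, dy);
      double m = 0.0;
      for (int i = 0; i < NN; ++i) m = std::max(m, std::fabs(dy[i]));
      if (m < 1e-10) {
        for (int i = 0; i < NN; ++i) obar(c, i) = sig(y[i] + net.theta[i]);
        period[c] = NA_REAL;
        osc[c] = false;
        pyl[c] = false;
        opc[c] = false;
        tie[c] = false;
        nb[c] = 0;
        dyn[c] = 0;
      } else {
        for (long k = 0; k <= n_rec; ++k) {
          for (int i = 0; i < NN; ++i)
            oc[(size_t)i * (n_rec + 1) + k] = sig(y[i] + net.theta[i]);
          if (k < n_rec) net.step(y, dt, method);
        }
        Analysis A = analyze_core(t.data(), oc.data(), (int)n_rec + 1,
                                  threshold, nonosc_window, rel_tol, tie_tol,
                                  min_gap);
        for (int i = 0; i < NN; ++i) obar(c, i) = A.obar[i];
        period[c] = A.period;
        osc[c] = A.osc;
        pyl[c] = A.pyloric;
        opc[c] = A.one_per_cycle;
        tie[c] = A.tie;
        nb[c] = A.n_bursting;
        if (A.osc) {
          dyn[c] = 1;
        } else {
          // neither a detected rhythm nor a settled fixed point means the
          // cell's trailing-window averages are not asymptotic quantities
          net.deriv(y, dy);
          double m2 = 0.0;
          for (int i = 0; i < NN; ++i) m2 = std::max(m2, std::fabs(dy[i]));
          dyn[c] = (m2 > 1e-8) ? 2 : 0;
        }
      }
    }
    // advance multi-index (first axis fastest, matching expand.grid)
    for (int d = 0; d < nd; ++d) {
      if (++idx[d] < (long)vals[d].size()) break;
      idx[d] = 0;
    }
    if ((c & 255) == 0) Rcpp::checkUserInterrupt();
  }
  colnames(obar) = CharacterVector::create("LP", "PY", "PD");
  return List::create(_["obar"] = obar, _["period"] = period,
                      _["oscillatory"] = osc, _["pyloric"] = pyl,
                      _["one_per_cycle"] = opc, _["tie"] = tie,
                      _["n_bursting"] = nb, _["dynamics"] = dyn);
}
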