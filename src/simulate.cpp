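// Periodic steady-beat integrator for the lumped-parameter LV-aorta circuit.
//
// State y = (V_LV [uL], P_Ao [mmHg]). The LV follows a time-varying linear
// elastance P_LV = E(t) (V_LV - V_LV,d); both valves are resistive diodes and
// the aorta is a single RC compartment drained by R_art into a constant
// capillary pressure. Integration is adaptive Dormand-Prince 5(4); beats are
// repeated from a fixed initial state until the sampled beat is periodic.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Params {
  double r_mv, r_av, r_art, e_es, e_ed, t_s, t_e, v_lv_d, c_ao;
  double p_la, p_cap, t_cycle;
};

// Two-piece cosine ramp: E_ed at t=0, E_es at t=T_s, back to E_ed at t=T_e,
// constant E_ed for the rest of the cycle. Continuous everywhere.
static inline double elastance_at(double t, const Params& p) {
  double tau = t - p.t_cycle * std::floor(t / p.t_cycle);
  if (tau < p.t_s)
    return p.e_ed + (p.e_es - p.e_ed) * 0.5 * (1.0 - std::cos(M_PI * tau / p.t_s));
  if (tau < p.t_e)
    return p.e_ed + (p.e_es - p.e_ed) * 0.5 *
      (1.0 + std::cos(M_PI * (tau - p.t_s) / (p.t_e - p.t_s)));
  return p.e_ed;
}

static inline void rhs(double t, const double y[2], double dy[2], const Params& p) {
  double p_lv = elastance_at(t, p) * (y[0] - p.v_lv_d);
  double q_mv = (p.p_la - p_lv) / p.r_mv; if (q_mv < 0) q_mv = 0;
  double q_av = (p_lv - y[1]) / p.r_av;  if (q_av < 0) q_av = 0;
  double q_sys = (y[1] - p.p_cap) / p.r_art;
  dy[0] = q_mv - q_av;
  dy[1] = (q_av - q_sys) / p.c_ao;
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0/5, c3 = 3.0/10, c4 = 4.0/5, c5 = 8.0/9;
static const double a21 = 1.0/5;
static const double a31 = 3.0/40, a32 = 9.0/40;
static const double a41 = 44.0/45, a42 = -56.0/15, a43 = 32.0/9;
static const double a51 = 19372.0/6561, a52 = -25360.0/2187, a53 = 64448.0/6561,
                    a54 = -212.0/729;
static const double a61 = 9017.0/3168, a62 = -355.0/33, a63 = 46732.0/5247,
                    a64 = 49.0/176, a65 = -5103.0/18656;
static const double b1 = 35.0/384, b3 = 500.0/1113, b4 = 125.0/192,
                    b5 = -2187.0/6784, b6 = 11.0/84;
// 4th-order embedded weights
static const double e1 = 5179.0/57600, e3 = 7571.0/16695, e4 = 393.0/640,
                    e5 = -92097.0/339200, e6 = 187.0/2100, e7 = 1.0/40;

// Integrate y over [t0, t1]; returns false if the state goes non-finite.
static bool integrate_segment(double t0, double t1, double y[2],
                              const Params& p, double rtol, double atol,
                              double& hstart) {
  double t = t0, h = hstart;
  double k1[2], k2[2], k3[2], k4[2], k5[2], k6[2], k7[2], ytmp[2], y5[2];
  if (h <= 0 || h > t1 - t0) h = t1 - t0;
  int iter = 0;
  rhs(t, y, k1, p);
  while (t < t1) {
    if (++iter > 100000) return false;
    if (t + h > t1) h = t1 - t;
    ytmp[0] = y[0] + h*a21*k1[0]; ytmp[1] = y[1] + h*a21*k1[1];
    rhs(t + c2*h, ytmp, k2, p);
    for (int i = 0; i < 2; ++i) ytmp[i] = y[i] + h*(a31*k1[i] + a32*k2[i]);
    rhs(t + c3*h, ytmp, k3, p);
    for (int i = 0; i < 2; ++i) ytmp[i] = y[i] + h*(a41*k1[i] + a42*k2[i] + a43*k3[i]);
    rhs(t + c4*h, ytmp, k4, p);
    for (int i = 0; i < 2; ++i)
      ytmp[i] = y[i] + h*(a51*k1[i] + a52*k2[i] + a53*k3[i] + a54*k4[i]);
    rhs(t + c5*h, ytmp, k5, p);
    for (int i = 0; i < 2; ++i)
      ytmp[i] = y[i] + h*(a61*k1[i] + a62*k2[i] + a63*k3[i] + a64*k4[i] + a65*k5[i]);
    rhs(t + h, ytmp, k6, p);
    for (int i = 0; i < 2; ++i)
      y5[i] = y[i] + h*(b1*k1[i] + b3*k3[i] + b4*k4[i] + b5*k5[i] + b6*k6[i]);
    rhs(t + h, y5, k7, p);

    double err = 0.0;
    for (int i = 0; i < 2; ++i) {
      double y4 = y[i] + h*(e1*k1[i] + e3*k3[i] + e4*k4[i] + e5*k5[i]
                            + e6*k6[i] + e7*k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double d = (y5[i] - y4) / sc;
      err += d * d;
    }
    err = std::sqrt(err / 2.0);
    if (!std::isfinite(err)) return false;

    if (err <= 1.0) {
      t += h;
      y[0] = y5[0]; y[1] = y5[1];
      k1[0] = k7[0]; k1[1] = k7[1];   // FSAL
      if (!std::isfinite(y[0]) || !std::isfinite(y[1])) return false;
      double fac = (err == 0.0) ? 5.0 : 0.9 * std::pow(err, -0.2);
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(err, -0.2);
      if (fac < 0.2) fac = 0.2;
      h *= fac;
      rhs(t, y, k1, p);              // FSAL invalidated by rejection
    }
    if (h < 1e-14) return false;
  }
  hstart = h;
  return true;
}

// [[Rcpp::export(name = ".simulate_beats_cpp")]]
List simulate_beats_cpp(NumericVector params, NumericVector constants,
                        int n_grid, double tol, int max_beats,
                        double rtol, double atol,
                        double v0, double pao0) {
  Params p;
  p.r_mv = params[0]; p.r_av = params[1]; p.r_art = params[2];
  p.e_es = params[3]; p.e_ed = params[4]; p.t_s = params[5];
  p.t_e  = params[6]; p.v_lv_d = params[7]; p.c_ao = params[8];
  p.p_la = constants[0]; p.p_cap = constants[1]; p.t_cycle = constants[2];

  double dt = p.t_cycle / n_grid;
  NumericVector v_cur(n_grid), pa_cur(n_grid), v_prev(n_grid), pa_prev(n_grid);
  double y[2] = {v0, pao0};
  double hstart = dt;
  double metric = R_PosInf;
  int beat = 0;
  bool ok = true, converged = false;

  for (beat = 1; beat <= max_beats && ok; ++beat) {
    for (int k = 0; k < n_grid; ++k) {
      v_cur[k] = y[0]; pa_cur[k] = y[1];
      ok = integrate_segment(k * dt, (k + 1) * dt, y, p, rtol, atol, hstart);
      if (!ok) break;
    }
    if (!ok) break;
    if (beat > 1) {
      double vmax = 0, pmax = 0, dv = 0, dp = 0;
      for (int k = 0; k < n_grid; ++k) {
        vmax = std::max(vmax, std::fabs(v_cur[k]));
        pmax = std::max(pmax, std::fabs(pa_cur[k]));
        dv = std::max(dv, std::fabs(v_cur[k] - v_prev[k]));
        dp = std::max(dp, std::fabs(pa_cur[k] - pa_prev[k]));
      }
      metric = std::max(dv / std::max(vmax, 1e-300), dp / std::max(pmax, 1e-300));
      if (metric < tol) { converged = true; break; }
    }
    v_prev = clone(v_cur); pa_prev = clone(pa_cur);
  }
  if (beat > max_beats) beat = max_beats;

  NumericVector time(n_grid), p_lv(n_grid), q_mv(n_grid), q_av(n_grid), q_sys(n_grid);
  for (int k = 0; k < n_grid; ++k) {
    double t = k * dt;
    time[k] = t;
    double plv = elastance_at(t, p) * (v_cur[k] - p.v_lv_d);
    p_lv[k] = plv;
    double qm = (p.p_la - plv) / p.r_mv; q_mv[k] = qm > 0 ? qm : 0;
    double qa = (plv - pa_cur[k]) / p.r_av; q_av[k] = qa > 0 ? qa : 0;
    q_sys[k] = (pa_cur[k] - p.p_cap) / p.r_art;
  }

  return List::create(
    _["time"] = time, _["v_lv"] = v_cur, _["p_lv"] = p_lv, _["p_ao"] = pa_cur,
    _["q_mv"] = q_mv, _["q_av"] = q_av, _["q_sys"] = q_sys,
    _["n_beats"] = beat, _["metric"] = metric,
    _["converged"] = converged, _["finite"] = ok);
}

// [[Rcpp::export(name = ".elastance_cpp")]]
NumericVector elastance_cpp(NumericVector t, NumericVector params,
                            NumericVector constants) {
  Params p;
  p.e_es = params[3]; p.e_ed = params[4]; p.t_s = params[5]; p.t_e = params[6];
  p.t_cycle = constants[2];
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = elastance_at(t[i], p);
  return out;
}
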