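// Event-driven integration of one female life history (plus dependent calf).
//
// States integrated with classical RK4 between breakpoints:
//   y[0] female reserve mass F (kg)       y[1] female log-survival
//   y[2] calf reserve mass (kg)           y[3] calf log-survival
//   y[4] cumulative milk energy assimilated by current calf (MJ)
//   y[5] cumulative resource energy assimilated by current calf (MJ)
// Structural size is deterministic in age (demand growth) and is not
// integrated. Deterministic breakpoints (phase clocks, disturbance window
// edges, milk-decline kink) bound every step; state-dependent events
// (pregnancy-threshold crossing, survival-threshold and condition-floor
// deaths) are localized by bisection on the step to 1e-9 d.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double EV_TOL = 1e-9;   // bisection tolerance, d
static const double T_EPS  = 1e-7;   // breakpoint coincidence tolerance, d

struct Par {
  double l_b, l_inf, k, omega1, omega2, T_P, T_L, T_D, T_N;
  double rho, rho_s, theta_F, phi_R, phi_L, eta, gamma, T_R, xi_c, xi_m;
  double sigma_M, sigma_G, sigma_L, eps_plus, eps_minus;
  double alpha1, beta1, alpha2, beta2, mu_s;
  double F_neonate, survival_threshold, condition_floor;
};

struct Env {
  double R_hat, A, dist_days, dist_start, period;
};

enum Phase { RESTING = 0, WAITING = 1, PREGNANT = 2, LACTATING = 3,
             LACTWAIT = 4 };

struct Sim {
  Phase phase;
  double a0;          // female age at t = 0 (weaning age)
  double t_wait;      // time the waiting clock started
  double t_conceive;  // time of conception (PREGNANT)
  double t_birth;     // birth time of current calf
  bool has_calf;
  double lnth_f, lnth_c;  // log death thresholds
  bool reproduce;
  double w_off;       // calf age at which the lactating-waiting window opens
};

struct Flows {
  double IRf, CMf, CGf, CP, CL, Bf;
  double IRc, IL, CMc, CGc, Bc;
  double lf, Sf, Wf, condf, lc, Sc, Wc, condc, Reff;
};

static inline double pw(double x, double e) { return std::pow(x, e); }

// positive modulus via floor (x >= 0 throughout the simulation)
static inline double pmod(double x, double m) {
  return x - std::floor(x / m) * m;
}

static inline double res_eff(double t, const Env& e) {
  double R = e.R_hat * (1.0 + e.A * std::sin(2.0 * M_PI * t / e.period));
  if (e.dist_days <= 0.0) return R;
  if (e.dist_days >= e.period) return 0.0;
  double doy = pmod(t, e.period);
  double s = e.dist_start, en = s + e.dist_days;
  bool dist = (en <= e.period) ? (doy >= s && doy < en)
                               : (doy >= s || doy < en - e.period);
  return dist ? 0.0 : R;
}

static inline double effort(double F, double W, const Par& p) {
  if (F <= 0.0) return 1.0;
  return 1.0 / (1.0 + std::exp(-p.eta * (p.rho * W / F - 1.0)));
}

static inline double age_eff(double a, const Par& p) {
  double ag = pw(a, p.gamma);
  return ag / (pw(p.T_R, p.gamma) + ag);
}

static inline double milk_age(double a, const Par& p) {
  if (a <= p.T_N) return 1.0;
  double x = (a - p.T_N) / (p.T_L - p.T_N);
  double f = (1.0 - x) / (1.0 - p.xi_c * x);
  return f < 0.0 ? 0.0 : (f > 1.0 ? 1.0 : f);
}

static inline double provisioning(double Fm, double Wm, const Par& p) {
  double x = Fm - p.rho_s * Wm;
  if (x <= 0.0) return 0.0;
  double f = (1.0 - p.xi_m) * x / ((p.rho - p.rho_s) * Wm - p.xi_m * x);
  return f < 0.0 ? 0.0 : (f > 1.0 ? 1.0 : f);
}

static inline double hazard_age(double a, const Par& p) {
  return p.alpha1 * std::exp(-p.beta1 * a) + p.alpha2 * std::exp(p.beta2 * a);
}

static inline double hazard_starv(double F, double W, const Par& p) {
  double thr = p.rho_s * W;
  if (F >= thr) return 0.0;
  double Fp = F > 1e-12 ? F : 1e-12;
  return p.mu_s * (thr / Fp - 1.0);
}

// Full rate computation; also reports the energy flows for recording.
static void rates(double t, const double y[6], const Sim& s, const Par& p,
                  const Env& e, double dy[6], Flows* fl) {
  double af = s.a0 + t;
  double lf = p.l_inf - (p.l_inf - p.l_b) * std::exp(-p.k * af);
  double Sf = p.omega1 * pw(lf, p.omega2);
  double Ff = y[0] > 0.0 ? y[0] : 0.0;

  double Sfet = 0.0, CP = 0.0;
  if (s.phase == PREGNANT) {
    double taup = t - s.t_conceive;
    if (taup < 0.0) taup = 0.0;
    if (taup > p.T_P) taup = p.T_P;
    double lp = p.l_b * taup / p.T_P;
    Sfet = p.omega1 * pw(lp, p.omega2);
    CP = taup > 0.0
      ? p.sigma_G * p.omega1 * p.omega2 * pw(p.l_b / p.T_P, p.omega2) *
        pw(taup, p.omega2 - 1.0)
      : 0.0;
  }
  double Wf  = Sf + Ff + Sfet;
  double WMf = Sf + p.theta_F * Ff + Sfet;
  double Reff = res_eff(t, e);
  double IRf = p.phi_R * Reff * pw(Sf, 2.0 / 3.0) * effort(Ff, Wf, p) *
               age_eff(af, p);
  double CMf = p.sigma_M * pw(WMf, 0.75);
  double CGf = p.sigma_G * p.omega1 * p.k * (p.l_inf - lf) * p.omega2 *
               pw(lf, p.omega2 - 1.0);

  double IL = 0.0, CL = 0.0, IRc = 0.0, CMc = 0.0, CGc = 0.0, Bc = 0.0;
  double lc = 0.0, Sc = 0.0, Wc = 0.0;
  dy[2] = dy[3] = dy[4] = dy[5] = 0.0;
  if (s.has_calf) {
    double ac = t - s.t_birth;
    if (ac < 0.0) ac = 0.0;
    lc = p.l_inf - (p.l_inf - p.l_b) * std::exp(-p.k * ac);
    Sc = p.omega1 * pw(lc, p.omega2);
    double Fc = y[2] > 0.0 ? y[2] : 0.0;
    Wc = Sc + Fc;
    double Sc23 = pw(Sc, 2.0 / 3.0);
    double effc = effort(Fc, Wc, p);
    IRc = p.phi_R * Reff * Sc23 * effc * age_eff(ac, p);
    IL  = p.phi_L * Sc23 * effc * milk_age(ac, p) * provisioning(Ff, Wf, p);
    CMc = p.sigma_M * pw(Sc + p.theta_F * Fc, 0.75);
    CGc = p.sigma_G * p.omega1 * p.k * (p.l_inf - lc) * p.omega2 *
          pw(lc, p.omega2 - 1.0);
    Bc = IRc + IL - CGc - CMc;
    dy[2] = Bc > 0.0 ? Bc / p.eps_plus : Bc / p.eps_minus;
    dy[3] = -(hazard_age(ac, p) + hazard_starv(Fc, Wc, p));
    dy[4] = IL;
    dy[5] = IRc;
    CL = IL / p.sigma_L;
  }
  double Bf = IRf - CGf - CMf - CP - CL;
  dy[0] = Bf > 0.0 ? Bf / p.eps_plus : Bf / p.eps_minus;
  dy[1] = -(hazard_age(af, p) + hazard_starv(Ff, Wf, p));

  if (fl) {
    fl->IRf = IRf; fl->CMf = CMf; fl->CGf = CGf; fl->CP = CP; fl->CL = CL;
    fl->Bf = Bf; fl->IRc = IRc; fl->IL = IL; fl->CMc = CMc; fl->CGc = CGc;
    fl->Bc = Bc; fl->lf = lf; fl->Sf = Sf; fl->Wf = Wf;
    fl->condf = Ff / Wf; fl->lc = lc; fl->Sc = Sc; fl->Wc = Wc;
    fl->condc = s.has_calf ? (y[2] > 0.0 ? y[2] : 0.0) / Wc : NA_REAL;
    fl->Reff = Reff;
  }
}

static void rk4(double t, const double y[6], double h, const Sim& s,
                const Par& p, const Env& e, double out[6]) {
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  rates(t, y, s, p, e, k1, nullptr);
  for (int i = 0; i < 6; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
  rates(t + 0.5 * h, tmp, s, p, e, k2, nullptr);
  for (int i = 0; i < 6; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
  rates(t + 0.5 * h, tmp, s, p, e, k3, nullptr);
  for (int i = 0; i < 6; ++i) tmp[i] = y[i] + h * k3[i];
  rates(t + h, tmp, s, p, e, k4, nullptr);
  for (int i = 0; i < 6; ++i)
    out[i] = y[i] + h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// female structural mass at time t
static inline double S_female(double t, const Sim& s, const Par& p) {
  double lf = p.l_inf - (p.l_inf - p.l_b) * std::exp(-p.k * (s.a0 + t));
  return p.omega1 * pw(lf, p.omega2);
}

// pregnancy-threshold margin: F - (rho_s * W + F_neonate), W = S + F
static inline double g_preg(double t, const double y[6], const Sim& s,
                            const Par& p) {
  double Sf = S_female(t, s, p);
  return y[0] - (p.rho_s * (Sf + y[0]) + p.F_neonate);
}

static inline double cond_f(double t, const double y[6], const Sim& s,
                            const Par& p) {
  double Sf = S_female(t, s, p);
  double Sfet = 0.0;
  if (s.phase == PREGNANT) {
    double taup = t - s.t_conceive;
    if (taup < 0.0) taup = 0.0;
    if (taup > p.T_P) taup = p.T_P;
    double lp = p.l_b * taup / p.T_P;
    Sfet = p.omega1 * pw(lp, p.omega2);
  }
  return y[0] / (Sf + y[0] + Sfet);
}

static inline double cond_c(double t, const double y[6], const Sim& s,
                            const Par& p) {
  double ac = t - s.t_birth;
  if (ac < 0.0) ac = 0.0;
  double lc = p.l_inf - (p.l_inf - p.l_b) * std::exp(-p.k * ac);
  double Sc = p.omega1 * pw(lc, p.omega2);
  return y[2] / (Sc + y[2]);
}

// Bisect for the root of monitor(te) within (0, h] given monitor(0) on the
// no-event side; integration restarts from (t, y) each probe.
template <typename G>
static double bisect_event(double t, const double y[6], double h,
                           const Sim& s, const Par& p, const Env& e, G g) {
  double lo = 0.0, hi = h, ytmp[6];
  while (hi - lo > EV_TOL) {
    double mid = 0.5 * (lo + hi);
    rk4(t, y, mid, s, p, e, ytmp);
    if (g(t + mid, ytmp)) hi = mid; else lo = mid;
  }
  return hi;
}

static Par par_from_list(const List& pl) {
  Par p;
  p.l_b = pl["l_b"]; p.l_inf = pl["l_inf"]; p.k = pl["k"];
  p.omega1 = pl["omega1"]; p.omega2 = pl["omega2"];
  p.T_P = pl["T_P"]; p.T_L = pl["T_L"]; p.T_D = pl["T_D"];
  p.T_N = pl["T_N"];
  p.rho = pl["rho"]; p.rho_s = pl["rho_s"]; p.theta_F = pl["theta_F"];
  p.phi_R = pl["phi_R"]; p.phi_L = pl["phi_L"]; p.eta = pl["eta"];
  p.gamma = pl["gamma"]; p.T_R = pl["T_R"];
  p.xi_c = pl["xi_c"]; p.xi_m = pl["xi_m"];
  p.sigma_M = pl["sigma_M"]; p.sigma_G = pl["sigma_G"];
  p.sigma_L = pl["sigma_L"];
  p.eps_plus = pl["eps_plus"]; p.eps_minus = pl["eps_minus"];
  p.alpha1 = pl["alpha1"]; p.beta1 = pl["beta1"];
  p.alpha2 = pl["alpha2"]; p.beta2 = pl["beta2"];
  p.mu_s = pl["mu_s"];
  p.F_neonate = pl["F_neonate"];
  p.survival_threshold = pl["survival_threshold"];
  p.condition_floor = pl["condition_floor"];
  return p;
}

// [[Rcpp::export(name = ".simulate_life_cpp")]]
List simulate_life_cpp(List par, List envl, bool fixed_mode,
                       NumericVector uniforms, double dt, double t_max,
                       bool record, double dt_record, bool ibi_quirk,
                       double a0, double F0, bool reproduce) {
  Par p = par_from_list(par);
  Env e;
  e.R_hat = envl["R_hat"]; e.A = envl["A"];
  e.dist_days = envl["disturbance_days"];
  e.dist_start = envl["disturbance_start"]; e.period = envl["period"];

  Sim s;
  s.phase = RESTING; s.a0 = a0; s.t_wait = -1.0; s.t_conceive = -1.0;
  s.t_birth = -1.0; s.has_calf = false; s.reproduce = reproduce;
  s.w_off = p.T_L - p.T_P + (ibi_quirk ? 1.0 : 0.0);
  s.lnth_f = fixed_mode ? std::log(p.survival_threshold)
                        : std::log(uniforms[0]);
  s.lnth_c = 0.0;
  int u_idx = 1;

  double y[6] = {F0, 0.0, 0.0, 0.0, 0.0, 0.0};
  double t = 0.0;

  // outcome bookkeeping
  double death_age = NA_REAL, afr_cross = NA_REAL, starv_days = 0.0;
  std::string death_cause = "none";
  int n_births = 0, n_weaned = 0;
  std::vector<double> birth_ages, weaning_ages, calf_death_fem, calf_death_calf;
  // per-calf energy accounting
  std::vector<double> cb_birth, cb_exit, cb_fate, cb_milk1, cb_milkT,
                      cb_res1, cb_resT;
  double cur_milk1 = NA_REAL, cur_res1 = NA_REAL;

  std::vector<double> traj;
  const int NCOL = 25;
  double next_rec = 0.0;
  auto rec_row = [&](double tt, const double yy[6]) {
    double dy[6]; Flows fl;
    rates(tt, yy, s, p, e, dy, &fl);
    double row[NCOL] = {
      tt, (s.a0 + tt) / 365.0, (double)s.phase,
      fl.lf, fl.Sf, yy[0], fl.Wf, fl.condf, std::exp(yy[1]),
      fl.IRf, fl.CMf, fl.CGf, fl.CP, fl.CL, fl.Bf,
      s.has_calf ? (tt - s.t_birth) : NA_REAL,
      s.has_calf ? fl.lc : NA_REAL, s.has_calf ? fl.Sc : NA_REAL,
      s.has_calf ? yy[2] : NA_REAL, s.has_calf ? fl.condc : NA_REAL,
      s.has_calf ? std::exp(yy[3]) : NA_REAL,
      s.has_calf ? fl.IRc : NA_REAL, s.has_calf ? fl.IL : NA_REAL,
      s.has_calf ? fl.Bc : NA_REAL, fl.Reff };
    for (int i = 0; i < NCOL; ++i) traj.push_back(row[i]);
  };

  auto end_calf = [&](double tt, bool weaned, const double yy[6]) {
    cb_birth.push_back((s.a0 + s.t_birth) / 365.0);
    cb_exit.push_back((s.a0 + tt) / 365.0);
    cb_fate.push_back(weaned ? 1.0 : 0.0);
    cb_milk1.push_back(ISNA(cur_milk1) ? yy[4] : cur_milk1);
    cb_milkT.push_back(yy[4]);
    cb_res1.push_back(ISNA(cur_res1) ? yy[5] : cur_res1);
    cb_resT.push_back(yy[5]);
    s.has_calf = false;
    cur_milk1 = NA_REAL; cur_res1 = NA_REAL;
  };

  auto to_waiting_if_ready = [&](double tt, const double yy[6]) {
    if (s.phase == RESTING && s.reproduce && g_preg(tt, yy, s, p) >= 0.0) {
      s.phase = WAITING; s.t_wait = tt;
      if (ISNA(afr_cross)) afr_cross = (s.a0 + tt) / 365.0;
    }
  };

  to_waiting_if_ready(t, y);
  if (record) { rec_row(t, y); next_rec = dt_record; }

  bool alive = true;
  long max_iter = (long)(t_max / (dt > 0.01 ? 0.01 : dt) * 10.0) + 1000;
  long iter = 0;

  while (alive && t < t_max - T_EPS) {
    if (++iter > max_iter)
      stop("integrator failure: step budget exceeded at t = %f (phase %d)",
           t, (int)s.phase);

    // ---- next deterministic breakpoint ----
    double tb = t_max;
    if (s.phase == WAITING) tb = std::min(tb, s.t_wait + p.T_D);
    if (s.phase == PREGNANT) tb = std::min(tb, s.t_conceive + p.T_P);
    if (s.has_calf) {
      tb = std::min(tb, s.t_birth + p.T_L);                 // weaning
      if (t < s.t_birth + p.T_N - T_EPS)
        tb = std::min(tb, s.t_birth + p.T_N);               // milk kink
      if (t < s.t_birth + 365.0 - T_EPS)
        tb = std::min(tb, s.t_birth + 365.0);               // year-1 snapshot
      if (s.phase == LACTATING && t < s.t_birth + s.w_off - T_EPS)
        tb = std::min(tb, s.t_birth + s.w_off);             // waiting window
    }
    if (e.dist_days > 0.0 && e.dist_days < e.period) {
      double base = std::floor(t / e.period) * e.period;
      double edges[2] = {e.dist_start,
                         pmod(e.dist_start + e.dist_days, e.period)};
      for (int cyc = 0; cyc < 2; ++cyc)
        for (int j = 0; j < 2; ++j) {
          double te = base + cyc * e.period + edges[j];
          if (te > t + T_EPS) tb = std::min(tb, te);
        }
    }

    double h = std::min(dt, tb - t);
    if (h < T_EPS) h = tb - t;
    if (h <= 0.0) { t = tb; continue; }

    double y1[6];
    rk4(t, y, h, s, p, e, y1);

    // ---- state-dependent events within the step ----
    bool armed_preg = s.reproduce &&
      (s.phase == RESTING ||
       (s.phase == LACTATING && t >= s.t_birth + s.w_off - T_EPS));
    double te_best = h + 1.0;
    int ev_best = 0;  // 1 fem death, 2 calf death, 3 preg crossing

    if (cond_f(t + h, y1, s, p) < p.condition_floor) {
      double te = bisect_event(t, y, h, s, p, e,
        [&](double tt, const double yy[6]) {
          return cond_f(tt, yy, s, p) < p.condition_floor; });
      if (te < te_best) { te_best = te; ev_best = 1; }
    }
    if (y1[1] < s.lnth_f) {
      double te = bisect_event(t, y, h, s, p, e,
        [&](double, const double yy[6]) { return yy[1] < s.lnth_f; });
      if (te < te_best) { te_best = te; ev_best = 1; }
    }
    if (s.has_calf) {
      if (cond_c(t + h, y1, s, p) < p.condition_floor) {
        double te = bisect_event(t, y, h, s, p, e,
          [&](double tt, const double yy[6]) {
            return cond_c(tt, yy, s, p) < p.condition_floor; });
        if (te < te_best - EV_TOL) { te_best = te; ev_best = 2; }
      }
      if (y1[3] < s.lnth_c) {
        double te = bisect_event(t, y, h, s, p, e,
          [&](double, const double yy[6]) { return yy[3] < s.lnth_c; });
        if (te < te_best - EV_TOL) { te_best = te; ev_best = 2; }
      }
    }
    if (armed_preg && g_preg(t, y, s, p) < 0.0 &&
        g_preg(t + h, y1, s, p) >= 0.0) {
      double te = bisect_event(t, y, h, s, p, e,
        [&](double tt, const double yy[6]) {
          return g_preg(tt, yy, s, p) >= 0.0; });
      if (te < te_best - EV_TOL) { te_best = te; ev_best = 3; }
    }

    // starvation-day accounting (step-start rule, reporting only)
    {
      double Sf = S_female(t, s, p);
      if (y[0] < p.rho_s * (Sf + y[0]))
        starv_days += std::min(h, ev_best > 0 ? te_best : h);
    }

    if (ev_best > 0) {
      double te = te_best;
      rk4(t, y, te, s, p, e, y1);
      t += te;
      for (int i = 0; i < 6; ++i) y[i] = y1[i];
      if (ev_best == 1) {
        death_age = (s.a0 + t) / 365.0;
        death_cause = cond_f(t, y, s, p) < p.condition_floor
                        ? "starvation-floor" : "mortality";
        if (s.has_calf) {  // orphaned calf dies, not weaned
          calf_death_fem.push_back((s.a0 + t) / 365.0);
          calf_death_calf.push_back(t - s.t_birth);
          end_calf(t, false, y);
        }
        alive = false;
      } else if (ev_best == 2) {
        calf_death_fem.push_back((s.a0 + t) / 365.0);
        calf_death_calf.push_back(t - s.t_birth);
        bool was_lw = (s.phase == LACTWAIT);
        end_calf(t, false, y);
        y[2] = y[3] = y[4] = y[5] = 0.0;
        s.phase = was_lw ? WAITING : RESTING;
        to_waiting_if_ready(t, y);
      } else {  // pregnancy-threshold crossing
        if (s.phase == RESTING) {
          s.phase = WAITING; s.t_wait = t;
          if (ISNA(afr_cross)) afr_cross = (s.a0 + t) / 365.0;
        } else {
          s.phase = LACTWAIT; s.t_wait = t;
        }
      }
      if (record && alive && t >= next_rec - T_EPS) {
        rec_row(t, y); while (next_rec <= t + T_EPS) next_rec += dt_record;
      }
      continue;
    }

    t += h;
    for (int i = 0; i < 6; ++i) y[i] = y1[i];

    // ---- deterministic events at t == tb ----
    if (std::fabs(t - tb) < T_EPS && tb < t_max - T_EPS) {
      // weaning first (precedes clock expirations in the tie-break)
      if (s.has_calf && std::fabs(t - (s.t_birth + p.T_L)) < T_EPS) {
        n_weaned++;
        weaning_ages.push_back((s.a0 + t) / 365.0);
        bool was_lw = (s.phase == LACTWAIT);
        end_calf(t, true, y);
        y[2] = y[3] = y[4] = y[5] = 0.0;
        s.phase = was_lw ? WAITING : RESTING;
        to_waiting_if_ready(t, y);
      }
      if (s.has_calf && std::fabs(t - (s.t_birth + 365.0)) < T_EPS) {
        cur_milk1 = y[4]; cur_res1 = y[5];   // year-1 energy snapshot
      }
      if (s.phase == PREGNANT &&
          std::fabs(t - (s.t_conceive + p.T_P)) < T_EPS) {
        // birth: neonate at the starvation condition threshold
        double Sb = p.omega1 * pw(p.l_b, p.omega2);
        s.has_calf = true; s.t_birth = t;
        y[2] = p.rho_s * Sb / (1.0 - p.rho_s);
        y[3] = 0.0; y[4] = 0.0; y[5] = 0.0;
        if (fixed_mode) s.lnth_c = std::log(p.survival_threshold);
        else {
          if (u_idx >= uniforms.size())
            stop("random-stream exhausted: more calves than supplied draws");
          s.lnth_c = std::log(uniforms[u_idx++]);
        }
        s.phase = LACTATING;
        n_births++;
        birth_ages.push_back((s.a0 + t) / 365.0);
      } else if (s.phase == WAITING &&
                 std::fabs(t - (s.t_wait + p.T_D)) < T_EPS) {
        s.phase = PREGNANT; s.t_conceive = t;
      }
      if (s.phase == LACTATING &&
          std::fabs(t - (s.t_birth + s.w_off)) < T_EPS &&
          s.reproduce && g_preg(t, y, s, p) >= 0.0) {
        s.phase = LACTWAIT; s.t_wait = t;
      }
    }

    if (record && t >= next_rec - T_EPS) {
      rec_row(t, y); while (next_rec <= t + T_EPS) next_rec += dt_record;
    }
  }

  if (alive) {  // ran into t_max
    death_age = NA_REAL;
    if (s.has_calf) end_calf(t, false, y);
  }
  if (record) rec_row(t, y);

  List calves = List::create(
    _["birth_age_yr"] = wrap(cb_birth), _["exit_age_yr"] = wrap(cb_exit),
    _["weaned"] = wrap(cb_fate), _["milk_y1_MJ"] = wrap(cb_milk1),
    _["milk_total_MJ"] = wrap(cb_milkT), _["resource_y1_MJ"] = wrap(cb_res1),
    _["resource_total_MJ"] = wrap(cb_resT));

  NumericMatrix tm(0, 0);
  if (record) {
    int nr = traj.size() / NCOL;
    tm = NumericMatrix(nr, NCOL);
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < NCOL; ++j) tm(i, j) = traj[i * NCOL + j];
  }

  return List::create(
    _["death_age_yr"] = death_age,
    _["death_cause"] = death_cause,
    _["n_births"] = n_births,
    _["n_weaned"] = n_weaned,
    _["birth_ages_yr"] = wrap(birth_ages),
    _["weaning_ages_yr"] = wrap(weaning_ages),
    _["calf_death_female_ages_yr"] = wrap(calf_death_fem),
    _["calf_death_calf_ages_d"] = wrap(calf_death_calf),
    _["first_crossing_age_yr"] = afr_cross,
    _["starvation_days"] = starv_days,
    _["final_survival"] = std::exp(y[1]),
    _["calves"] = calves,
    _["trajectory"] = tm);
}
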