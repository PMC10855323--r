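// Compiled core for the Ting viscoelastic indentation model under power-law
// rheology.  Unit contract (shared with the R layer): lengths nm, time s,
// modulus Pa, force nN.  The geometric prefactor C = 4*sqrt(R)/(3*(1-nu^2))
// carries the 1e-9 scale so that C * E[Pa] * delta[nm]^{3/2} is in nN.
//
// Quadrature: product integration of E1*(t-xi)^{-alpha} against a
// piecewise-linear history (exact for piecewise-linear histories, with the
// weak endpoint singularity integrated analytically).  Sampled AFM records
// are uniform in time, which lets the per-segment kernel integrals come from
// a precomputed power table and gives a closed-form within-segment solution
// of the t1 equation; an arbitrary-grid fallback covers everything else.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double bec_poly(double delta, double h, double R,
                              const std::vector<double> &cf) {
  if (cf.empty() || !std::isfinite(h) || delta <= 0.0) return 1.0;
  double chi = std::sqrt(R * delta) / h;
  double f = 1.0, p = 1.0;
  for (size_t i = 0; i < cf.size(); ++i) {
    p *= chi;
    f += cf[i] * p;
  }
  return f;
}

// \int_a^b (t - x)^{-alpha} dx for a <= b <= t (times p = 1 - alpha NOT yet
// divided out; returns (t-a)^p - (t-b)^p).
static inline double kpow(double a, double b, double t, double p) {
  double ta = t - a;
  double tb = t - b;
  if (tb < 0.0) tb = 0.0;
  if (ta < 0.0) ta = 0.0;
  return std::pow(ta, p) - std::pow(tb, p);
}

// ---------------------------------------------------------------------------
// Shared evaluation context.  Nodes x[0..n-1]; the grid is "uniform-tail"
// when x[j] = x[1] + (j-1)*dt for all j >= 1 (the first interval may be
// shorter, e.g. a contact node inserted between samples).  P[k] = (k*dt)^p.
// ---------------------------------------------------------------------------
struct TingCtx {
  const double *x;
  int n;
  double p;        // 1 - alpha
  bool uniform;
  double dt;
  std::vector<double> P;

  void init(const double *x_, int n_, double alpha) {
    x = x_;
    n = n_;
    p = 1.0 - alpha;
    uniform = false;
    if (n >= 3) {
      dt = x[2] - x[1];
      if (dt > 0) {
        uniform = true;
        for (int j = 2; j < n - 1; ++j)
          if (std::fabs((x[j + 1] - x[j]) - dt) > 1e-9 * dt) {
            uniform = false;
            break;
          }
      }
    }
    if (uniform) {
      P.resize(n + 1);
      for (int k = 0; k <= n; ++k) P[k] = std::pow(k * dt, p);
    }
  }

  // (t_i - x_j)^p - (t_i - x_{j+1})^p for a full segment j (0-based), at
  // observation node i (t = x[i]); j >= 1 segments come from the table.
  inline double dP(int i, int j) const {
    if (j >= 1) return P[i - j] - P[i - j - 1];
    return std::pow(x[i] - x[0], p) - P[i - 1];
  }
};

// hereditary integral of piecewise-linear g over [0, s] at t = x[i],
// divided by nothing (caller divides by p): sum_j w_j * kernel_j
static double hered_ctx(const TingCtx &C, const double *g, int i, double s) {
  const double *x = C.x;
  double t = x[i];
  double acc = 0.0;
  if (C.uniform) {
    for (int j = 0; j < i; ++j) {
      double a = x[j], b = x[j + 1];
      if (a >= s) break;
      double dx = b - a;
      if (dx <= 0.0) continue;
      double w = (g[j + 1] - g[j]) / dx;
      if (w == 0.0) continue;
      if (b <= s) {
        acc += w * C.dP(i, j);
      } else {
        acc += w * kpow(a, s, t, C.p);
      }
    }
  } else {
    for (int j = 0; j < i; ++j) {
      double a = x[j], b = x[j + 1];
      if (a >= s) break;
      double bb = (b < s) ? b : s;
      double dx = b - a;
      if (dx <= 0.0) continue;
      double w = (g[j + 1] - g[j]) / dx;
      if (w != 0.0) acc += w * kpow(a, bb, t, C.p);
    }
  }
  return acc;
}

// Solve the t1 equation at node i (> itm):
//   E1/p * int_{t1}^{t} (t-xi)^{-alpha} d'(xi) dxi + geta = 0
// For the uniform path, suffix sums over full segments give G at every node
// and the within-segment root is closed-form.  Returns t1 in [0, tm].
static double solve_t1_ctx(const TingCtx &C, const double *d, int i,
                           double E1, double geta, int itm, double tm,
                           int *jhint) {
  const double *x = C.x;
  double t = x[i];
  double gp = geta * C.p / E1; // work with p-scaled integral
  // G_scaled(s) = int_s^t kernel d' + gp ; root in s
  // node values via suffix sums over segments j = js..i-1
  double total = hered_ctx(C, d, i, t);
  double G0 = total + gp;
  if (G0 <= 0.0) return 0.0;
  // find segment js (0..itm-1) with G(x_js) >= 0 > G(x_{js+1}), scanning
  // from the hint (t1 is non-increasing in t)
  int js = *jhint;
  if (js > itm - 1) js = itm - 1;
  if (js < 0) js = 0;
  // G at node x_k: total - hered(0..x_k)
  auto Gnode = [&](int k) {
    return total - hered_ctx(C, d, i, x[k]) + gp;
  };
  double Gjs = Gnode(js);
  if (Gjs >= 0.0) {
    while (js + 1 <= itm && Gnode(js + 1) >= 0.0) ++js;
  } else {
    while (js > 0 && Gjs < 0.0) Gjs = Gnode(--js);
    if (js == 0 && Gjs < 0.0) return 0.0; // shouldn't happen, G0 > 0
  }
  *jhint = js;
  if (js >= itm) return tm;
  // root inside segment [x_js, x_{js+1}]:
  //   G(s) = Gend + w * ((t-s)^p - (t-x_{js+1})^p)  with Gend = G(x_{js+1})
  double a = x[js], b = x[js + 1];
  double w = (d[js + 1] - d[js]) / (b - a);
  double Gend = Gnode(js + 1);
  if (w <= 0.0 || !std::isfinite(Gend)) return a; // degenerate/flat segment
  double target = std::pow(t - b < 0 ? 0.0 : t - b, C.p) - Gend / w;
  if (target <= 0.0) return b;
  double s = t - std::pow(target, 1.0 / C.p);
  if (s < a) s = a;
  if (s > b) s = b;
  return s;
}

// [[Rcpp::export]]
List ting_force_cpp(NumericVector t, NumericVector delta, NumericVector u,
                    int itm, double E1, double alpha, double eta) {
  int n = t.size();
  NumericVector F(n), t1v(n);
  const double *x = &t[0];
  const double *d = &delta[0];
  const double *uu = &u[0];
  TingCtx C;
  C.init(x, n, alpha);
  std::vector<double> dudt(n, 0.0), dddt(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int a = (i > 0) ? i - 1 : 0;
    int b = (i < n - 1) ? i + 1 : n - 1;
    double dx = x[b] - x[a];
    if (dx > 0.0) {
      dudt[i] = (uu[b] - uu[a]) / dx;
      dddt[i] = (d[b] - d[a]) / dx;
    }
  }
  double tm = x[itm];
  int jhint = itm - 1;
  bool separated = false;
  for (int i = 1; i < n; ++i) {
    double ti = x[i];
    if (i <= itm) {
      F[i] = E1 * hered_ctx(C, uu, i, ti) / C.p + eta * dudt[i];
      t1v[i] = ti;
    } else {
      if (separated) continue; // force and t1 stay 0
      double s = solve_t1_ctx(C, d, i, E1, eta * dddt[i], itm, tm, &jhint);
      t1v[i] = s;
      if (s <= 0.0) {
        separated = true;
      } else {
        F[i] = E1 * hered_ctx(C, uu, i, s) / C.p;
      }
    }
  }
  return List::create(_["force"] = F, _["t1"] = t1v);
}

// ---------------------------------------------------------------------------
// Quasi-static force-curve simulator: triangular piezo ramp coupled to the
// cantilever by force balance k * d = F_ting(delta), delta = (z - z0) - d.
// The ramp reverses at the trigger force (or when the ramp distance is
// exhausted) and retracts back to z_start.  Thin samples: indentation is
// capped at wall_frac * h; beyond the cap the residual displacement loads
// the cantilever directly (rigid-substrate wall).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List ting_simulate_cpp(double z_start, double z0, double v, double dt,
                       double ramp, double k, double E1, double alpha,
                       double eta, double Cpref, double R, double h,
                       NumericVector bec_coef, double trigger, int max_n,
                       double wall_frac) {
  std::vector<double> cf(bec_coef.begin(), bec_coef.end());
  std::vector<double> tt, zz, dd, del;
  std::vector<double> hx, hd, hu; // in-contact history (time from contact)
  tt.reserve(max_n);
  zz.reserve(max_n);
  dd.reserve(max_n);
  del.reserve(max_n);
  double p = 1.0 - alpha;
  std::vector<double> P(max_n + 2);
  for (int kk = 0; kk <= max_n + 1; ++kk) P[kk] = std::pow(kk * dt, p);

  double t = 0.0, z = z_start;
  int dir = 1;
  int i_turn = -1, i_contact = -1;
  double tc = -1.0;
  bool separated = false;
  int itm = -1;
  int jhint = 0;
  double dcap = wall_frac * h;

  // hereditary integral over history nodes 0..m at t = hx[m], upper limit s;
  // node 0 sits at the contact crossing, nodes >= 1 on the sample grid
  auto hered_hist = [&](const std::vector<double> &g, int m, double s) {
    double tcur = hx[m];
    double acc = 0.0;
    for (int j = 0; j < m; ++j) {
      double a = hx[j], b = hx[j + 1];
      if (a >= s) break;
      double dx = b - a;
      if (dx <= 0.0) continue;
      double w = (g[j + 1] - g[j]) / dx;
      if (w == 0.0) continue;
      if (b <= s) {
        if (j >= 1)
          acc += w * (P[m - j] - P[m - j - 1]);
        else
          acc += w * (std::pow(tcur - a, p) - P[m - 1]);
      } else {
        acc += w * kpow(a, s, tcur, p);
      }
    }
    return acc;
  };

  for (int i = 0; i < max_n; ++i) {
    double d_i = 0.0, delta_i = 0.0;
    bool in_contact = (z > z0) && !(dir < 0 && separated);
    if (in_contact) {
      if (i_contact < 0) {
        i_contact = i;
        tc = t - (z - z0) / std::fabs(v);
        if (tc < 0.0) tc = 0.0;
        hx.push_back(0.0);
        hd.push_back(0.0);
        hu.push_back(0.0);
      }
      double xi = t - tc;
      int m = (int)hx.size();
      hx.push_back(xi);
      hd.push_back(0.0);
      hu.push_back(0.0);
      double tm = (itm >= 0) ? hx[itm] : xi;
      double dmax_prev = (itm >= 0) ? hd[itm] : 0.0;
      double avail = z - z0;
      double delta_g = 0.0;
      double F = 0.0, s1 = xi;
      // The monotone-contact (t1 = t) phase extends past the piezo
      // turnaround while the indentation is still non-decreasing (the force
      // can relax faster than the piezo retracts); tm is the time of
      // maximum indentation, not of the z-reversal.  Try the monotone
      // balance first and fall back to the t1 branch if delta drops.
      bool retract_phase = false;
      {
        // monotone phase: the force is affine in u(delta_i) given the fixed
        // history, F = a0 + a1 * u(delta); solve the balance
        // k * (avail - delta) = F(delta) by bisection (robust even when the
        // contact stiffness at the sampling timescale approaches k)
        double dx = hx[m] - hx[m - 1];
        double uprev = hu[m - 1];
        hd[m] = 0.0;
        hu[m] = 0.0;
        // hered with u[m] = 0 equals (true prefix) - uprev * dx^{p-1}, so
        // the full integral is hered0 + u(delta) * dx^{p-1}
        double hered0 = hered_hist(hu, m, xi);
        double dxp = (dx > 0.0) ? std::pow(dx, p - 1.0) : 0.0;
        double a0 = Cpref * (E1 * hered0 / p -
                             ((dx > 0.0) ? eta * uprev / dx : 0.0));
        double a1 = Cpref * (E1 * dxp / p + ((dx > 0.0) ? eta / dx : 0.0));
        double hi_d = avail;
        if (std::isfinite(h) && hi_d > dcap) hi_d = dcap;
        auto gbal = [&](double d_) {
          double u_ = bec_poly(d_, h, R, cf) * std::pow(d_, 1.5);
          return k * (avail - d_) - (a0 + a1 * u_);
        };
        if (gbal(0.0) <= 0.0) {
          delta_g = 0.0;
        } else if (gbal(hi_d) >= 0.0) {
          delta_g = hi_d; // wall (or full available travel)
        } else {
          double lo_d = 0.0, hi_b = hi_d;
          for (int it = 0; it < 60; ++it) {
            double mid = 0.5 * (lo_d + hi_b);
            if (gbal(mid) > 0.0) lo_d = mid; else hi_b = mid;
            if (hi_b - lo_d < 1e-9) break;
          }
          delta_g = 0.5 * (lo_d + hi_b);
        }
        hd[m] = delta_g;
        hu[m] = bec_poly(delta_g, h, R, cf) * std::pow(delta_g, 1.5);
        double Fvisc = a0 + a1 * hu[m];
        double F_wall = k * (avail - delta_g);
        // when pinned at the thin-sample cap, the substrate carries the
        // remaining load through the cantilever
        F = (delta_g >= hi_d - 1e-12 && F_wall > Fvisc) ? F_wall : Fvisc;
        if (F < 0.0) F = 0.0;
        d_i = F / k;
        s1 = xi;
        if (dir < 0 && itm >= 0 && delta_g < dmax_prev - 1e-9) {
          retract_phase = true; // indentation genuinely receding
        } else {
          itm = m;       // still at (or past) maximum indentation
          jhint = m - 1;
        }
      }
      if (retract_phase) {
        // retract: F(delta_i) is monotone increasing in delta_i (through
        // the last-segment slope, t1 and the u-integral), so the force
        // balance k * (avail - delta) = F(delta) has a unique root.  Only
        // the last history segment depends on delta, so prefix sums of the
        // hereditary integrals make every balance evaluation O(log m).
        double hi_d = avail;
        if (std::isfinite(h) && hi_d > dcap) hi_d = dcap;
        double dt_last = hx[m] - hx[m - 1];
        double klast = std::pow(dt_last, p);
        // Hpre[kk] = int over [0, x_kk] of kernel * hd'; Upre likewise for hu
        std::vector<double> Hpre(m + 1, 0.0), Upre(m + 1, 0.0);
        for (int j = 0; j < m; ++j) {
          double dx = hx[j + 1] - hx[j];
          double dj;
          if (j >= 1) dj = P[m - j] - P[m - j - 1];
          else dj = std::pow(xi - hx[0], p) - P[m - 1];
          double wd = (dx > 0.0) ? (hd[j + 1] - hd[j]) / dx : 0.0;
          double wu = (dx > 0.0) ? (hu[j + 1] - hu[j]) / dx : 0.0;
          if (j == m - 1) { wd = 0.0; wu = 0.0; } // delta-dependent, excluded
          Hpre[j + 1] = Hpre[j] + wd * dj;
          Upre[j + 1] = Upre[j] + wu * dj;
        }
        double total_pref = Hpre[m - 1]; // segments 0..m-2
        double s1_loc = 0.0;
        auto fret = [&](double d_) {
          double w_last = (d_ - hd[m - 1]) / dt_last;
          double total = total_pref + w_last * klast;
          double gp = (E1 > 0.0) ? (eta * w_last * p / E1) : 0.0;
          if (total + gp <= 0.0) {
            s1_loc = 0.0;
            return 0.0;
          }
          // G(x_kk) = total - Hpre[kk] + gp, decreasing in kk on [0, itm];
          // binary search for the sign change
          int lo_k = 0, hi_k = itm;
          if (total - Hpre[itm] + gp >= 0.0) {
            s1_loc = tm;
            return Cpref * E1 * Upre[itm] / p;
          }
          while (hi_k - lo_k > 1) {
            int mid = (lo_k + hi_k) / 2;
            if (total - Hpre[mid] + gp >= 0.0) lo_k = mid; else hi_k = mid;
          }
          int js = lo_k;
          double a = hx[js], b = hx[js + 1];
          double w = (hd[js + 1] - hd[js]) / (b - a);
          double Gend = total - Hpre[js + 1] + gp;
          if (w <= 0.0) {
            s1_loc = a;
          } else {
            double tb = xi - b;
            if (tb < 0) tb = 0;
            double target = std::pow(tb, p) - Gend / w;
            s1_loc = (target <= 0.0) ? b : xi - std::pow(target, 1.0 / p);
            if (s1_loc < a) s1_loc = a;
            if (s1_loc > b) s1_loc = b;
          }
          double wu = (hu[js + 1] - hu[js]) / (b - a);
          double raw = Upre[js] +
              wu * (std::pow(xi - a, p) - std::pow(xi - s1_loc, p));
          double Fv = Cpref * E1 * raw / p;
          return (Fv > 0.0) ? Fv : 0.0;
        };
        auto gbal = [&](double d_) { return k * (avail - d_) - fret(d_); };
        if (gbal(0.0) <= 0.0) {
          delta_g = 0.0;
        } else if (gbal(hi_d) >= 0.0) {
          delta_g = hi_d;
        } else {
          double lo_d = 0.0, hi_b = hi_d;
          for (int it = 0; it < 50; ++it) {
            double mid = 0.5 * (lo_d + hi_b);
            if (gbal(mid) > 0.0) lo_d = mid; else hi_b = mid;
            if (hi_b - lo_d < 1e-9) break;
          }
          delta_g = 0.5 * (lo_d + hi_b);
        }
        F = fret(delta_g);
        if (delta_g >= hi_d - 1e-12) {
          double F_wall = k * (avail - delta_g);
          if (F_wall > F) F = F_wall;
        }
        s1 = s1_loc;
        d_i = F / k;
        if (s1 <= 0.0) {
          separated = true;
          F = 0.0;
          delta_g = 0.0;
        }
      }
      hd[m] = delta_g;
      hu[m] = bec_poly(delta_g, h, R, cf) * std::pow(delta_g, 1.5);
      delta_i = delta_g;
      d_i = F / k;
      if (dir > 0 && (F >= trigger || (z - z_start) >= ramp)) {
        i_turn = i;
        dir = -1;
      }
    } else if (dir > 0 && (z - z_start) >= ramp) {
      i_turn = i;
      dir = -1;
    }
    tt.push_back(t);
    zz.push_back(z);
    dd.push_back(d_i);
    del.push_back(delta_i);
    if (dir < 0 && z <= z_start) break;
    t += dt;
    z += dir * std::fabs(v) * dt;
  }
  if (i_turn < 0) i_turn = (int)tt.size() - 1;
  return List::create(_["t"] = wrap(tt), _["z"] = wrap(zz),
                      _["defl"] = wrap(dd), _["delta"] = wrap(del),
                      _["i_turn"] = i_turn + 1,
                      _["i_contact"] = i_contact + 1, _["t_contact"] = tc);
}
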