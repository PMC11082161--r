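#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-trial Euler integration of one or two MSNs driven by cortical spike
// events, with optional pair-based STDP + non-associative reward-LTP applied
// online. All-to-all STDP sums are computed with exact exponential traces:
//   pre trace  S_i(t)  = sum_{t_pre,i <= t} exp(-(t - t_pre,i)/tau_s)
//   post trace T_m(t)  = sum_{t_post < t}   exp(-(t - t_post)/tau_s)
// A pre/post pair falling in the same Euler step is causally ordered
// input-before-output, so it contributes to the post-spike update at full
// amplitude (Delta t -> 0+ of the pre-post branch) and never to the
// pre-spike update.
//
// Units: mV, ms, nA, nF, MOhm. The quadratic gain k is in nS/mV, so the
// quadratic current k*(V-Vc)*(V-Veq) is in pA and carries a 1e-3 factor.

struct Trace {
  double v = 0.0, t = 0.0;
  double tau;
  explicit Trace(double tau_) : tau(tau_) {}
  double at(double now) {
    if (now > t) { v *= std::exp(-(now - t) / tau); t = now; }
    return v;
  }
  void bump(double now) { at(now); v += 1.0; }
};

static inline double clipw(double w, double lo, double hi) {
  return w < lo ? lo : (w > hi ? hi : w);
}

// [[Rcpp::export]]
List cpp_sim_trial(int model, NumericVector mp, int kernel, double Ts, int P,
                   IntegerVector ev_ch, NumericVector ev_t, NumericVector ext_t,
                   double W_ext, NumericVector W0, double duration, double dt,
                   bool noise, int n_msn, NumericVector W20, double J,
                   bool plastic, double A_post_pre, double A_pre_post,
                   double tau_s, double eps, double A_reward1, double A_reward2,
                   double w_min, double w_max, bool record_v,
                   double record_w_every) {
  // model params
  double Veq, Vth, Vr, R = 0, tau = 0, tauref = 0, eta = 0;
  double C = 0, kq = 0, Vc = 0, a = 0, b = 0, dU = 0, Rscale = 0;
  if (model == 1) {
    Veq = mp[0]; Vth = mp[1]; Vr = mp[2]; R = mp[3]; tau = mp[4];
    tauref = mp[5]; eta = mp[6];
  } else {
    C = mp[0]; kq = mp[1]; Vc = mp[2]; Veq = mp[3]; Vth = mp[4]; Vr = mp[5];
    a = mp[6]; b = mp[7]; dU = mp[8]; Rscale = mp[9]; eta = mp[10];
  }
  const double Rfac = (model == 1) ? R : Rscale;
  const int nsteps = (int)std::lround(duration / dt);
  const int nev = ev_ch.size(), next = ext_t.size();

  std::vector<double> W1(W0.begin(), W0.end());
  std::vector<double> W2;
  if (n_msn == 2) W2.assign(W20.begin(), W20.end());

  // per-MSN membrane state
  double V1 = Veq, U1 = 0, refr1 = -1e9;
  double V2 = Veq, U2 = 0, refr2 = -1e9;
  // synaptic kernel state, weighted at spike arrival (per MSN, per channel)
  // exponential: g' = -g/Ts (bump W/Ts); alpha: x' = -x/Ts, g' = (x-g)/Ts
  std::vector<double> g1(P, 0.0), x1(P, 0.0), g2(P, 0.0), x2(P, 0.0);
  double ge1 = 0, xe1 = 0, ge2 = 0, xe2 = 0;  // external channel
  // plasticity traces
  std::vector<Trace> S;  // shared pre traces
  S.reserve(P);
  for (int i = 0; i < P; ++i) S.emplace_back(tau_s);
  Trace Tp1(tau_s), Tp2(tau_s);  // post traces per MSN

  std::vector<double> sp1, sp2;
  NumericVector vtr1, vtr2;
  if (record_v) { vtr1 = NumericVector(nsteps + 1); vtr1[0] = Veq; }
  if (record_v && n_msn == 2) { vtr2 = NumericVector(nsteps + 1); vtr2[0] = Veq; }
  std::vector<double> wsnap_t;
  std::vector<std::vector<double>> wsnap;
  double next_snap = record_w_every > 0 ? record_w_every : 1e18;

  int ei = 0, xi = 0;
  const double sq_dt = std::sqrt(dt);

  for (int s = 0; s < nsteps; ++s) {
    double t = s * dt, tnext = (s + 1) * dt;
    bool updated = false;

    // --- cortical events in [t, t+dt) -----------------------------------
    while (ei < nev && ev_t[ei] < tnext) {
      int c = ev_ch[ei] - 1;
      double te = t;  // left-edge convention
      // voltage/current effect uses W(t-), i.e. the weight before this
      // event's own plasticity update
      double w1 = W1[c], w2 = (n_msn == 2) ? W2[c] : 0.0;
      if (plastic) {
        double post1 = Tp1.at(te);
        W1[c] += eps * (A_post_pre * post1 + A_reward1);
        if (n_msn == 2) {
          double post2 = Tp2.at(te);
          W2[c] += eps * (A_post_pre * post2 + A_reward2);
        }
        S[c].bump(te);
        updated = true;
      }
      if (kernel == 0) {
        if (!(model == 1 && te < refr1)) V1 += Rfac * w1;  // discarded in refractory
        if (n_msn == 2 && !(model == 1 && te < refr2)) V2 += Rfac * w2;
      } else if (kernel == 1) {
        g1[c] += w1 / Ts;
        if (n_msn == 2) g2[c] += w2 / Ts;
      } else {
        x1[c] += w1 / Ts;
        if (n_msn == 2) x2[c] += w2 / Ts;
      }
      ++ei;
    }
    // --- external (non-plastic) events ----------------------------------
    while (xi < next && ext_t[xi] < tnext) {
      if (kernel == 0) {
        if (!(model == 1 && t < refr1)) V1 += Rfac * W_ext;
        if (n_msn == 2 && !(model == 1 && t < refr2)) V2 += Rfac * W_ext;
      } else if (kernel == 1) {
        ge1 += W_ext / Ts; if (n_msn == 2) ge2 += W_ext / Ts;
      } else {
        xe1 += W_ext / Ts; if (n_msn == 2) xe2 += W_ext / Ts;
      }
      ++xi;
    }

    // --- membrane integration over [t, t+dt) ----------------------------
    double drive1 = 0, drive2 = 0;
    if (kernel != 0) {
      for (int i = 0; i < P; ++i) drive1 += g1[i];
      drive1 += ge1;
      if (n_msn == 2) { for (int i = 0; i < P; ++i) drive2 += g2[i]; drive2 += ge2; }
    }
    if (model == 1) {
      if (t >= refr1) {
        V1 += dt * (-(V1 - Veq) / tau) + dt * Rfac * drive1;
        if (noise) V1 += eta * sq_dt * norm_rand();
      } else V1 = Vr;
      if (n_msn == 2) {
        if (t >= refr2) {
          V2 += dt * (-(V2 - Veq) / tau) + dt * Rfac * drive2;
          if (noise) V2 += eta * sq_dt * norm_rand();
        } else V2 = Vr;
      }
    } else {
      double q1 = 1e-3 * kq * (V1 - Vc) * (V1 - Veq);
      double dV1 = dt * ((q1 - U1) / C) + dt * Rfac * drive1;
      U1 += dt * a * (b * (V1 - Veq) - U1);
      V1 += dV1;
      if (noise) V1 += eta * sq_dt * norm_rand();
      if (n_msn == 2) {
        double q2 = 1e-3 * kq * (V2 - Vc) * (V2 - Veq);
        double dV2 = dt * ((q2 - U2) / C) + dt * Rfac * drive2;
        U2 += dt * a * (b * (V2 - Veq) - U2);
        V2 += dV2;
        if (noise) V2 += eta * sq_dt * norm_rand();
      }
    }

    // --- synaptic kernel state decay (Euler, using start-of-step values) -
    if (kernel == 1) {
      double f = 1.0 - dt / Ts;
      for (int i = 0; i < P; ++i) { g1[i] *= f; if (n_msn == 2) g2[i] *= f; }
      ge1 *= f; ge2 *= f;
    } else if (kernel == 2) {
      double f = 1.0 - dt / Ts;
      for (int i = 0; i < P; ++i) {
        double nx = x1[i] * f;
        g1[i] += dt * (x1[i] - g1[i]) / Ts;
        x1[i] = nx;
        if (n_msn == 2) {
          double nx2 = x2[i] * f;
          g2[i] += dt * (x2[i] - g2[i]) / Ts;
          x2[i] = nx2;
        }
      }
      double nxe = xe1 * f; ge1 += dt * (xe1 - ge1) / Ts; xe1 = nxe;
      nxe = xe2 * f; ge2 += dt * (xe2 - ge2) / Ts; xe2 = nxe;
    }

    // --- threshold detection; MSN2 first so its collateral inhibition can
    //     veto an MSN1 spike in the same step --------------------------------
    if (n_msn == 2) {
      bool fire2 = (V2 >= Vth) || !std::isfinite(V2);
      if (model == 1 && t < refr2) fire2 = false;
      if (fire2) {
        sp2.push_back(t);
        V2 = Vr;
        if (model == 1) refr2 = t + tauref; else U2 += dU;
        if (plastic) {
          for (int i = 0; i < P; ++i) W2[i] += eps * A_pre_post * S[i].at(t);
          Tp2.bump(t);
          updated = true;
        }
        V1 += Rfac * J;  // instantaneous collateral inhibition
      }
    }
    {
      bool fire1 = (V1 >= Vth) || !std::isfinite(V1);
      if (model == 1 && t < refr1) fire1 = false;
      if (fire1) {
        sp1.push_back(t);
        V1 = Vr;
        if (model == 1) refr1 = t + tauref; else U1 += dU;
        if (plastic) {
          for (int i = 0; i < P; ++i) W1[i] += eps * A_pre_post * S[i].at(t);
          Tp1.bump(t);
          updated = true;
        }
      }
    }

    // clip the net plasticity update of this step; within one Euler step
    // sub-updates are simultaneous at the integration resolution
    if (updated) {
      for (int i = 0; i < P; ++i) {
        W1[i] = clipw(W1[i], w_min, w_max);
        if (n_msn == 2) W2[i] = clipw(W2[i], w_min, w_max);
      }
    }

    if (record_v) { vtr1[s + 1] = V1; if (n_msn == 2) vtr2[s + 1] = V2; }
    if (tnext >= next_snap - 1e-9) {
      wsnap_t.push_back(tnext);
      wsnap.push_back(W1);
      next_snap += record_w_every;
    }
  }

  List out = List::create(
      _["spikes"] = wrap(sp1), _["weights"] = wrap(W1),
      _["spikes2"] = wrap(sp2),
      _["weights2"] = (n_msn == 2) ? wrap(W2) : R_NilValue);
  if (record_v) {
    out["voltage"] = vtr1;
    if (n_msn == 2) out["voltage2"] = vtr2;
  }
  if (record_w_every > 0) {
    NumericMatrix M(wsnap.size(), P);
    for (size_t r = 0; r < wsnap.size(); ++r)
      for (int i = 0; i < P; ++i) M(r, i) = wsnap[r][i];
    out["weight_snapshots"] = M;
    out["snapshot_times"] = wrap(wsnap_t);
  }
  return out;
}
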