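#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Gate rate functions of the classical squid-axon membrane (mV, 1/ms).
static inline double vtrap(double x, double y) {
  // x / (1 - exp(-x/y)) with the 0/0 limit handled
  double r = x / y;
  if (std::fabs(r) < 1e-7) return y * (1.0 - r / 2.0);
  return x / (1.0 - std::exp(-r));
}

struct HHRates {
  double am, bm, ah, bh, an, bn;
};

static inline HHRates hh_rates(double v) {
  HHRates r;
  r.am = 0.1 * vtrap(v + 40.0, 10.0);
  r.bm = 4.0 * std::exp(-(v + 65.0) / 18.0);
  r.ah = 0.07 * std::exp(-(v + 65.0) / 20.0);
  r.bh = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  r.an = 0.01 * vtrap(v + 55.0, 10.0);
  r.bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
  return r;
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Derivative of (v, m, h, n) under receptor drive + classical HH currents.
// g_eff / e_rev: per-detector effective conductance (nS) and reversal (mV),
// constant over the trial because channel gating depends on the stimulus only.
static inline void hh_deriv(const double *s, double *ds,
                            const std::vector<double> &g_eff,
                            const std::vector<double> &e_rev,
                            double gNa, double gK, double gL,
                            double ENa, double EK, double EL,
                            double Cm, double I_noise) {
  double v = s[0];
  double m = clamp01(s[1]), h = clamp01(s[2]), n = clamp01(s[3]);
  double I_recep = I_noise;
  for (size_t i = 0; i < g_eff.size(); ++i)
    I_recep += g_eff[i] * (e_rev[i] - v);
  double I_ion = gNa * m * m * m * h * (v - ENa) +
                 gK * n * n * n * n * (v - EK) + gL * (v - EL);
  HHRates r = hh_rates(v);
  ds[0] = (I_recep - I_ion) / Cm;
  ds[1] = r.am * (1.0 - m) - r.bm * m;
  ds[2] = r.ah * (1.0 - h) - r.bh * h;
  ds[3] = r.an * (1.0 - n) - r.bn * n;
}

// [[Rcpp::export]]
NumericVector cpp_hh_rk4(NumericVector g_eff, NumericVector e_rev,
                         double gNa, double gK, double gL,
                         double ENa, double EK, double EL,
                         double Cm, int n_steps, double dt,
                         NumericVector noise_per_ms,
                         double v0, double m0, double h0, double n0,
                         double v_bound) {
  std::vector<double> ge(g_eff.begin(), g_eff.end());
  std::vector<double> er(e_rev.begin(), e_rev.end());
  NumericVector out(n_steps + 1);
  double s[4] = {v0, m0, h0, n0};
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  out[0] = v0;
  bool has_noise = noise_per_ms.size() > 0;
  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;
    double In = 0.0;
    if (has_noise) {
      int idx = (int)std::floor(t);
      if (idx >= noise_per_ms.size()) idx = noise_per_ms.size() - 1;
      In = noise_per_ms[idx];
    }
    hh_deriv(s, k1, ge, er, gNa, gK, gL, ENa, EK, EL, Cm, In);
    for (int i = 0; i < 4; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
    hh_deriv(tmp, k2, ge, er, gNa, gK, gL, ENa, EK, EL, Cm, In);
    for (int i = 0; i < 4; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
    hh_deriv(tmp, k3, ge, er, gNa, gK, gL, ENa, EK, EL, Cm, In);
    for (int i = 0; i < 4; ++i) tmp[i] = s[i] + dt * k3[i];
    hh_deriv(tmp, k4, ge, er, gNa, gK, gL, ENa, EK, EL, Cm, In);
    for (int i = 0; i < 4; ++i)
      s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    for (int i = 1; i < 4; ++i) s[i] = clamp01(s[i]);
    if (!std::isfinite(s[0]) || std::fabs(s[0]) > v_bound)
      stop("membrane integration diverged at step %d (t = %.3f ms)", k + 1,
           (k + 1) * dt);
    out[k + 1] = s[0];
  }
  return out;
}

// Cleft glutamate concentration per presynaptic source on the step grid
// t_k = k*dt.  Alpha kernels are truncated 10*tau past each spike.
static void glut_matrix(const List &pre_spikes, double A, double tau,
                        double dt, int n_steps,
                        std::vector<std::vector<double> > &G) {
  int n_pre = pre_spikes.size();
  G.assign(n_pre, std::vector<double>(n_steps, 0.0));
  double win = 10.0 * tau;
  for (int j = 0; j < n_pre; ++j) {
    NumericVector ts = pre_spikes[j];
    for (int si = 0; si < ts.size(); ++si) {
      double t0 = ts[si];
      int k0 = (int)std::ceil(t0 / dt - 1e-9);
      if (k0 < 0) k0 = 0;
      int k1 = (int)std::floor((t0 + win) / dt);
      if (k1 > n_steps - 1) k1 = n_steps - 1;
      for (int k = k0; k <= k1; ++k) {
        double td = k * dt - t0;
        if (td < 0) continue;
        G[j][k] += A * (td / tau) * std::exp(1.0 - td / tau);
      }
    }
  }
}

// One feedforward layer: presynaptic spike times -> postsynaptic Izhikevich
// spike times.  Wp/Wu are n_post x n_pre conductance weights (nS) for the
// phosphorylated / unphosphorylated receptor pools.
static List layer_propagate(const List &pre_spikes,
                            const NumericMatrix &Wp, const NumericMatrix &Wu,
                            double A, double tau, double Kp, double Ku,
                            double E_ampa, double gain,
                            const NumericVector &a, const NumericVector &b,
                            const NumericVector &c, const NumericVector &d,
                            double dt, int n_steps, double v_bound,
                            bool return_v) {
  int n_pre = pre_spikes.size();
  int n_post = Wp.nrow();
  if (Wp.ncol() != n_pre || Wu.ncol() != n_pre || Wu.nrow() != n_post)
    stop("weight matrix dimensions do not match layer sizes");
  std::vector<std::vector<double> > G;
  glut_matrix(pre_spikes, A, tau, dt, n_steps, G);

  // gsyn(i, k) = sum_j Wp(i,j) * G_j/(G_j+Kp) + Wu(i,j) * G_j/(G_j+Ku)
  std::vector<double> gsyn((size_t)n_post * n_steps, 0.0);
  for (int j = 0; j < n_pre; ++j) {
    for (int k = 0; k < n_steps; ++k) {
      double g = G[j][k];
      if (g <= 0.0) continue;
      double hp = g / (g + Kp), hu = g / (g + Ku);
      for (int i = 0; i < n_post; ++i) {
        double w = Wp(i, j) * hp + Wu(i, j) * hu;
        if (w != 0.0) gsyn[(size_t)i * n_steps + k] += w;
      }
    }
  }

  std::vector<double> v(n_post, -65.0), u(n_post);
  for (int i = 0; i < n_post; ++i) u[i] = b[i] * v[i];
  std::vector<std::vector<double> > spikes(n_post);
  NumericMatrix vtrace;
  if (return_v) vtrace = NumericMatrix(n_post, n_steps);
  for (int k = 0; k < n_steps; ++k) {
    for (int i = 0; i < n_post; ++i) {
      double I = gain * gsyn[(size_t)i * n_steps + k] * (E_ampa - v[i]);
      double vn = v[i] + dt * (0.04 * v[i] * v[i] + 5.0 * v[i] + 140.0 -
                               u[i] + I);
      double un = u[i] + dt * a[i] * (b[i] * v[i] - u[i]);
      if (!std::isfinite(vn))
        stop("Izhikevich update diverged for neuron %d at step %d", i + 1,
             k + 1);
      if (vn >= 30.0) {
        spikes[i].push_back((k + 1) * dt);
        vn = c[i];
        un += d[i];
      }
      if (std::fabs(vn) > v_bound)
        stop("Izhikevich update diverged for neuron %d at step %d", i + 1,
             k + 1);
      v[i] = vn;
      u[i] = un;
      if (return_v) vtrace(i, k) = vn;
    }
  }
  List out_spk(n_post);
  for (int i = 0; i < n_post; ++i) out_spk[i] = wrap(spikes[i]);
  if (return_v) return List::create(_["spikes"] = out_spk, _["v"] = vtrace);
  return List::create(_["spikes"] = out_spk);
}

// [[Rcpp::export]]
List cpp_layer_propagate(List pre_spikes, NumericMatrix Wp, NumericMatrix Wu,
                         double A, double tau, double Kp, double Ku,
                         double E_ampa, double gain, NumericVector a,
                         NumericVector b, NumericVector c, NumericVector d,
                         double dt, int n_steps, double v_bound,
                         bool return_v) {
  return layer_propagate(pre_spikes, Wp, Wu, A, tau, Kp, Ku, E_ampa, gain, a,
                         b, c, d, dt, n_steps, v_bound, return_v);
}

// Full hidden cascade: input spike trains through every hidden layer.
// Wp_list/Wu_list/a_list/... have one element per layer gap.
// [[Rcpp::export]]
List cpp_run_hidden(List input_spikes, List Wp_list, List Wu_list,
                    double A, double tau, double Kp, double Ku,
                    double E_ampa, double gain, List a_list, List b_list,
                    List c_list, List d_list, double dt, int n_steps,
                    double v_bound) {
  int n_layers = Wp_list.size();
  List rasters(n_layers);
  List pre = input_spikes;
  for (int l = 0; l < n_layers; ++l) {
    List res = layer_propagate(pre, Wp_list[l], Wu_list[l], A, tau, Kp, Ku,
                               E_ampa, gain, a_list[l], b_list[l], c_list[l],
                               d_list[l], dt, n_steps, v_bound, false);
    rasters[l] = res["spikes"];
    pre = res["spikes"];
  }
  return rasters;
}

// Minimal |t_pre - t_post| for every (post, pre) pair of spike-time vectors;
// NA when either train is empty.  Both inputs are assumed sorted ascending.
// [[Rcpp::export]]
NumericMatrix cpp_min_cross_dist(List pre, List post) {
  int n_pre = pre.size(), n_post = post.size();
  NumericMatrix out(n_post, n_pre);
  for (int j = 0; j < n_pre; ++j) {
    NumericVector tp = pre[j];
    for (int i = 0; i < n_post; ++i) {
      NumericVector tq = post[i];
      if (tp.size() == 0 || tq.size() == 0) {
        out(i, j) = NA_REAL;
        continue;
      }
      // two-pointer sweep over sorted trains
      double best = R_PosInf;
      int x = 0, y = 0;
      while (x < tp.size() && y < tq.size()) {
        double diff = std::fabs(tp[x] - tq[y]);
        if (diff < best) best = diff;
        if (tp[x] < tq[y]) ++x; else ++y;
      }
      out(i, j) = best;
    }
  }
  return out;
}
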