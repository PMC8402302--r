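// Fixed-step RK4 integrators for the FitzHugh-Nagumo neuron and for the
// one-way coupled pre -> memristor -> post system. Device parameters are
// held piecewise-constant between resampling events; all random draws are
// made in R and passed in, so results are reproducible independent of the
// C++ RNG.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct FhnP {
  double eps, I, alpha, beta;
};

static inline double f_cubic(double u) { return u - u * u * u / 3.0; }

static inline double g_pw(double u, const FhnP &p) {
  return (u < 0.0) ? p.alpha * u : p.beta * u;
}

// device parameter layout: 0 rho, 1 b, 2 Eb, 3 Em, 4 alpha1, 5 A, 6 kT
static inline double w_inf(double u, const double *d) {
  double w = d[5] * std::exp(-(d[3] - d[4] * u) / d[6]);
  if (w < 0.0) w = 0.0;
  if (w > 1.0) w = 1.0;
  return w;
}

static inline double j_mix(double u, double w, const double *d) {
  return w * u / d[0] + (1.0 - w) * u * std::exp(d[1] * u - d[2]);
}

static FhnP as_fhn(const NumericVector &v) {
  FhnP p;
  p.eps = v[0];
  p.I = v[1];
  p.alpha = v[2];
  p.beta = v[3];
  return p;
}

// [[Rcpp::export]]
List simulate_fhn_cpp(NumericVector params, double u0, double v0, double dt,
                      int n_steps, int record_every) {
  FhnP p = as_fhn(params);
  int n_rec = n_steps / record_every + 1;
  NumericVector t(n_rec), u(n_rec), v(n_rec);
  double uu = u0, vv = v0;
  t[0] = 0.0;
  u[0] = uu;
  v[0] = vv;
  int k = 1;
  for (int i = 1; i <= n_steps; ++i) {
    double k1u = f_cubic(uu) - vv;
    double k1v = p.eps * (g_pw(uu, p) - vv) - p.I;
    double u2 = uu + 0.5 * dt * k1u, v2 = vv + 0.5 * dt * k1v;
    double k2u = f_cubic(u2) - v2;
    double k2v = p.eps * (g_pw(u2, p) - v2) - p.I;
    double u3 = uu + 0.5 * dt * k2u, v3 = vv + 0.5 * dt * k2v;
    double k3u = f_cubic(u3) - v3;
    double k3v = p.eps * (g_pw(u3, p) - v3) - p.I;
    double u4 = uu + dt * k3u, v4 = vv + dt * k3v;
    double k4u = f_cubic(u4) - v4;
    double k4v = p.eps * (g_pw(u4, p) - v4) - p.I;
    uu += dt / 6.0 * (k1u + 2.0 * k2u + 2.0 * k3u + k4u);
    vv += dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
    if (!std::isfinite(uu) || !std::isfinite(vv))
      stop("integration diverged at step %d (t = %g)", i, i * dt);
    if (i % record_every == 0) {
      t[k] = i * dt;
      u[k] = uu;
      v[k] = vv;
      ++k;
    }
  }
  return List::create(_["t"] = t, _["u"] = u, _["v"] = v);
}

struct CoupledDeriv {
  double du1, dv1, du2, dv2, dw;
};

static inline CoupledDeriv coupled_rhs(double u1, double v1, double u2,
                                       double v2, double w, const FhnP &pre,
                                       const FhnP &post, const double *dev,
                                       double gain, double Sd, int relax,
                                       double tau_w) {
  CoupledDeriv d;
  double udev = gain * u1;
  double wloc = relax ? w : w_inf(udev, dev);
  double j = j_mix(udev, wloc, dev);
  d.du1 = f_cubic(u1) - v1;
  d.dv1 = pre.eps * (g_pw(u1, pre) - v1) - pre.I;
  d.du2 = f_cubic(u2) - v2 + j * Sd;
  d.dv2 = post.eps * (g_pw(u2, post) - v2) - post.I;
  d.dw = relax ? (w_inf(udev, dev) - w) / tau_w : 0.0;
  return d;
}

// draws: n_blocks x 3 matrix of multiplicative factors for (Em, Eb, rho);
// block i applies to steps [i*resample_every, (i+1)*resample_every).
// [[Rcpp::export]]
List simulate_coupled_cpp(NumericVector pre_params, NumericVector post_params,
                          NumericVector dev_params, NumericMatrix draws,
                          int resample_every, NumericVector init, double gain,
                          double S, double d_load, double dt, int n_steps,
                          int record_every, int relax, double tau_w) {
  FhnP pre = as_fhn(pre_params), post = as_fhn(post_params);
  double Sd = S * d_load;
  double dev[7];
  for (int q = 0; q < 7; ++q) dev[q] = dev_params[q];
  double u1 = init[0], v1 = init[1], u2 = init[2], v2 = init[3];
  double w = (init.size() > 4) ? init[4] : w_inf(gain * u1, dev);
  int n_rec = n_steps / record_every + 1;
  NumericVector t(n_rec), U1(n_rec), V1(n_rec), U2(n_rec), V2(n_rec),
      J(n_rec), W(n_rec), C(n_rec);
  int block = -1;
  double cur[7];
  for (int q = 0; q < 7; ++q) cur[q] = dev[q];
  int k = 0;
  for (int i = 0; i <= n_steps; ++i) {
    int bl = (resample_every > 0 && draws.nrow() > 0)
                 ? std::min<int>(i / resample_every, draws.nrow() - 1)
                 : -1;
    if (bl != block && bl >= 0) {
      block = bl;
      cur[3] = dev[3] * draws(block, 0);  // Em
      cur[2] = dev[2] * draws(block, 1);  // Eb
      cur[0] = dev[0] * draws(block, 2);  // rho
    }
    if (i % record_every == 0) {
      double udev = gain * u1;
      double wl = relax ? w : w_inf(udev, cur);
      double j = j_mix(udev, wl, cur);
      t[k] = i * dt;
      U1[k] = u1;
      V1[k] = v1;
      U2[k] = u2;
      V2[k] = v2;
      J[k] = j;
      W[k] = wl;
      C[k] = j * Sd;
      ++k;
    }
    if (i == n_steps) break;
    CoupledDeriv k1 = coupled_rhs(u1, v1, u2, v2, w, pre, post, cur, gain, Sd,
                                  relax, tau_w);
    CoupledDeriv k2 = coupled_rhs(u1 + 0.5 * dt * k1.du1, v1 + 0.5 * dt * k1.dv1,
                                  u2 + 0.5 * dt * k1.du2, v2 + 0.5 * dt * k1.dv2,
                                  w + 0.5 * dt * k1.dw, pre, post, cur, gain,
                                  Sd, relax, tau_w);
    CoupledDeriv k3 = coupled_rhs(u1 + 0.5 * dt * k2.du1, v1 + 0.5 * dt * k2.dv1,
                                  u2 + 0.5 * dt * k2.du2, v2 + 0.5 * dt * k2.dv2,
                                  w + 0.5 * dt * k2.dw, pre, post, cur, gain,
                                  Sd, relax, tau_w);
    CoupledDeriv k4 = coupled_rhs(u1 + dt * k3.du1, v1 + dt * k3.dv1,
                                  u2 + dt * k3.du2, v2 + dt * k3.dv2,
                                  w + dt * k3.dw, pre, post, cur, gain, Sd,
                                  relax, tau_w);
    u1 += dt / 6.0 * (k1.du1 + 2.0 * k2.du1 + 2.0 * k3.du1 + k4.du1);
    v1 += dt / 6.0 * (k1.dv1 + 2.0 * k2.dv1 + 2.0 * k3.dv1 + k4.dv1);
    u2 += dt / 6.0 * (k1.du2 + 2.0 * k2.du2 + 2.0 * k3.du2 + k4.du2);
    v2 += dt / 6.0 * (k1.dv2 + 2.0 * k2.dv2 + 2.0 * k3.dv2 + k4.dv2);
    if (relax) {
      w += dt / 6.0 * (k1.dw + 2.0 * k2.dw + 2.0 * k3.dw + k4.dw);
      if (w < 0.0) w = 0.0;
      if (w > 1.0) w = 1.0;
    }
    if (!std::isfinite(u1) || !std::isfinite(v1) || !std::isfinite(u2) ||
        !std::isfinite(v2))
      stop("integration diverged at step %d (t = %g, u1 = %g, u2 = %g)",
           i + 1, (i + 1) * dt, u1, u2);
  }
  return List::create(_["t"] = t, _["u1"] = U1, _["v1"] = V1, _["u2"] = U2,
                      _["v2"] = V2, _["j"] = J, _["w"] = W, _["c"] = C);
}
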