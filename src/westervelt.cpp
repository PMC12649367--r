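// Time-explicit kernel for the conservative first-order Westervelt system on
// an axisymmetric staggered grid (pressure at cell centers, velocities at
// faces), classical 4-stage Runge-Kutta at fixed step.
//
//   (1/(rho c0^2)) dp/dt + div[(1 + beta p/(rho c0^2)) u] = 0
//   rho du/dt + grad p = delta rho grad(div u)
//
// The diffusivity term realizes thermoviscous loss (lossy wave equation
// p_tt = c^2 lap p + delta lap p_t, attenuation alpha = delta w^2 / (2 c^3)).
// A Rayleigh sponge (-gamma x) damps both fields in the absorber ring; the
// source is a time-varying pressure Dirichlet on the cap cells.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
using namespace Rcpp;

namespace {

struct Fields {
  int nr, nz;
  std::vector<double> p, ur, uz;  // p: nr*nz, ur: (nr+1)*nz, uz: nr*(nz+1)
  Fields(int nr_, int nz_) : nr(nr_), nz(nz_),
    p(nr_ * nz_, 0.0), ur((nr_ + 1) * nz_, 0.0), uz(nr_ * (nz_ + 1), 0.0) {}
};

inline void axpy(std::vector<double>& y, const std::vector<double>& x,
                 double a) {
  const size_t n = y.size();
  for (size_t i = 0; i < n; ++i) y[i] += a * x[i];
}

class Kernel {
public:
  int nr, nz;
  double dx, dt, inv_dx;
  bool linear;
  std::vector<double> rho, K, delta, beta, gamma, bK;  // cell fields
  std::vector<double> irho_fr, delta_fr, gamma_fr;     // radial faces
  std::vector<double> irho_fz, delta_fz, gamma_fz;     // axial faces
  std::vector<double> rf, inv_rc_dx;
  std::vector<int> src;                                // cell indices
  std::vector<double> src_delay;                       // per source cell, s
  // pulse samples (uniform)
  std::vector<double> pulse;
  double pulse_rate, pulse_t0;
  // scratch
  std::vector<double> Fr, Fz, divU;

  inline int idc(int i, int k) const { return i + k * nr; }
  inline int idr(int j, int k) const { return j + k * (nr + 1); }
  inline int idz(int i, int m) const { return i + m * nr; }

  double pulse_at(double t) const {
    double pos = (t - pulse_t0) * pulse_rate;
    if (pos <= 0.0 || pos >= (double)(pulse.size() - 1)) return 0.0;
    int j = (int)pos;
    double f = pos - j;
    return pulse[j] * (1.0 - f) + pulse[j + 1] * f;
  }

  bool soft_source;
  double soft_scale;   // 2 c / dx: plane-sheet forcing radiating the pulse
                       // amplitude to each side

  // hard source: pressure Dirichlet on the cap cells
  void impose(Fields& y, double t) const {
    if (soft_source) return;
    for (size_t s = 0; s < src.size(); ++s)
      y.p[src[s]] = pulse_at(t - src_delay[s]);
  }

  // soft source: additive dp/dt forcing (transparent to reflections)
  void force(Fields& dy, double t) const {
    if (!soft_source) return;
    for (size_t s = 0; s < src.size(); ++s)
      dy.p[src[s]] += soft_scale * pulse_at(t - src_delay[s]);
  }

  // dy = f(y); boundary faces of dur/duz stay zero (never written).
  // All 1/dx factors are pre-folded into the face coefficient arrays.
  void deriv(const Fields& y, Fields& dy) {
    // face fluxes of the (possibly nonlinear) mass flux and plain div u
    for (int k = 0; k < nz; ++k) {
      for (int j = 1; j < nr; ++j) {
        int cl = idc(j - 1, k), cr = idc(j, k);
        double fac = linear ? 1.0
          : 1.0 + 0.5 * (bK[cl] * y.p[cl] + bK[cr] * y.p[cr]);
        Fr[idr(j, k)] = fac * y.ur[idr(j, k)];
      }
    }
    for (int m = 1; m < nz; ++m) {
      for (int i = 0; i < nr; ++i) {
        int cl = idc(i, m - 1), cr = idc(i, m);
        double fac = linear ? 1.0
          : 1.0 + 0.5 * (bK[cl] * y.p[cl] + bK[cr] * y.p[cr]);
        Fz[idz(i, m)] = fac * y.uz[idz(i, m)];
      }
    }
    for (int k = 0; k < nz; ++k) {
      for (int i = 0; i < nr; ++i) {
        int c = idc(i, k);
        double dvF = (rf[i + 1] * Fr[idr(i + 1, k)] - rf[i] * Fr[idr(i, k)]) *
                       inv_rc_dx[i] +
                     (Fz[idz(i, k + 1)] - Fz[idz(i, k)]) * inv_dx;
        double dvU = (rf[i + 1] * y.ur[idr(i + 1, k)] -
                      rf[i] * y.ur[idr(i, k)]) * inv_rc_dx[i] +
                     (y.uz[idz(i, k + 1)] - y.uz[idz(i, k)]) * inv_dx;
        divU[c] = dvU;
        dy.p[c] = -K[c] * dvF - gamma[c] * y.p[c];
      }
    }
    // irho_f* and delta_f* carry a 1/dx factor each
    for (int k = 0; k < nz; ++k) {
      for (int j = 1; j < nr; ++j) {
        int f = idr(j, k);
        int cl = idc(j - 1, k), cr = idc(j, k);
        dy.ur[f] = -(y.p[cr] - y.p[cl]) * irho_fr[f] +
                   delta_fr[f] * (divU[cr] - divU[cl]) -
                   gamma_fr[f] * y.ur[f];
      }
    }
    for (int m = 1; m < nz; ++m) {
      for (int i = 0; i < nr; ++i) {
        int f = idz(i, m);
        int cl = idc(i, m - 1), cr = idc(i, m);
        dy.uz[f] = -(y.p[cr] - y.p[cl]) * irho_fz[f] +
                   delta_fz[f] * (divU[cr] - divU[cl]) -
                   gamma_fz[f] * y.uz[f];
      }
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".westervelt_chunk")]]
List westervelt_chunk(NumericMatrix p0, NumericMatrix ur0, NumericMatrix uz0,
                      NumericMatrix rho, NumericMatrix K, NumericMatrix delta,
                      NumericMatrix beta, NumericMatrix gamma,
                      IntegerVector src_cells, NumericVector src_delay,
                      NumericVector pulse,
                      double pulse_rate, double pulse_t0,
                      double t, double dt, int nsteps, double dx,
                      bool linear, bool soft_source, double soft_scale,
                      IntegerVector probe_cells,
                      NumericMatrix envelope, double envelope_start) {
  const int nr = p0.nrow(), nz = p0.ncol();
#ifdef __SSE2__
  // the sponge drives fields through the denormal range, which cripples
  // x86 FP throughput; flush-to-zero is harmless at these amplitudes
  unsigned int csr = _mm_getcsr();
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
  Kernel kn;
  kn.nr = nr; kn.nz = nz; kn.dx = dx; kn.dt = dt; kn.linear = linear;
  kn.inv_dx = 1.0 / dx;
  kn.rho.assign(rho.begin(), rho.end());
  kn.K.assign(K.begin(), K.end());
  kn.delta.assign(delta.begin(), delta.end());
  kn.beta.assign(beta.begin(), beta.end());
  kn.gamma.assign(gamma.begin(), gamma.end());
  kn.bK.resize(nr * nz);
  for (int c = 0; c < nr * nz; ++c) kn.bK[c] = kn.beta[c] / kn.K[c];
  kn.soft_source = soft_source;
  kn.soft_scale = soft_scale;
  kn.src.assign(src_cells.begin(), src_cells.end());
  kn.src_delay.assign(src_delay.begin(), src_delay.end());
  kn.pulse.assign(pulse.begin(), pulse.end());
  kn.pulse_rate = pulse_rate; kn.pulse_t0 = pulse_t0;
  kn.Fr.assign((nr + 1) * nz, 0.0);
  kn.Fz.assign(nr * (nz + 1), 0.0);
  kn.divU.assign(nr * nz, 0.0);

  kn.rf.resize(nr + 1);
  kn.inv_rc_dx.resize(nr);
  for (int j = 0; j <= nr; ++j) kn.rf[j] = j * dx;
  for (int i = 0; i < nr; ++i) kn.inv_rc_dx[i] = 1.0 / ((i + 0.5) * dx * dx);

  // face-averaged material fields: harmonic-mean density, arithmetic-mean
  // diffusivity and sponge rate
  kn.irho_fr.assign((nr + 1) * nz, 0.0);
  kn.delta_fr.assign((nr + 1) * nz, 0.0);
  kn.gamma_fr.assign((nr + 1) * nz, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 1; j < nr; ++j) {
      int f = kn.idr(j, k), cl = kn.idc(j - 1, k), cr = kn.idc(j, k);
      kn.irho_fr[f] = 0.5 * (1.0 / kn.rho[cl] + 1.0 / kn.rho[cr]) * kn.inv_dx;
      kn.delta_fr[f] = 0.5 * (kn.delta[cl] + kn.delta[cr]) * kn.inv_dx;
      kn.gamma_fr[f] = 0.5 * (kn.gamma[cl] + kn.gamma[cr]);
    }
  kn.irho_fz.assign(nr * (nz + 1), 0.0);
  kn.delta_fz.assign(nr * (nz + 1), 0.0);
  kn.gamma_fz.assign(nr * (nz + 1), 0.0);
  for (int m = 1; m < nz; ++m)
    for (int i = 0; i < nr; ++i) {
      int f = kn.idz(i, m), cl = kn.idc(i, m - 1), cr = kn.idc(i, m);
      kn.irho_fz[f] = 0.5 * (1.0 / kn.rho[cl] + 1.0 / kn.rho[cr]) * kn.inv_dx;
      kn.delta_fz[f] = 0.5 * (kn.delta[cl] + kn.delta[cr]) * kn.inv_dx;
      kn.gamma_fz[f] = 0.5 * (kn.gamma[cl] + kn.gamma[cr]);
    }

  Fields y(nr, nz), yt(nr, nz);
  Fields k1(nr, nz), k2(nr, nz), k3(nr, nz), k4(nr, nz);
  std::copy(p0.begin(), p0.end(), y.p.begin());
  std::copy(ur0.begin(), ur0.end(), y.ur.begin());
  std::copy(uz0.begin(), uz0.end(), y.uz.begin());

  std::vector<double> env(envelope.begin(), envelope.end());
  const int npr = probe_cells.size();
  NumericMatrix prec(nsteps, npr);
  NumericVector ptimes(nsteps);

  for (int s = 0; s < nsteps; ++s) {
    kn.impose(y, t);
    kn.deriv(y, k1); kn.force(k1, t);

    yt = y; axpy(yt.p, k1.p, dt / 2); axpy(yt.ur, k1.ur, dt / 2);
    axpy(yt.uz, k1.uz, dt / 2);
    kn.impose(yt, t + dt / 2);
    kn.deriv(yt, k2); kn.force(k2, t + dt / 2);

    yt = y; axpy(yt.p, k2.p, dt / 2); axpy(yt.ur, k2.ur, dt / 2);
    axpy(yt.uz, k2.uz, dt / 2);
    kn.impose(yt, t + dt / 2);
    kn.deriv(yt, k3); kn.force(k3, t + dt / 2);

    yt = y; axpy(yt.p, k3.p, dt); axpy(yt.ur, k3.ur, dt);
    axpy(yt.uz, k3.uz, dt);
    kn.impose(yt, t + dt);
    kn.deriv(yt, k4); kn.force(k4, t + dt);

    for (size_t i = 0; i < y.p.size(); ++i)
      y.p[i] += dt / 6.0 * (k1.p[i] + 2 * k2.p[i] + 2 * k3.p[i] + k4.p[i]);
    for (size_t i = 0; i < y.ur.size(); ++i)
      y.ur[i] += dt / 6.0 * (k1.ur[i] + 2 * k2.ur[i] + 2 * k3.ur[i] + k4.ur[i]);
    for (size_t i = 0; i < y.uz.size(); ++i)
      y.uz[i] += dt / 6.0 * (k1.uz[i] + 2 * k2.uz[i] + 2 * k3.uz[i] + k4.uz[i]);
    t += dt;
    kn.impose(y, t);

    double mx = 0.0;
    const bool acc = t >= envelope_start;
    for (size_t i = 0; i < y.p.size(); ++i) {
      double a = std::fabs(y.p[i]);
      if (acc && a > env[i]) env[i] = a;
      if (a > mx) mx = a;
    }
    if (!std::isfinite(mx)) {
      int bad = 0;
      for (size_t i = 0; i < y.p.size(); ++i)
        if (!std::isfinite(y.p[i])) { bad = (int)i; break; }
      stop("time-explicit instability: non-finite pressure at cell (i=%d, k=%d), step %d",
           bad % nr + 1, bad / nr + 1, s + 1);
    }
    for (int q = 0; q < npr; ++q) prec(s, q) = y.p[probe_cells[q]];
    ptimes[s] = t;
    if (s % 200 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pout(nr, nz), urout(nr + 1, nz), uzout(nr, nz + 1),
      envout(nr, nz);
  std::copy(y.p.begin(), y.p.end(), pout.begin());
  std::copy(y.ur.begin(), y.ur.end(), urout.begin());
  std::copy(y.uz.begin(), y.uz.end(), uzout.begin());
  std::copy(env.begin(), env.end(), envout.begin());
#ifdef __SSE2__
  _mm_setcsr(csr);
#endif
  return List::create(_["p"] = pout, _["ur"] = urout, _["uz"] = uzout,
                      _["t"] = t, _["envelope"] = envout,
                      _["probe_pressures"] = prec, _["probe_times"] = ptimes);
}
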