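// Core energetics and Langevin integration for the extended
// Peyrard-Bishop-Dauxois chain coupled to a sliding Brownian particle.
//
// Conventions: energies in eV, lengths in Angstrom, mass in amu; the derived
// time unit is A*sqrt(amu/eV) (~10 fs). Sites are 0-based here; R wrappers
// translate to 1-based indices. The particle coordinate x lives on [0, N)
// with periodic wrap applied only at the end of a full step; Gaussian wells
// are not wrapped across the boundary (clamped ends keep the field ~0 there).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct ChainPars {
  std::vector<double> D, a;   // per-site Morse depth / inverse width
  double G, bpos, bw;         // Gaussian solvent barrier
  double k, rho, alpha;       // anharmonic stacking
  double Ap, sigp, ysat;      // particle coupling
  double mass, mass_p;
  int N;
};

ChainPars unpack(const NumericVector& D, const NumericVector& a,
                 const List& pars) {
  ChainPars p;
  p.N = D.size();
  p.D.assign(D.begin(), D.end());
  p.a.assign(a.begin(), a.end());
  p.G = as<double>(pars["G_bar"]);
  p.bpos = as<double>(pars["b_pos"]);
  p.bw = as<double>(pars["b_w"]);
  p.k = as<double>(pars["k_stack"]);
  p.rho = as<double>(pars["rho"]);
  p.alpha = as<double>(pars["alpha"]);
  p.Ap = as<double>(pars["A_p"]);
  p.sigp = as<double>(pars["sigma_p"]);
  p.ysat = as<double>(pars["y_sat"]);
  p.mass = as<double>(pars["mass"]);
  p.mass_p = as<double>(pars["mass_p"]);
  return p;
}

inline double morse_barrier(double y, double D, double a, const ChainPars& p) {
  const double ey = std::exp(-a * y);
  double v = D * (ey - 1.0) * (ey - 1.0);
  if (p.G > 0.0) {
    const double z = (y - p.bpos) / p.bw;
    v += p.G * std::exp(-0.5 * z * z);
  }
  return v;
}

inline double morse_barrier_dy(double y, double D, double a,
                               const ChainPars& p) {
  const double ey = std::exp(-a * y);
  double d = 2.0 * D * a * ey * (1.0 - ey);
  if (p.G > 0.0) {
    const double z = (y - p.bpos) / p.bw;
    d += -p.G * (z / p.bw) * std::exp(-0.5 * z * z);
  }
  return d;
}

inline double stack(double yn, double yp, const ChainPars& p) {
  const double d = yn - yp;
  const double e = p.rho * std::exp(-p.alpha * (yn + yp));
  return 0.5 * p.k * (1.0 + e) * d * d;
}

// saturation of the particle-chain coupling: linear near 0, bounded at 1,
// zero for compressed pairs
inline double fsat(double y, double ysat) {
  return (y > 0.0) ? std::tanh(y / ysat) : 0.0;
}
inline double fsat_dy(double y, double ysat) {
  if (y <= 0.0) return 0.0;
  const double t = std::tanh(y / ysat);
  return (1.0 - t * t) / ysat;
}

// periodic wrap into [0, L)
inline double wrap_period(double x, double L) {
  return x - L * std::floor(x / L);
}

// window of wells within 6 sigma of the particle (truncation error < 1e-6)
inline void well_window(double x, double sigp, int N, int& lo, int& hi) {
  lo = (int)std::ceil(x - 6.0 * sigp);
  hi = (int)std::floor(x + 6.0 * sigp);
  if (lo < 0) lo = 0;
  if (hi > N - 1) hi = N - 1;
}

double particle_energy(const std::vector<double>& y, double x,
                       const ChainPars& p) {
  if (p.Ap == 0.0) return 0.0;
  int lo, hi;
  well_window(x, p.sigp, p.N, lo, hi);
  double v = 0.0;
  for (int n = lo; n <= hi; ++n) {
    const double z = (x - n) / p.sigp;
    v += fsat(y[n], p.ysat) * std::exp(-0.5 * z * z);
  }
  return -p.Ap * v;
}

double chain_energy(const std::vector<double>& y, const ChainPars& p) {
  double v = 0.0;
  for (int n = 0; n < p.N; ++n) v += morse_barrier(y[n], p.D[n], p.a[n], p);
  for (int n = 1; n < p.N; ++n) v += stack(y[n], y[n - 1], p);
  return v;
}

// fy[n] = -dH/dy_n, fx = -dH/dx (potential part only)
void compute_forces(const std::vector<double>& y, double x, const ChainPars& p,
                    std::vector<double>& fy, double& fx) {
  for (int n = 0; n < p.N; ++n)
    fy[n] = -morse_barrier_dy(y[n], p.D[n], p.a[n], p);
  for (int n = 1; n < p.N; ++n) {
    const double d = y[n] - y[n - 1];
    const double e = p.rho * std::exp(-p.alpha * (y[n] + y[n - 1]));
    const double dcommon = -0.5 * p.k * p.alpha * e * d * d;
    const double delast = p.k * (1.0 + e) * d;
    fy[n]     -= dcommon + delast;
    fy[n - 1] -= dcommon - delast;
  }
  fx = 0.0;
  if (p.Ap != 0.0) {
    int lo, hi;
    well_window(x, p.sigp, p.N, lo, hi);
    const double s2 = p.sigp * p.sigp;
    for (int n = lo; n <= hi; ++n) {
      const double z = (x - n) / p.sigp;
      const double g = std::exp(-0.5 * z * z);
      fy[n] += p.Ap * fsat_dy(y[n], p.ysat) * g;
      // -dVp/dx = -Ap * f * g * (x-n)/sig^2
      fx += -p.Ap * fsat(y[n], p.ysat) * g * (x - n) / s2;
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".energy_cpp")]]
List energy_cpp(NumericVector y, double x, NumericVector D, NumericVector a,
                List pars, bool with_particle) {
  ChainPars p = unpack(D, a, pars);
  if (!with_particle) p.Ap = 0.0;
  std::vector<double> yy(y.begin(), y.end());
  double ons = 0.0, stk = 0.0;
  for (int n = 0; n < p.N; ++n) ons += morse_barrier(yy[n], p.D[n], p.a[n], p);
  for (int n = 1; n < p.N; ++n) stk += stack(yy[n], yy[n - 1], p);
  const double vp = particle_energy(yy, x, p);
  return List::create(_["onsite"] = ons, _["stacking"] = stk,
                      _["particle"] = vp, _["total"] = ons + stk + vp);
}

// [[Rcpp::export(name = ".forces_cpp")]]
List forces_cpp(NumericVector y, double x, NumericVector D, NumericVector a,
                List pars, bool with_particle) {
  ChainPars p = unpack(D, a, pars);
  if (!with_particle) p.Ap = 0.0;
  std::vector<double> yy(y.begin(), y.end()), fy(p.N);
  double fx;
  compute_forces(yy, x, p, fy, fx);
  return List::create(_["fy"] = NumericVector(fy.begin(), fy.end()),
                      _["fx"] = fx);
}

// [[Rcpp::export(name = ".onsite_cpp")]]
NumericVector onsite_cpp(NumericVector y, NumericVector D, NumericVector a,
                         List pars) {
  ChainPars p = unpack(D, a, pars);
  NumericVector out(y.size());
  // broadcast: if a single (D, a) pair is given, apply it to every y
  for (int i = 0; i < y.size(); ++i) {
    const int j = (D.size() == y.size()) ? i : 0;
    out[i] = morse_barrier(y[i], p.D[j], p.a[j], p);
  }
  return out;
}

// One deterministic RK4 substep on (y, v, x, u) under conservative forces,
// followed (in the caller) by an exact Ornstein-Uhlenbeck update of the
// velocities. Clamped sites are frozen at y = 0, v = 0.
struct SimState {
  std::vector<double> y, v;
  double x, u;
};

static void deriv(const SimState& s, const ChainPars& p,
                  const std::vector<int>& clamp, bool with_particle,
                  std::vector<double>& fy, double& fx, SimState& ds) {
  compute_forces(s.y, s.x, p, fy, fx);
  const int N = p.N;
  for (int n = 0; n < N; ++n) {
    if (clamp[n]) { ds.y[n] = 0.0; ds.v[n] = 0.0; }
    else { ds.y[n] = s.v[n]; ds.v[n] = fy[n] / p.mass; }
  }
  if (with_particle) { ds.x = s.u; ds.u = fx / p.mass_p; }
  else { ds.x = 0.0; ds.u = 0.0; }
}

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(NumericVector y0, NumericVector v0, double x0, double u0,
                  NumericVector D, NumericVector a, LogicalVector is_clamp,
                  List pars, double gamma, double kBT, double dt, int n_steps,
                  int stride, bool with_particle, double y_wall,
                  bool record_energy) {
  ChainPars p = unpack(D, a, pars);
  if (!with_particle) p.Ap = 0.0;
  const int N = p.N;
  std::vector<int> clamp(N);
  for (int n = 0; n < N; ++n) clamp[n] = is_clamp[n] ? 1 : 0;

  SimState s;
  s.y.assign(y0.begin(), y0.end());
  s.v.assign(v0.begin(), v0.end());
  s.x = x0; s.u = u0;
  for (int n = 0; n < N; ++n) if (clamp[n]) { s.y[n] = 0.0; s.v[n] = 0.0; }

  const int nframes = n_steps / stride;
  NumericMatrix Y(nframes, N);
  NumericVector X(nframes), KE(nframes), E(nframes);

  // OU coefficients for the friction + noise half of the dynamics
  const double c1 = std::exp(-gamma * dt);
  const double c2 = (gamma > 0.0 && kBT > 0.0)
                        ? std::sqrt(kBT / p.mass * (1.0 - c1 * c1))
                        : 0.0;
  const double c2p = (gamma > 0.0 && kBT > 0.0)
                         ? std::sqrt(kBT / p.mass_p * (1.0 - c1 * c1))
                         : 0.0;

  std::vector<double> fy(N), fxbuf;
  SimState k1, k2, k3, k4, tmp;
  k1 = k2 = k3 = k4 = tmp = s;
  double fx;
  RNGScope rng;

  int frame = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // classical RK4 on the conservative dynamics
    deriv(s, p, clamp, with_particle, fy, fx, k1);
    for (int n = 0; n < N; ++n) {
      tmp.y[n] = s.y[n] + 0.5 * dt * k1.y[n];
      tmp.v[n] = s.v[n] + 0.5 * dt * k1.v[n];
    }
    tmp.x = s.x + 0.5 * dt * k1.x; tmp.u = s.u + 0.5 * dt * k1.u;
    deriv(tmp, p, clamp, with_particle, fy, fx, k2);
    for (int n = 0; n < N; ++n) {
      tmp.y[n] = s.y[n] + 0.5 * dt * k2.y[n];
      tmp.v[n] = s.v[n] + 0.5 * dt * k2.v[n];
    }
    tmp.x = s.x + 0.5 * dt * k2.x; tmp.u = s.u + 0.5 * dt * k2.u;
    deriv(tmp, p, clamp, with_particle, fy, fx, k3);
    for (int n = 0; n < N; ++n) {
      tmp.y[n] = s.y[n] + dt * k3.y[n];
      tmp.v[n] = s.v[n] + dt * k3.v[n];
    }
    tmp.x = s.x + dt * k3.x; tmp.u = s.u + dt * k3.u;
    deriv(tmp, p, clamp, with_particle, fy, fx, k4);
    for (int n = 0; n < N; ++n) {
      if (clamp[n]) continue;
      s.y[n] += dt / 6.0 * (k1.y[n] + 2.0 * k2.y[n] + 2.0 * k3.y[n] + k4.y[n]);
      s.v[n] += dt / 6.0 * (k1.v[n] + 2.0 * k2.v[n] + 2.0 * k3.v[n] + k4.v[n]);
    }
    if (with_particle) {
      s.x += dt / 6.0 * (k1.x + 2.0 * k2.x + 2.0 * k3.x + k4.x);
      s.u += dt / 6.0 * (k1.u + 2.0 * k2.u + 2.0 * k3.u + k4.u);
    }

    // exact OU velocity update (friction + thermal noise)
    if (gamma > 0.0) {
      for (int n = 0; n < N; ++n) {
        if (clamp[n]) continue;
        s.v[n] = c1 * s.v[n] + c2 * norm_rand();
      }
      if (with_particle) s.u = c1 * s.u + c2p * norm_rand();
    }

    // optional reflecting wall (finite simulation box for unbound openings)
    if (R_finite(y_wall)) {
      for (int n = 0; n < N; ++n) {
        if (!clamp[n] && s.y[n] > y_wall) {
          s.y[n] = 2.0 * y_wall - s.y[n];
          s.v[n] = -s.v[n];
        }
      }
    }

    // periodic wrap of the particle
    if (with_particle) s.x = wrap_period(s.x, (double)N);

    if (step % stride == 0) {
      double ke = 0.0;
      for (int n = 0; n < N; ++n) {
        Y(frame, n) = s.y[n];
        if (!clamp[n]) ke += 0.5 * p.mass * s.v[n] * s.v[n];
      }
      if (with_particle) ke += 0.5 * p.mass_p * s.u * s.u;
      X[frame] = s.x;
      KE[frame] = ke;
      if (record_energy)
        E[frame] = ke + chain_energy(s.y, p) + particle_energy(s.y, s.x, p);
      if (!std::isfinite(s.y[N / 2]) || !std::isfinite(ke))
        stop("non-finite state at step %d: time step too large?", step);
      ++frame;
    }
  }

  return List::create(
      _["Y"] = Y, _["x"] = X, _["kinetic"] = KE,
      _["energy"] = record_energy ? (SEXP)E : R_NilValue,
      _["y_final"] = NumericVector(s.y.begin(), s.y.end()),
      _["v_final"] = NumericVector(s.v.begin(), s.v.end()),
      _["x_final"] = s.x, _["u_final"] = s.u);
}

// Euler-Maruyama reference integrator (cross-check oracle for stationary
// statistics; first order, not used by the production pipeline).
// [[Rcpp::export(name = ".simulate_em_cpp")]]
List simulate_em_cpp(NumericVector y0, NumericVector v0, double x0, double u0,
                     NumericVector D, NumericVector a, LogicalVector is_clamp,
                     List pars, double gamma, double kBT, double dt,
                     int n_steps, int stride, bool with_particle,
                     double y_wall) {
  ChainPars p = unpack(D, a, pars);
  if (!with_particle) p.Ap = 0.0;
  const int N = p.N;
  std::vector<int> clamp(N);
  for (int n = 0; n < N; ++n) clamp[n] = is_clamp[n] ? 1 : 0;
  std::vector<double> y(y0.begin(), y0.end()), v(v0.begin(), v0.end()), fy(N);
  double x = x0, u = u0, fx;
  for (int n = 0; n < N; ++n) if (clamp[n]) { y[n] = 0.0; v[n] = 0.0; }
  const int nframes = n_steps / stride;
  NumericMatrix Y(nframes, N);
  NumericVector X(nframes);
  const double sd = std::sqrt(2.0 * gamma * kBT * dt / p.mass);
  const double sdp = std::sqrt(2.0 * gamma * kBT * dt / p.mass_p);
  RNGScope rng;
  int frame = 0;
  for (int step = 1; step <= n_steps; ++step) {
    compute_forces(y, x, p, fy, fx);
    for (int n = 0; n < N; ++n) {
      if (clamp[n]) continue;
      const double vn = v[n];
      v[n] += dt * (fy[n] / p.mass - gamma * vn) + sd * norm_rand();
      y[n] += dt * vn;
      if (R_finite(y_wall) && y[n] > y_wall) {
        y[n] = 2.0 * y_wall - y[n];
        v[n] = -v[n];
      }
    }
    if (with_particle) {
      const double un = u;
      u += dt * (fx / p.mass_p - gamma * un) + sdp * norm_rand();
      x += dt * un;
      x = wrap_period(x, (double)N);
    }
    if (step % stride == 0) {
      for (int n = 0; n < N; ++n) Y(frame, n) = y[n];
      X[frame] = x;
      ++frame;
    }
  }
  return List::create(_["Y"] = Y, _["x"] = X);
}
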