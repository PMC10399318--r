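// Core time integrator for the bead-chain discrete-element model.
//
// Forces: harmonic stretch bonds between adjacent particles, harmonic angle
// (bending) bonds on consecutive triples, one-sided string bonds tying the
// chain ends to fixed anchors, linear viscous damping, and a per-step random
// kick force (Gaussian or Laplace components) emulating grain buffeting.
//
// Two integrators:
//  * verlet        - velocity Verlet with the damping force treated
//                    semi-explicitly (evaluated at the current velocity).
//                    Faithful only when kv*dt/m is small.
//  * split_damping - velocity Verlet for the conservative + kick forces,
//                    with each half velocity update replaced by the exact
//                    solution of m dv/dt = F - kv v over dt/2 (F held).
//                    Reduces to velocity Verlet as kv -> 0 and is stable for
//                    arbitrarily strong damping; its fixed point under a
//                    constant force is exactly F/kv.
//
// Random numbers come from R's RNG so that set.seed() governs runs.
// Draw order within a step: target particle (chain order), then component
// x,y,z; the Laplace branch draws (U1, U2) per component.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sq(double x) { return x * x; }

struct Forces {
  int n;
  std::vector<double> fx, fy, fz;
  Forces(int n_) : n(n_), fx(n_), fy(n_), fz(n_) {}
  void zero() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
  }
};

// conservative bonded forces; returns max |F| component for diagnostics
static double bonded_forces(const std::vector<double>& x,
                            const std::vector<double>& y,
                            const std::vector<double>& z,
                            const IntegerVector& lin_i, const IntegerVector& lin_j,
                            const NumericVector& lin_r0, double kl,
                            const IntegerVector& ang_i, const IntegerVector& ang_j,
                            const IntegerVector& ang_k, double ka,
                            const IntegerVector& str_a, const IntegerVector& str_p,
                            const NumericVector& str_l0, double ks,
                            Forces& F) {
  F.zero();
  // stretch bonds: -kl (R - r0) rhat, acting to restore separation r0
  for (int b = 0; b < lin_i.size(); ++b) {
    int i = lin_i[b], j = lin_j[b];
    double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
    double R = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (R <= 0) continue;  // coincident centers: direction undefined, no force
    double c = kl * (R - lin_r0[b]) / R;  // >0 when stretched
    F.fx[i] += c * dx; F.fy[i] += c * dy; F.fz[i] += c * dz;
    F.fx[j] -= c * dx; F.fy[j] -= c * dy; F.fz[j] -= c * dz;
  }
  // angle bonds: gradient of 0.5*ka*(theta - pi)^2
  for (int b = 0; b < ang_i.size(); ++b) {
    int i = ang_i[b], j = ang_j[b], k = ang_k[b];
    double ax = x[i] - x[j], ay = y[i] - y[j], az = z[i] - z[j];
    double bx = x[k] - x[j], by = y[k] - y[j], bz = z[k] - z[j];
    double la = std::sqrt(ax * ax + ay * ay + az * az);
    double lb = std::sqrt(bx * bx + by * by + bz * bz);
    if (la <= 0 || lb <= 0) stop("angle bond with zero-length arm");
    ax /= la; ay /= la; az /= la;
    bx /= lb; by /= lb; bz /= lb;
    double ct = ax * bx + ay * by + az * bz;
    if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
    double st = std::sqrt(std::max(1.0 - ct * ct, 0.0));
    if (st < 1e-12) continue;  // collinear: straightening torque vanishes
    double theta = std::acos(ct);
    double dU = ka * (theta - M_PI);  // dU/dtheta
    double ci = -dU / (la * st), ck = -dU / (lb * st);
    double fix = ci * (ct * ax - bx), fiy = ci * (ct * ay - by), fiz = ci * (ct * az - bz);
    double fkx = ck * (ct * bx - ax), fky = ck * (ct * by - ay), fkz = ck * (ct * bz - az);
    F.fx[i] += fix; F.fy[i] += fiy; F.fz[i] += fiz;
    F.fx[k] += fkx; F.fy[k] += fky; F.fz[k] += fkz;
    F.fx[j] -= fix + fkx; F.fy[j] -= fiy + fky; F.fz[j] -= fiz + fkz;
  }
  // string bonds: slack below l0, linear restoring above
  for (int b = 0; b < str_a.size(); ++b) {
    int a = str_a[b], p = str_p[b];
    double dx = x[p] - x[a], dy = y[p] - y[a], dz = z[p] - z[a];
    double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (l > str_l0[b]) {
      double c = -ks * (l - str_l0[b]) / l;
      F.fx[p] += c * dx; F.fy[p] += c * dy; F.fz[p] += c * dz;
    }
  }
  double fmax = 0.0;
  for (int i = 0; i < F.n; ++i) {
    fmax = std::max(fmax, std::max(std::fabs(F.fx[i]),
                    std::max(std::fabs(F.fy[i]), std::fabs(F.fz[i]))));
  }
  return fmax;
}

// [[Rcpp::export(name = ".cpp_run_chain")]]
List cpp_run_chain(NumericMatrix x0, NumericVector mass, LogicalVector mobile,
                   LogicalVector kicked,
                   IntegerVector lin_i, IntegerVector lin_j, NumericVector lin_r0,
                   IntegerVector ang_i, IntegerVector ang_j, IntegerVector ang_k,
                   IntegerVector str_a, IntegerVector str_p, NumericVector str_l0,
                   double kl, double ka, double ks, double kv, double kr,
                   int kick_kind,  // 0 none, 1 gaussian, 2 laplace
                   double dt, int n_steps, int equil, int stride,
                   int integrator,  // 0 verlet, 1 split_damping
                   NumericMatrix v0) {
  const int n = x0.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = x0(i, 0); y[i] = x0(i, 1); z[i] = x0(i, 2);
    vx[i] = v0(i, 0); vy[i] = v0(i, 1); vz[i] = v0(i, 2);
  }
  Forces F(n);
  std::vector<double> kx(n, 0.0), ky(n, 0.0), kz(n, 0.0);
  // split-damping half-step coefficients per particle
  std::vector<double> dec(n), em(n);
  for (int i = 0; i < n; ++i) {
    double gh = kv * dt / (2.0 * mass[i]);
    dec[i] = std::exp(-gh);
    em[i] = -std::expm1(-gh);
  }
  const int n_frames = (n_steps - equil) / stride;
  NumericVector times(n_frames);
  // frame-major storage [frame, particle, axis]
  NumericVector P(n_frames * n * 3), V(n_frames * n * 3);
  int frame = 0;

  for (int step = 0; step < n_steps; ++step) {
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
    // one kick per step, held constant across both half updates
    if (kick_kind > 0) {
      for (int i = 0; i < n; ++i) {
        if (!kicked[i]) { kx[i] = ky[i] = kz[i] = 0.0; continue; }
        double p[3];
        for (int c = 0; c < 3; ++c) {
          if (kick_kind == 1) {
            p[c] = norm_rand();
          } else {
            double u1 = unif_rand(), u2 = unif_rand();
            p[c] = (u2 <= 0.5) ? -std::log(u1) : std::log(u1);
          }
        }
        kx[i] = kr * p[0]; ky[i] = kr * p[1]; kz[i] = kr * p[2];
      }
    }

    double fmax = bonded_forces(x, y, z, lin_i, lin_j, lin_r0, kl,
                                ang_i, ang_j, ang_k, ka,
                                str_a, str_p, str_l0, ks, F);
    if (integrator == 1) {
      // half A: exact damping with held force
      for (int i = 0; i < n; ++i) {
        if (!mobile[i]) continue;
        double fx = F.fx[i] + kx[i], fy = F.fy[i] + ky[i], fz = F.fz[i] + kz[i];
        if (kv > 0) {
          vx[i] = vx[i] * dec[i] + fx / kv * em[i];
          vy[i] = vy[i] * dec[i] + fy / kv * em[i];
          vz[i] = vz[i] * dec[i] + fz / kv * em[i];
        } else {
          double h = dt / (2.0 * mass[i]);
          vx[i] += fx * h; vy[i] += fy * h; vz[i] += fz * h;
        }
      }
    } else {
      // semi-explicit velocity Verlet: damping evaluated at current v
      for (int i = 0; i < n; ++i) {
        if (!mobile[i]) continue;
        double h = dt / (2.0 * mass[i]);
        vx[i] += (F.fx[i] + kx[i] - kv * vx[i]) * h;
        vy[i] += (F.fy[i] + ky[i] - kv * vy[i]) * h;
        vz[i] += (F.fz[i] + kz[i] - kv * vz[i]) * h;
      }
    }
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      x[i] += vx[i] * dt; y[i] += vy[i] * dt; z[i] += vz[i] * dt;
    }
    fmax = bonded_forces(x, y, z, lin_i, lin_j, lin_r0, kl,
                         ang_i, ang_j, ang_k, ka,
                         str_a, str_p, str_l0, ks, F);
    if (integrator == 1) {
      for (int i = 0; i < n; ++i) {
        if (!mobile[i]) continue;
        double fx = F.fx[i] + kx[i], fy = F.fy[i] + ky[i], fz = F.fz[i] + kz[i];
        if (kv > 0) {
          vx[i] = vx[i] * dec[i] + fx / kv * em[i];
          vy[i] = vy[i] * dec[i] + fy / kv * em[i];
          vz[i] = vz[i] * dec[i] + fz / kv * em[i];
        } else {
          double h = dt / (2.0 * mass[i]);
          vx[i] += fx * h; vy[i] += fy * h; vz[i] += fz * h;
        }
      }
    } else {
      for (int i = 0; i < n; ++i) {
        if (!mobile[i]) continue;
        double h = dt / (2.0 * mass[i]);
        vx[i] += (F.fx[i] + kx[i] - kv * vx[i]) * h;
        vy[i] += (F.fy[i] + ky[i] - kv * vy[i]) * h;
        vz[i] += (F.fz[i] + kz[i] - kv * vz[i]) * h;
      }
    }

    // blow-up check with diagnostics
    bool bad = false;
    double vmax = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]) ||
          !std::isfinite(vx[i]) || !std::isfinite(vy[i]) || !std::isfinite(vz[i]))
        bad = true;
      vmax = std::max(vmax, std::max(std::fabs(vx[i]),
                      std::max(std::fabs(vy[i]), std::fabs(vz[i]))));
    }
    if (bad) {
      stop("integration blow-up at step %d (max |force| %.3g N, max |velocity| %.3g m/s)",
           step + 1, fmax, vmax);
    }

    if (step + 1 > equil && (step + 1 - equil) % stride == 0 && frame < n_frames) {
      times[frame] = (step + 1) * dt;
      for (int i = 0; i < n; ++i) {
        P[frame + n_frames * i] = x[i];
        P[frame + n_frames * (i + n)] = y[i];
        P[frame + n_frames * (i + 2 * n)] = z[i];
        V[frame + n_frames * i] = vx[i];
        V[frame + n_frames * (i + n)] = vy[i];
        V[frame + n_frames * (i + 2 * n)] = vz[i];
      }
      ++frame;
    }
  }

  P.attr("dim") = IntegerVector::create(n_frames, n, 3);
  V.attr("dim") = IntegerVector::create(n_frames, n, 3);
  NumericMatrix xout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i) {
    xout(i, 0) = x[i]; xout(i, 1) = y[i]; xout(i, 2) = z[i];
    vout(i, 0) = vx[i]; vout(i, 1) = vy[i]; vout(i, 2) = vz[i];
  }
  return List::create(_["times"] = times, _["positions"] = P, _["velocities"] = V,
                      _["n_frames"] = frame, _["x_final"] = xout, _["v_final"] = vout);
}
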