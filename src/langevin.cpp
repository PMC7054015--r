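// Langevin dynamics for a restrained bead-and-spring chromatin model.
//
// Reduced units throughout: length in bead diameters (sigma = 30 nm),
// energy in kT (epsilon = 1), mass m = 1, time in tau_LJ = sigma*sqrt(m/eps).
// Forces: WCA excluded volume, FENE bonds along each chain, Kratky-Porod
// bending, one-sided indent restraints F = K (r - R)^2 toward compliance
// (nuclear envelope, SPB sphere for centromeres, nucleolar sphere kept
// inside for rDNA / outside for the rest), and a truncated-shifted 12-6
// wall attraction toward the NE for terminal (telomere) beads.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
using namespace Rcpp;

namespace {

struct CellList {
  double cell;                 // cell edge (>= pair cutoff)
  double x0, y0, z0;           // box origin
  int nx, ny, nz;
  std::vector<int> head, nxt;

  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, int n) {
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0],
           zmin = z[0], zmax = z[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    x0 = xmin - 1e-9; y0 = ymin - 1e-9; z0 = zmin - 1e-9;
    nx = std::max(1, (int)((xmax - x0) / cell) + 1);
    ny = std::max(1, (int)((ymax - y0) / cell) + 1);
    nz = std::max(1, (int)((zmax - z0) / cell) + 1);
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = idx(x[i], y[i], z[i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  inline int idx(double xx, double yy, double zz) const {
    int ix = (int)((xx - x0) / cell), iy = (int)((yy - y0) / cell),
        iz = (int)((zz - z0) / cell);
    ix = std::min(std::max(ix, 0), nx - 1);
    iy = std::min(std::max(iy, 0), ny - 1);
    iz = std::min(std::max(iz, 0), nz - 1);
    return (ix * ny + iy) * nz + iz;
  }
};

inline void wca_force(double dx, double dy, double dz, double r2,
                      double& fx, double& fy, double& fz) {
  // WCA with sigma = eps = 1, cutoff^2 = 2^(1/3)
  double inv2 = 1.0 / r2;
  double s6 = inv2 * inv2 * inv2;
  double fr = 24.0 * (2.0 * s6 * s6 - s6) * inv2;  // (1/r dV/dr) with sign
  fx += fr * dx; fy += fr * dy; fz += fr * dz;
}

}  // namespace

// [[Rcpp::export(name = ".langevin_run_cpp")]]
List langevin_run_cpp(NumericMatrix pos0, IntegerVector chain_id,
                      LogicalVector is_cen, LogicalVector is_rdna,
                      LogicalVector is_term, NumericVector kappa,
                      double fene_k, double fene_r0,
                      double wall_eps, double wall_cut,
                      double r_nuc, NumericVector c_spb, double r_spb,
                      NumericVector c_nucl, double r_nucl,
                      double indent_k, double f_cap,
                      bool restraints_on,
                      double dt, double gamma, double temp,
                      int n_steps, int sample_every, int seed) {
  const int n = pos0.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n),
      fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
  }

  std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double vsd = std::sqrt(temp);
  for (int i = 0; i < n; ++i) {
    vx[i] = vsd * gauss(rng); vy[i] = vsd * gauss(rng); vz[i] = vsd * gauss(rng);
  }

  const double rc2 = std::pow(2.0, 1.0 / 3.0);  // WCA cutoff^2
  const double r02 = fene_r0 * fene_r0;
  const double wall_cut_d = wall_cut;
  // shift so the wall potential is continuous at the cutoff
  double wc6 = std::pow(wall_cut_d, -6.0);
  const double wall_shift = 4.0 * wall_eps * (wc6 * wc6 - wc6);
  (void)wall_shift;  // forces only; shift documents the truncation

  // Verlet neighbour list with skin, rebuilt from a cell list whenever any
  // particle has moved more than half the skin since the last build;
  // forces are identical to the all-pairs computation.
  const double skin = 0.4;
  const double rlist = std::sqrt(rc2) + skin;
  const double rlist2 = rlist * rlist;
  CellList cl; cl.cell = std::max(rlist, 1.2);
  std::vector<int> pi, pj;        // neighbour pairs
  std::vector<double> bx(n), by(n), bz(n);  // positions at last build

  auto build_nlist = [&](void) {
    cl.build(x, y, z, n);
    pi.clear(); pj.clear();
    for (int i = 0; i < n; ++i) {
      int ix = (int)((x[i] - cl.x0) / cl.cell), iy = (int)((y[i] - cl.y0) / cl.cell),
          iz = (int)((z[i] - cl.z0) / cl.cell);
      for (int ax = std::max(ix - 1, 0); ax <= std::min(ix + 1, cl.nx - 1); ++ax)
        for (int ay = std::max(iy - 1, 0); ay <= std::min(iy + 1, cl.ny - 1); ++ay)
          for (int az = std::max(iz - 1, 0); az <= std::min(iz + 1, cl.nz - 1); ++az) {
            int j = cl.head[((size_t)ax * cl.ny + ay) * cl.nz + az];
            while (j >= 0) {
              if (j > i) {
                double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
                if (dx * dx + dy * dy + dz * dz < rlist2) {
                  pi.push_back(i); pj.push_back(j);
                }
              }
              j = cl.nxt[j];
            }
          }
    }
    for (int i = 0; i < n; ++i) { bx[i] = x[i]; by[i] = y[i]; bz[i] = z[i]; }
  };

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * temp);

  auto forces = [&](void) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);

    // pair (WCA) via the Verlet list, refreshed on the displacement trigger
    double max_d2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = x[i] - bx[i], dy = y[i] - by[i], dz = z[i] - bz[i];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > max_d2) max_d2 = d2;
    }
    if (max_d2 > 0.25 * skin * skin) build_nlist();
    for (size_t p = 0; p < pi.size(); ++p) {
      int i = pi[p], j = pj[p];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < rc2 && r2 > 1e-12) {
        double gx = 0, gy = 0, gz = 0;
        wca_force(dx, dy, dz, r2, gx, gy, gz);
        fx[i] += gx; fy[i] += gy; fz[i] += gz;
        fx[j] -= gx; fy[j] -= gy; fz[j] -= gz;
      }
    }

    // FENE bonds between consecutive beads of the same chain
    for (int i = 0; i + 1 < n; ++i) {
      if (chain_id[i] != chain_id[i + 1]) continue;
      double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i], dz = z[i + 1] - z[i];
      double r2 = dx * dx + dy * dy + dz * dz;
      double denom = 1.0 - r2 / r02;
      if (denom < 0.05) denom = 0.05;  // emergency clamp, never hit in a stable run
      double fr = -fene_k / denom;     // force per unit separation, attractive
      fx[i] -= fr * dx; fy[i] -= fr * dy; fz[i] -= fr * dz;
      fx[i + 1] += fr * dx; fy[i + 1] += fr * dy; fz[i + 1] += fr * dz;
    }

    // Kratky-Porod bending: E = kappa_j (1 - cos theta_j) at interior bead j
    for (int j = 1; j + 1 < n; ++j) {
      double k = kappa[j];
      if (k <= 0.0) continue;
      if (chain_id[j - 1] != chain_id[j] || chain_id[j] != chain_id[j + 1]) continue;
      double ax = x[j] - x[j - 1], ay = y[j] - y[j - 1], az = z[j] - z[j - 1];
      double bx = x[j + 1] - x[j], by = y[j + 1] - y[j], bz = z[j + 1] - z[j];
      double la2 = ax * ax + ay * ay + az * az;
      double lb2 = bx * bx + by * by + bz * bz;
      double la = std::sqrt(la2), lb = std::sqrt(lb2);
      if (la < 1e-9 || lb < 1e-9) continue;
      double dot = ax * bx + ay * by + az * bz;
      double cosq = dot / (la * lb);
      // dE/d(cos) = -kappa; F = kappa * d(cos)/d(positions)
      double inv = 1.0 / (la * lb);
      // gradient of cos wrt a and b
      double gax = bx * inv - cosq * ax / la2;
      double gay = by * inv - cosq * ay / la2;
      double gaz = bz * inv - cosq * az / la2;
      double gbx = ax * inv - cosq * bx / lb2;
      double gby = ay * inv - cosq * by / lb2;
      double gbz = az * inv - cosq * bz / lb2;
      // a = r_j - r_{j-1}; b = r_{j+1} - r_j
      fx[j - 1] -= k * gax; fy[j - 1] -= k * gay; fz[j - 1] -= k * gaz;
      fx[j]     += k * (gax - gbx); fy[j] += k * (gay - gby); fz[j] += k * (gaz - gbz);
      fx[j + 1] += k * gbx; fy[j + 1] += k * gby; fz[j + 1] += k * gbz;
    }

    if (!restraints_on) return;

    for (int i = 0; i < n; ++i) {
      double rfx = 0, rfy = 0, rfz = 0;
      double r = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);

      // nuclear envelope: keep inside radius r_nuc
      if (r > r_nuc) {
        double mag = indent_k * (r - r_nuc) * (r - r_nuc);
        rfx -= mag * x[i] / r; rfy -= mag * y[i] / r; rfz -= mag * z[i] / r;
      }

      // SPB sphere: centromere beads kept inside
      if (is_cen[i]) {
        double dx = x[i] - c_spb[0], dy = y[i] - c_spb[1], dz = z[i] - c_spb[2];
        double rs = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (rs > r_spb) {
          double mag = indent_k * (rs - r_spb) * (rs - r_spb);
          rfx -= mag * dx / rs; rfy -= mag * dy / rs; rfz -= mag * dz / rs;
        }
      }

      // nucleolar sphere: rDNA kept inside, everything else kept out
      {
        double dx = x[i] - c_nucl[0], dy = y[i] - c_nucl[1], dz = z[i] - c_nucl[2];
        double rs = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (is_rdna[i]) {
          if (rs > r_nucl) {
            double mag = indent_k * (rs - r_nucl) * (rs - r_nucl);
            rfx -= mag * dx / rs; rfy -= mag * dy / rs; rfz -= mag * dz / rs;
          }
        } else if (rs < r_nucl) {
          double mag = indent_k * (r_nucl - rs) * (r_nucl - rs);
          if (rs < 1e-9) { rfx += mag; }  // degenerate centre: push along +x
          else { rfx += mag * dx / rs; rfy += mag * dy / rs; rfz += mag * dz / rs; }
        }
      }

      // telomere-wall attraction for terminal beads: 12-6 well in the
      // distance d from the NE, truncated at wall_cut
      if (is_term[i] && wall_eps > 0.0) {
        double d = r_nuc - r;
        if (d < wall_cut_d) {
          if (d < 0.5) d = 0.5;  // guard: NE indent handles deeper violations
          double id6 = std::pow(d, -6.0);
          double dVdd = 4.0 * wall_eps * (-12.0 * id6 * id6 + 6.0 * id6) / d;
          // F = +dV/dd * r_hat (attraction outward when dVdd > 0)
          if (r > 1e-9) {
            rfx += dVdd * x[i] / r; rfy += dVdd * y[i] / r; rfz += dVdd * z[i] / r;
          }
        }
      }

      // cap the restraint force so large initial violations relax smoothly
      double fm2 = rfx * rfx + rfy * rfy + rfz * rfz;
      if (fm2 > f_cap * f_cap) {
        double sc = f_cap / std::sqrt(fm2);
        rfx *= sc; rfy *= sc; rfz *= sc;
      }
      fx[i] += rfx; fy[i] += rfy; fz[i] += rfz;
    }
  };

  // Global guard against pathological force spikes (deep accidental
  // overlaps); far above the working force scale, so it never shapes the
  // physics of a healthy trajectory.
  const double f_max = 1e3;
  auto cap_forces = [&](void) {
    for (int i = 0; i < n; ++i) {
      double fm2 = fx[i] * fx[i] + fy[i] * fy[i] + fz[i] * fz[i];
      if (fm2 > f_max * f_max) {
        double sc = f_max / std::sqrt(fm2);
        fx[i] *= sc; fy[i] *= sc; fz[i] *= sc;
      }
    }
  };

  build_nlist();
  forces();
  cap_forces();

  int n_samples = (sample_every > 0) ? n_steps / sample_every : 0;
  List samples(n_samples);
  int si = 0;

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {  // B
      vx[i] += 0.5 * dt * fx[i]; vy[i] += 0.5 * dt * fy[i]; vz[i] += 0.5 * dt * fz[i];
    }
    for (int i = 0; i < n; ++i) {  // A
      x[i] += 0.5 * dt * vx[i]; y[i] += 0.5 * dt * vy[i]; z[i] += 0.5 * dt * vz[i];
    }
    for (int i = 0; i < n; ++i) {  // O
      vx[i] = c1 * vx[i] + c2 * gauss(rng);
      vy[i] = c1 * vy[i] + c2 * gauss(rng);
      vz[i] = c1 * vz[i] + c2 * gauss(rng);
    }
    for (int i = 0; i < n; ++i) {  // A
      x[i] += 0.5 * dt * vx[i]; y[i] += 0.5 * dt * vy[i]; z[i] += 0.5 * dt * vz[i];
    }
    forces();
    cap_forces();
    for (int i = 0; i < n; ++i) {  // B
      vx[i] += 0.5 * dt * fx[i]; vy[i] += 0.5 * dt * fy[i]; vz[i] += 0.5 * dt * fz[i];
    }

    if (step % 200 == 0 || (sample_every > 0 && step % sample_every == 0)) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i])) {
          stop("non-finite coordinate at step %d (seed %d)", step, seed);
        }
      }
    }
    if (sample_every > 0 && step % sample_every == 0 && si < n_samples) {
      NumericMatrix s(n, 3);
      for (int i = 0; i < n; ++i) { s(i, 0) = x[i]; s(i, 1) = y[i]; s(i, 2) = z[i]; }
      samples[si++] = s;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix fin(n, 3);
  for (int i = 0; i < n; ++i) { fin(i, 0) = x[i]; fin(i, 1) = y[i]; fin(i, 2) = z[i]; }
  return List::create(_["samples"] = samples, _["final"] = fin);
}
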