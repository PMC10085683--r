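// Coarse-grained chromatin dynamics: fixed-step Langevin (BAOAB) integration
// of a beads-on-a-string polymer with harmonic bonds, harmonic angles, a
// truncated polynomial repulsion, harmonic tethers on loop-base beads and a
// harmonic cylindrical confinement. Internal units: kBT = 1, nm, unit mass.
// The integrator uses its own counter-free xoshiro256++ RNG seeded from R so
// trajectories are exactly reproducible per seed.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// --- RNG: splitmix64-seeded xoshiro256++, Box-Muller normals -------------
struct Rng {
  uint64_t s[4];
  double spare;
  bool has_spare;

  explicit Rng(uint64_t seed) : spare(0), has_spare(false) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// --- cell list on a uniform grid -----------------------------------------
struct CellList {
  double cell, ox, oy, oz;
  int nx, ny, nz;
  std::vector<int> head, next;

  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, double cutoff) {
    const int n = (int)x.size();
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0],
           zmin = z[0], zmax = z[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    cell = cutoff;
    ox = xmin; oy = ymin; oz = zmin;
    nx = std::max(1, (int)((xmax - xmin) / cell) + 1);
    ny = std::max(1, (int)((ymax - ymin) / cell) + 1);
    nz = std::max(1, (int)((zmax - zmin) / cell) + 1);
    head.assign((size_t)nx * ny * nz, -1);
    next.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = cellOf(x[i], y[i], z[i]);
      next[i] = head[c];
      head[c] = i;
    }
  }
  inline int clampc(int v, int hi) const {
    return std::min(hi - 1, std::max(0, v));
  }
  inline int cellOf(double px, double py, double pz) const {
    int cx = clampc((int)((px - ox) / cell), nx);
    int cy = clampc((int)((py - oy) / cell), ny);
    int cz = clampc((int)((pz - oz) / cell), nz);
    return (cz * ny + cy) * nx + cx;
  }
};

// pairs within `cutoff`, i < j
inline void neighbour_pairs(const std::vector<double>& x,
                            const std::vector<double>& y,
                            const std::vector<double>& z, double cutoff,
                            std::vector<int>& pi, std::vector<int>& pj) {
  pi.clear(); pj.clear();
  const int n = (int)x.size();
  if (n == 0) return;
  CellList cl;
  cl.build(x, y, z, cutoff);
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    int cx = cl.clampc((int)((x[i] - cl.ox) / cl.cell), cl.nx);
    int cy = cl.clampc((int)((y[i] - cl.oy) / cl.cell), cl.ny);
    int cz = cl.clampc((int)((z[i] - cl.oz) / cl.cell), cl.nz);
    for (int dz = -1; dz <= 1; ++dz) {
      int zc = cz + dz; if (zc < 0 || zc >= cl.nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int yc = cy + dy; if (yc < 0 || yc >= cl.ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int xc = cx + dx; if (xc < 0 || xc >= cl.nx) continue;
          int j = cl.head[((size_t)zc * cl.ny + yc) * cl.nx + xc];
          for (; j >= 0; j = cl.next[j]) {
            if (j <= i) continue;
            double ddx = x[j] - x[i], ddy = y[j] - y[i], ddz = z[j] - z[i];
            if (ddx * ddx + ddy * ddy + ddz * ddz <= c2) {
              pi.push_back(i);
              pj.push_back(j);
            }
          }
        }
      }
    }
  }
}

struct Forces {
  int n;
  std::vector<int> bi, bj;
  std::vector<double> br0, bk;
  std::vector<int> ti;
  std::vector<double> tx, ty, tz;
  double tk;
  double angle_k;
  double rep_e0, rep_rc;
  double cyl_r, cyl_k;
  // Verlet pair list with skin, rebuilt periodically
  std::vector<int> vi, vj;

  void rebuild_pairs(const std::vector<double>& x, const std::vector<double>& y,
                     const std::vector<double>& z, double skin) {
    if (rep_e0 > 0) neighbour_pairs(x, y, z, rep_rc + skin, vi, vj);
  }

  void compute(const std::vector<double>& x, const std::vector<double>& y,
               const std::vector<double>& z, std::vector<double>& fx,
               std::vector<double>& fy, std::vector<double>& fz) const {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);

    for (size_t b = 0; b < bi.size(); ++b) {
      const int i = bi[b], j = bj[b];
      double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      double f = bk[b] * (r - br0[b]) / r;
      fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
      fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
    }

    if (angle_k > 0) {
      for (int i = 1; i < n - 1; ++i) {
        double ax = x[i - 1] - x[i], ay = y[i - 1] - y[i], az = z[i - 1] - z[i];
        double bx = x[i + 1] - x[i], by = y[i + 1] - y[i], bz = z[i + 1] - z[i];
        double ra = std::sqrt(ax * ax + ay * ay + az * az);
        double rb = std::sqrt(bx * bx + by * by + bz * bz);
        if (ra < 1e-12 || rb < 1e-12) continue;
        double cosv = (ax * bx + ay * by + az * bz) / (ra * rb);
        cosv = std::max(-1.0, std::min(1.0, cosv));
        // cosine-harmonic bending U = k (1 + cos theta): same curvature as
        // the harmonic angle at the straight minimum, bounded force when the
        // chain folds back on itself
        double coef = -angle_k;
        double fax = coef * (bx / (ra * rb) - cosv * ax / (ra * ra));
        double fay = coef * (by / (ra * rb) - cosv * ay / (ra * ra));
        double faz = coef * (bz / (ra * rb) - cosv * az / (ra * ra));
        double fbx = coef * (ax / (ra * rb) - cosv * bx / (rb * rb));
        double fby = coef * (ay / (ra * rb) - cosv * by / (rb * rb));
        double fbz = coef * (az / (ra * rb) - cosv * bz / (rb * rb));
        fx[i - 1] += fax; fy[i - 1] += fay; fz[i - 1] += faz;
        fx[i + 1] += fbx; fy[i + 1] += fby; fz[i + 1] += fbz;
        fx[i] -= fax + fbx; fy[i] -= fay + fby; fz[i] -= faz + fbz;
      }
    }

    // truncated repulsion U(r) = e0 * (1 - (r/rc)^2)^3: finite barrier at
    // r = 0 so fibres may cross (topoisomerase-permissive)
    if (rep_e0 > 0) {
      const double rc2 = rep_rc * rep_rc;
      const double pref = 6.0 * rep_e0 / rc2;
      for (size_t p = 0; p < vi.size(); ++p) {
        const int i = vi[p], j = vj[p];
        double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rc2 || r2 < 1e-14) continue;
        double u = 1.0 - r2 / rc2;
        double f = pref * u * u;
        fx[i] -= f * dx; fy[i] -= f * dy; fz[i] -= f * dz;
        fx[j] += f * dx; fy[j] += f * dy; fz[j] += f * dz;
      }
    }

    for (size_t t = 0; t < ti.size(); ++t) {
      const int i = ti[t];
      fx[i] -= tk * (x[i] - tx[t]);
      fy[i] -= tk * (y[i] - ty[t]);
      fz[i] -= tk * (z[i] - tz[t]);
    }

    if (cyl_r > 0) {
      for (int i = 0; i < n; ++i) {
        double rho = std::sqrt(x[i] * x[i] + y[i] * y[i]);
        if (rho > cyl_r && rho > 1e-12) {
          double f = cyl_k * (rho - cyl_r) / rho;
          fx[i] -= f * x[i];
          fy[i] -= f * y[i];
        }
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".langevin_block")]]
List langevin_block(NumericMatrix coords, NumericMatrix vel,
                    IntegerMatrix bonds, NumericVector bond_r0,
                    NumericVector bond_k, double angle_k,
                    IntegerVector tether_idx, NumericMatrix tether_xyz,
                    double tether_k, double rep_e0, double rep_rc,
                    double cyl_r, double cyl_k, double dt, double gamma,
                    int nsteps, double seed) {
  const int n = coords.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }

  Forces F;
  F.n = n;
  F.angle_k = angle_k;
  F.rep_e0 = rep_e0; F.rep_rc = rep_rc;
  F.cyl_r = cyl_r; F.cyl_k = cyl_k;
  F.tk = tether_k;
  for (int b = 0; b < bonds.nrow(); ++b) {
    F.bi.push_back(bonds(b, 0) - 1);
    F.bj.push_back(bonds(b, 1) - 1);
    F.br0.push_back(bond_r0[b]);
    F.bk.push_back(bond_k[b]);
  }
  for (int t = 0; t < tether_idx.size(); ++t) {
    F.ti.push_back(tether_idx[t] - 1);
    F.tx.push_back(tether_xyz(t, 0));
    F.ty.push_back(tether_xyz(t, 1));
    F.tz.push_back(tether_xyz(t, 2));
  }

  Rng rng((uint64_t)seed);
  // pair-list skin sized for ~thermal drift over the rebuild interval
  const int rebuild_every = 10;
  const double skin = 4.0;
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);

  F.rebuild_pairs(x, y, z, skin);
  F.compute(x, y, z, fx, fy, fz);
  bool finite = true;
  for (int step = 0; step < nsteps && finite; ++step) {
    for (int i = 0; i < n; ++i) {  // B half kick + A half drift
      vx[i] += 0.5 * dt * fx[i];
      vy[i] += 0.5 * dt * fy[i];
      vz[i] += 0.5 * dt * fz[i];
      x[i] += 0.5 * dt * vx[i];
      y[i] += 0.5 * dt * vy[i];
      z[i] += 0.5 * dt * vz[i];
    }
    for (int i = 0; i < n; ++i) {  // O + A half drift
      vx[i] = c1 * vx[i] + c2 * rng.norm();
      vy[i] = c1 * vy[i] + c2 * rng.norm();
      vz[i] = c1 * vz[i] + c2 * rng.norm();
      x[i] += 0.5 * dt * vx[i];
      y[i] += 0.5 * dt * vy[i];
      z[i] += 0.5 * dt * vz[i];
    }
    if ((step + 1) % rebuild_every == 0) F.rebuild_pairs(x, y, z, skin);
    F.compute(x, y, z, fx, fy, fz);
    for (int i = 0; i < n; ++i) {  // B half kick
      vx[i] += 0.5 * dt * fx[i];
      vy[i] += 0.5 * dt * fy[i];
      vz[i] += 0.5 * dt * fz[i];
    }
    if ((step & 63) == 0) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i])) {
          finite = false;
          break;
        }
      }
    }
  }

  for (int i = 0; i < n && finite; ++i) {
    if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i])) {
      finite = false;
    }
  }

  NumericMatrix out(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i];
    vout(i, 0) = vx[i]; vout(i, 1) = vy[i]; vout(i, 2) = vz[i];
  }
  return List::create(_["coords"] = out, _["vel"] = vout,
                      _["finite"] = finite);
}

// [[Rcpp::export(name = ".contacts_within")]]
IntegerMatrix contacts_within(NumericMatrix coords, double radius) {
  const int n = coords.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
  }
  std::vector<int> pi, pj;
  neighbour_pairs(x, y, z, radius, pi, pj);
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    out(k, 0) = pi[k] + 1;
    out(k, 1) = pj[k] + 1;
  }
  return out;
}
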