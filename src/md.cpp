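// Molecular-dynamics kernels for the two-temperature bead-spring melt:
// WCA + FENE pair interactions, linked-cell neighbor search, a
// Gronbech-Jensen/Farago Langevin integrator with per-particle target
// temperatures, a capped-soft-potential push-off used during melt
// preparation, the like-species contact order parameter, and the
// plane-crossing virial profile. All quantities in reduced LJ units
// (sigma, epsilon, tau, m = kB = 1).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Pair_ff {
  double eps, sigma, rc, rc2, K, rmax, rmax2;
};

// WCA (shifted, truncated LJ): U = 4 eps [ (s/r)^12 - (s/r)^6 ] + eps, r < rc
// returns energy and scalar force magnitude F = -dU/dr (repulsive > 0)
inline void wca_pair(double r2, const Pair_ff &ff, double &u, double &fmag_over_r) {
  if (r2 >= ff.rc2) { u = 0.0; fmag_over_r = 0.0; return; }
  double s2 = ff.sigma * ff.sigma / r2;
  double s6 = s2 * s2 * s2;
  double s12 = s6 * s6;
  u = 4.0 * ff.eps * (s12 - s6) + ff.eps;
  // F/r = 24 eps (2 s12 - s6) / r^2
  fmag_over_r = 24.0 * ff.eps * (2.0 * s12 - s6) / r2;
}

// FENE: U = -K rmax^2/2 log(1-(r/rmax)^2); attractive force K r/(1-(r/rmax)^2)
inline void fene_pair(double r2, const Pair_ff &ff, double &u, double &fmag_over_r) {
  double x = r2 / ff.rmax2;
  u = -0.5 * ff.K * ff.rmax2 * std::log(1.0 - x);
  // force on the pair is attractive: F/r = -K/(1-x)
  fmag_over_r = -ff.K / (1.0 - x);
}

inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

inline double min_image_inv(double d, double L, double invL) {
  return d - L * std::nearbyint(d * invL);
}

// Linked-cell list over the periodic box. Falls back to all-pairs when the
// box is too small for 3 cells along some direction.
struct CellList {
  int nx, ny, nz, ncell;
  bool brute;
  std::vector<int> head, nxt;

  void build(const std::vector<double> &x, const std::vector<double> &y,
             const std::vector<double> &z, const double L[3], double rcut) {
    int np = (int)x.size();
    nx = std::max(1, (int)std::floor(L[0] / rcut));
    ny = std::max(1, (int)std::floor(L[1] / rcut));
    nz = std::max(1, (int)std::floor(L[2] / rcut));
    brute = (nx < 3 || ny < 3 || nz < 3);
    if (brute) return;
    ncell = nx * ny * nz;
    head.assign(ncell, -1);
    nxt.assign(np, -1);
    for (int i = 0; i < np; ++i) {
      int cx = (int)(x[i] / L[0] * nx); if (cx >= nx) cx = nx - 1; if (cx < 0) cx = 0;
      int cy = (int)(y[i] / L[1] * ny); if (cy >= ny) cy = ny - 1; if (cy < 0) cy = 0;
      int cz = (int)(z[i] / L[2] * nz); if (cz >= nz) cz = nz - 1; if (cz < 0) cz = 0;
      int c = (cz * ny + cy) * nx + cx;
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

// Visit all unique pairs within rcut; calls f(i, j, dx, dy, dz, r2) with the
// minimum-image separation r_i - r_j.
template <typename F>
void for_pairs(const std::vector<double> &x, const std::vector<double> &y,
               const std::vector<double> &z, const double L[3], double rcut,
               F &&f) {
  int np = (int)x.size();
  double rc2 = rcut * rcut;
  const double iL0 = 1.0 / L[0], iL1 = 1.0 / L[1], iL2 = 1.0 / L[2];
  CellList cl;
  cl.build(x, y, z, L, rcut);
  if (cl.brute) {
    for (int i = 0; i < np; ++i)
      for (int j = i + 1; j < np; ++j) {
        double dx = min_image_inv(x[i] - x[j], L[0], iL0);
        double dy = min_image_inv(y[i] - y[j], L[1], iL1);
        double dz = min_image_inv(z[i] - z[j], L[2], iL2);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rc2) f(i, j, dx, dy, dz, r2);
      }
    return;
  }
  for (int cz = 0; cz < cl.nz; ++cz)
    for (int cy = 0; cy < cl.ny; ++cy)
      for (int cx = 0; cx < cl.nx; ++cx) {
        int c = (cz * cl.ny + cy) * cl.nx + cx;
        // half the neighbor stencil (13 cells) + the cell itself
        static const int off[14][3] = {
          {0,0,0}, {1,0,0}, {-1,1,0}, {0,1,0}, {1,1,0},
          {-1,-1,1}, {0,-1,1}, {1,-1,1}, {-1,0,1}, {0,0,1},
          {1,0,1}, {-1,1,1}, {0,1,1}, {1,1,1}};
        for (int k = 0; k < 14; ++k) {
          int ox = (cx + off[k][0] + cl.nx) % cl.nx;
          int oy = (cy + off[k][1] + cl.ny) % cl.ny;
          int oz = (cz + off[k][2] + cl.nz) % cl.nz;
          int c2 = (oz * cl.ny + oy) * cl.nx + ox;
          for (int i = cl.head[c]; i >= 0; i = cl.nxt[i]) {
            int jstart = (k == 0) ? cl.nxt[i] : cl.head[c2];
            const double xi = x[i], yi = y[i], zi = z[i];
            for (int j = jstart; j >= 0; j = cl.nxt[j]) {
              double dx = min_image_inv(xi - x[j], L[0], iL0);
              double dy = min_image_inv(yi - y[j], L[1], iL1);
              double dz = min_image_inv(zi - z[j], L[2], iL2);
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 < rc2) f(i, j, dx, dy, dz, r2);
            }
          }
        }
      }
}

void get_box(const NumericVector &box, double L[3]) {
  if (box.size() != 3) stop("box must have 3 lengths");
  for (int k = 0; k < 3; ++k) {
    L[k] = box[k];
    if (!(L[k] > 0)) stop("box lengths must be positive");
  }
}

Pair_ff get_ff(double eps, double sigma, double rc, double K, double rmax) {
  Pair_ff ff;
  ff.eps = eps; ff.sigma = sigma; ff.rc = rc; ff.rc2 = rc * rc;
  ff.K = K; ff.rmax = rmax; ff.rmax2 = rmax * rmax;
  return ff;
}

// Computes forces and potential energy; fx/fy/fz must be zeroed by caller.
double compute_forces_core(const std::vector<double> &x, const std::vector<double> &y,
                           const std::vector<double> &z, const IntegerMatrix &bonds,
                           const double L[3], const Pair_ff &ff,
                           std::vector<double> &fx, std::vector<double> &fy,
                           std::vector<double> &fz) {
  double epot = 0.0;
  for_pairs(x, y, z, L, ff.rc, [&](int i, int j, double dx, double dy, double dz, double r2) {
    if (r2 < 1e-12)
      stop("particle overlap: particles %d and %d at distance ~0", i + 1, j + 1);
    double u, fr;
    wca_pair(r2, ff, u, fr);
    epot += u;
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
  });
  int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double dx = min_image(x[i] - x[j], L[0]);
    double dy = min_image(y[i] - y[j], L[1]);
    double dz = min_image(z[i] - z[j], L[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= ff.rmax2)
      stop("FENE bond overstretched: bond %d (particles %d-%d), length %.4f >= rmax %.4f",
           b + 1, i + 1, j + 1, std::sqrt(r2), ff.rmax);
    double u, fr;
    fene_pair(r2, ff, u, fr);
    epot += u;
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
  }
  return epot;
}

void mat_to_vecs(const NumericMatrix &m, std::vector<double> &a,
                 std::vector<double> &b, std::vector<double> &c) {
  int n = m.nrow();
  a.resize(n); b.resize(n); c.resize(n);
  for (int i = 0; i < n; ++i) { a[i] = m(i, 0); b[i] = m(i, 1); c[i] = m(i, 2); }
}

NumericMatrix vecs_to_mat(const std::vector<double> &a, const std::vector<double> &b,
                          const std::vector<double> &c) {
  int n = (int)a.size();
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i) { m(i, 0) = a[i]; m(i, 1) = b[i]; m(i, 2) = c[i]; }
  return m;
}

inline double wrap01(double v, double L) {
  v -= L * std::floor(v / L);
  if (v >= L) v -= L;
  return v;
}

// Fast thermal-noise generator: xoshiro256++ seeded from R's RNG stream
// (so set.seed() still controls trajectories), Gaussians by polar
// Box-Muller. R's own normal sampler is too slow for per-step use.
struct NoiseGen {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;

  static uint64_t splitmix64(uint64_t &state) {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  void seed_from_R() {
    uint64_t mix = 0;
    for (int k = 0; k < 4; ++k) {
      mix ^= (uint64_t)(unif_rand() * 9007199254740992.0) << (k * 11);
      s[k] = splitmix64(mix);
    }
  }

  static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  double runif() { // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  double rnorm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, w;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      w = u * u + v * v;
    } while (w >= 1.0 || w == 0.0);
    double m = std::sqrt(-2.0 * std::log(w) / w);
    spare = v * m;
    have_spare = true;
    return u * m;
  }
};

} // namespace

// [[Rcpp::export]]
NumericVector cpp_wca(double r, double eps, double sigma, double rc) {
  if (r <= 0) stop("particle overlap: pair distance must be positive");
  Pair_ff ff = get_ff(eps, sigma, rc, 1.0, 2.0);
  double u, fr;
  wca_pair(r * r, ff, u, fr);
  return NumericVector::create(_["energy"] = u, _["force"] = fr * r);
}

// [[Rcpp::export]]
NumericVector cpp_fene(double r, double K, double rmax) {
  if (r < 0) stop("bond length must be nonnegative");
  if (r >= rmax) stop("FENE bond overstretched: length %.4f >= rmax %.4f", r, rmax);
  Pair_ff ff = get_ff(1.0, 1.0, 1.0, K, rmax);
  double u, fr;
  fene_pair(r * r, ff, u, fr);
  // report attractive magnitude (positive)
  return NumericVector::create(_["energy"] = u, _["force"] = -fr * r);
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, IntegerMatrix bonds, NumericVector box,
                double eps, double sigma, double rc, double K, double rmax) {
  double L[3];
  get_box(box, L);
  Pair_ff ff = get_ff(eps, sigma, rc, K, rmax);
  std::vector<double> x, y, z;
  mat_to_vecs(pos, x, y, z);
  int np = (int)x.size();
  std::vector<double> fx(np, 0.0), fy(np, 0.0), fz(np, 0.0);
  double epot = compute_forces_core(x, y, z, bonds, L, ff, fx, fy, fz);
  return List::create(_["forces"] = vecs_to_mat(fx, fy, fz), _["energy"] = epot);
}

// [[Rcpp::export]]
double cpp_potential_energy(NumericMatrix pos, IntegerMatrix bonds, NumericVector box,
                            double eps, double sigma, double rc, double K, double rmax) {
  double L[3];
  get_box(box, L);
  Pair_ff ff = get_ff(eps, sigma, rc, K, rmax);
  std::vector<double> x, y, z;
  mat_to_vecs(pos, x, y, z);
  int np = (int)x.size();
  std::vector<double> fx(np, 0.0), fy(np, 0.0), fz(np, 0.0);
  return compute_forces_core(x, y, z, bonds, L, ff, fx, fy, fz);
}

// Verlet pair list built through the linked cells; rebuilt when any
// particle has moved more than half the skin since the last build.
struct NeighborList {
  double skin, rlist;
  std::vector<int> pi, pj;
  std::vector<double> bx, by, bz; // positions at last build

  void build(const std::vector<double> &x, const std::vector<double> &y,
             const std::vector<double> &z, const double L[3], double rc) {
    rlist = rc + skin;
    pi.clear(); pj.clear();
    for_pairs(x, y, z, L, rlist, [&](int i, int j, double, double, double, double) {
      pi.push_back(i); pj.push_back(j);
    });
    bx = x; by = y; bz = z;
  }

  bool stale(const std::vector<double> &x, const std::vector<double> &y,
             const std::vector<double> &z, const double L[3]) const {
    double lim2 = (skin / 2) * (skin / 2);
    for (size_t i = 0; i < x.size(); ++i) {
      double dx = min_image(x[i] - bx[i], L[0]);
      double dy = min_image(y[i] - by[i], L[1]);
      double dz = min_image(z[i] - bz[i], L[2]);
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }
};

// Gronbech-Jensen/Farago discretization of Langevin dynamics with a
// per-particle target temperature (species-dependent thermostat). With
// zeta = 0 this reduces exactly to velocity Verlet. Uses R's RNG stream.
// Snapshots (wrapped positions + velocities) are stored every
// sample_every steps; step 0 is not stored.
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos0, NumericMatrix vel0, NumericVector temp,
                      IntegerMatrix bonds, NumericVector box,
                      double eps, double sigma, double rc, double K, double rmax,
                      double zeta, double dt, int nsteps, int sample_every) {
  double L[3];
  get_box(box, L);
  Pair_ff ff = get_ff(eps, sigma, rc, K, rmax);
  std::vector<double> x, y, z, vx, vy, vz;
  mat_to_vecs(pos0, x, y, z);
  mat_to_vecs(vel0, vx, vy, vz);
  int np = (int)x.size();
  if ((int)temp.size() != np) stop("temp must have one entry per particle");

  const bool noise = zeta > 0;
  const double bcoef = 1.0 / (1.0 + zeta * dt / 2.0);
  const double acoef = (1.0 - zeta * dt / 2.0) / (1.0 + zeta * dt / 2.0);
  std::vector<double> sd(np, 0.0);
  if (noise)
    for (int i = 0; i < np; ++i) sd[i] = std::sqrt(2.0 * zeta * temp[i] * dt);

  NoiseGen rng;
  if (noise) rng.seed_from_R();

  NeighborList nl;
  nl.skin = 0.3 * sigma;
  nl.build(x, y, z, L, ff.rc);
  const double iL0 = 1.0 / L[0], iL1 = 1.0 / L[1], iL2 = 1.0 / L[2];
  const int nb = bonds.nrow();
  std::vector<int> b0(nb), b1(nb);
  for (int b = 0; b < nb; ++b) { b0[b] = bonds(b, 0) - 1; b1[b] = bonds(b, 1) - 1; }

  auto eval_forces = [&](std::vector<double> &fx, std::vector<double> &fy,
                         std::vector<double> &fz) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    const size_t npair = nl.pi.size();
    for (size_t p = 0; p < npair; ++p) {
      int i = nl.pi[p], j = nl.pj[p];
      double dx = min_image_inv(x[i] - x[j], L[0], iL0);
      double dy = min_image_inv(y[i] - y[j], L[1], iL1);
      double dz = min_image_inv(z[i] - z[j], L[2], iL2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= ff.rc2) continue;
      if (r2 < 1e-12) stop("particle overlap during integration");
      double s2 = ff.sigma * ff.sigma / r2;
      double s6 = s2 * s2 * s2;
      double fr = 24.0 * ff.eps * (2.0 * s6 * s6 - s6) / r2;
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
    for (int b = 0; b < nb; ++b) {
      int i = b0[b], j = b1[b];
      double dx = min_image_inv(x[i] - x[j], L[0], iL0);
      double dy = min_image_inv(y[i] - y[j], L[1], iL1);
      double dz = min_image_inv(z[i] - z[j], L[2], iL2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= ff.rmax2)
        stop("FENE bond overstretched: bond %d (particles %d-%d), length %.4f >= rmax %.4f",
             b + 1, i + 1, j + 1, std::sqrt(r2), ff.rmax);
      double fr = -ff.K / (1.0 - r2 / ff.rmax2);
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
  };

  std::vector<double> fx(np), fy(np), fz(np);
  eval_forces(fx, fy, fz);

  std::vector<double> nfx(np), nfy(np), nfz(np);
  std::vector<double> gx(np), gy(np), gz(np);
  List snaps;
  for (int step = 1; step <= nsteps; ++step) {
    if (noise) {
      for (int i = 0; i < np; ++i) {
        double bx = sd[i] * rng.rnorm(), by = sd[i] * rng.rnorm(), bz = sd[i] * rng.rnorm();
        x[i] = wrap01(x[i] + bcoef * dt * vx[i] + bcoef * dt * dt * 0.5 * fx[i] + bcoef * dt * 0.5 * bx, L[0]);
        y[i] = wrap01(y[i] + bcoef * dt * vy[i] + bcoef * dt * dt * 0.5 * fy[i] + bcoef * dt * 0.5 * by, L[1]);
        z[i] = wrap01(z[i] + bcoef * dt * vz[i] + bcoef * dt * dt * 0.5 * fz[i] + bcoef * dt * 0.5 * bz, L[2]);
        // stash noise for the velocity update
        nfx[i] = bx; nfy[i] = by; nfz[i] = bz;
      }
    } else {
      for (int i = 0; i < np; ++i) {
        x[i] = wrap01(x[i] + dt * vx[i] + dt * dt * 0.5 * fx[i], L[0]);
        y[i] = wrap01(y[i] + dt * vy[i] + dt * dt * 0.5 * fy[i], L[1]);
        z[i] = wrap01(z[i] + dt * vz[i] + dt * dt * 0.5 * fz[i], L[2]);
      }
    }
    if (nl.stale(x, y, z, L)) nl.build(x, y, z, L, ff.rc);
    eval_forces(gx, gy, gz);
    if (noise) {
      for (int i = 0; i < np; ++i) {
        vx[i] = acoef * vx[i] + dt * 0.5 * (acoef * fx[i] + gx[i]) + bcoef * nfx[i];
        vy[i] = acoef * vy[i] + dt * 0.5 * (acoef * fy[i] + gy[i]) + bcoef * nfy[i];
        vz[i] = acoef * vz[i] + dt * 0.5 * (acoef * fz[i] + gz[i]) + bcoef * nfz[i];
      }
    } else {
      for (int i = 0; i < np; ++i) {
        vx[i] += dt * 0.5 * (fx[i] + gx[i]);
        vy[i] += dt * 0.5 * (fy[i] + gy[i]);
        vz[i] += dt * 0.5 * (fz[i] + gz[i]);
      }
    }
    fx.swap(gx); fy.swap(gy); fz.swap(gz);
    if (sample_every > 0 && step % sample_every == 0)
      snaps.push_back(List::create(_["pos"] = vecs_to_mat(x, y, z),
                                   _["vel"] = vecs_to_mat(vx, vy, vz),
                                   _["step"] = step));
    if (step % 2000 == 0) checkUserInterrupt();
  }
  return List::create(_["pos"] = vecs_to_mat(x, y, z),
                      _["vel"] = vecs_to_mat(vx, vy, vz),
                      _["snapshots"] = snaps);
}

// Push-off stage for melt preparation: capped soft cosine repulsion
// U = A (1 + cos(pi r / rcut)) with prefactor ramped linearly to a_max,
// plus FENE bonds, integrated with the same Langevin scheme at temperature T.
// [[Rcpp::export]]
List cpp_pushoff(NumericMatrix pos0, IntegerMatrix bonds, NumericVector box,
                 double rcut, double a_max, double K, double rmax,
                 double temperature, double zeta, double dt, int nsteps) {
  double L[3];
  get_box(box, L);
  Pair_ff ff = get_ff(1.0, 1.0, rcut, K, rmax);
  std::vector<double> x, y, z;
  mat_to_vecs(pos0, x, y, z);
  int np = (int)x.size();
  std::vector<double> vx(np, 0.0), vy(np, 0.0), vz(np, 0.0);
  const double bcoef = 1.0 / (1.0 + zeta * dt / 2.0);
  const double acoef = (1.0 - zeta * dt / 2.0) / (1.0 + zeta * dt / 2.0);
  const double sd = std::sqrt(2.0 * zeta * temperature * dt);
  const double pi = M_PI;
  NoiseGen rng;
  rng.seed_from_R();

  auto soft_forces = [&](double amp, std::vector<double> &fx, std::vector<double> &fy,
                         std::vector<double> &fz) {
    for_pairs(x, y, z, L, rcut, [&](int i, int j, double dx, double dy, double dz, double r2) {
      double r = std::sqrt(r2);
      if (r < 1e-9) return; // coincident particles drift apart via noise
      double fr = amp * pi / rcut * std::sin(pi * r / rcut) / r;
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    });
    int nb = bonds.nrow();
    for (int b = 0; b < nb; ++b) {
      int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
      double dx = min_image(x[i] - x[j], L[0]);
      double dy = min_image(y[i] - y[j], L[1]);
      double dz = min_image(z[i] - z[j], L[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= ff.rmax2)
        stop("FENE bond overstretched during push-off (bond %d)", b + 1);
      double u, fr;
      fene_pair(r2, ff, u, fr);
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
  };

  std::vector<double> fx(np, 0.0), fy(np, 0.0), fz(np, 0.0);
  soft_forces(a_max / nsteps, fx, fy, fz);
  for (int step = 1; step <= nsteps; ++step) {
    double amp = a_max * (double)step / nsteps;
    std::vector<double> nx_(np), ny_(np), nz_(np);
    for (int i = 0; i < np; ++i) {
      double bx = sd * rng.rnorm(), by = sd * rng.rnorm(), bz = sd * rng.rnorm();
      x[i] = wrap01(x[i] + bcoef * dt * vx[i] + bcoef * dt * dt * 0.5 * fx[i] + bcoef * dt * 0.5 * bx, L[0]);
      y[i] = wrap01(y[i] + bcoef * dt * vy[i] + bcoef * dt * dt * 0.5 * fy[i] + bcoef * dt * 0.5 * by, L[1]);
      z[i] = wrap01(z[i] + bcoef * dt * vz[i] + bcoef * dt * dt * 0.5 * fz[i] + bcoef * dt * 0.5 * bz, L[2]);
      nx_[i] = bx; ny_[i] = by; nz_[i] = bz;
    }
    std::vector<double> gx(np, 0.0), gy(np, 0.0), gz(np, 0.0);
    soft_forces(amp, gx, gy, gz);
    for (int i = 0; i < np; ++i) {
      vx[i] = acoef * vx[i] + dt * 0.5 * (acoef * fx[i] + gx[i]) + bcoef * nx_[i];
      vy[i] = acoef * vy[i] + dt * 0.5 * (acoef * fy[i] + gy[i]) + bcoef * ny_[i];
      vz[i] = acoef * vz[i] + dt * 0.5 * (acoef * fz[i] + gz[i]) + bcoef * nz_[i];
    }
    fx.swap(gx); fy.swap(gy); fz.swap(gz);
    if (step % 2000 == 0) checkUserInterrupt();
  }
  return List::create(_["pos"] = vecs_to_mat(x, y, z),
                      _["vel"] = vecs_to_mat(vx, vy, vz));
}

// Minimum pair distance (diagnostic for the push-off contract).
// [[Rcpp::export]]
double cpp_min_pair_distance(NumericMatrix pos, NumericVector box, double rcut) {
  double L[3];
  get_box(box, L);
  std::vector<double> x, y, z;
  mat_to_vecs(pos, x, y, z);
  double best = rcut;
  for_pairs(x, y, z, L, rcut, [&](int, int, double, double, double, double r2) {
    double r = std::sqrt(r2);
    if (r < best) best = r;
  });
  return best;
}

// Like-species inter-chain contact fraction: for every monomer, among
// neighbors within rc on *other* chains, the fraction of same-species
// neighbors; x averages this over monomers with >= 1 such neighbor.
// [[Rcpp::export]]
List cpp_contact_fraction(NumericMatrix pos, IntegerVector species, IntegerVector chain,
                          NumericVector box, double rc) {
  double L[3];
  get_box(box, L);
  std::vector<double> x, y, z;
  mat_to_vecs(pos, x, y, z);
  int np = (int)x.size();
  std::vector<int> same(np, 0), tot(np, 0);
  for_pairs(x, y, z, L, rc, [&](int i, int j, double, double, double, double) {
    if (chain[i] == chain[j]) return;
    tot[i]++; tot[j]++;
    if (species[i] == species[j]) { same[i]++; same[j]++; }
  });
  double acc = 0.0;
  int nmon = 0;
  for (int i = 0; i < np; ++i)
    if (tot[i] > 0) { acc += (double)same[i] / tot[i]; nmon++; }
  return List::create(_["x"] = nmon > 0 ? acc / nmon : NA_REAL,
                      _["n_contributing"] = nmon);
}

// Virial part of the slab pressure profile: every unique interacting pair
// (WCA within rc, plus FENE bonds) contributes (r (x) F) / (2 A) to each
// slab whose mid-plane its minimum-image segment crosses. Columns:
// xx, yy, zz, xy, xz, yz. axis is 0/1/2 for x/y/z.
// [[Rcpp::export]]
NumericMatrix cpp_virial_profile(NumericMatrix pos, IntegerMatrix bonds, NumericVector box,
                                 double eps, double sigma, double rc, double K, double rmax,
                                 int nslab, int axis) {
  double L[3];
  get_box(box, L);
  if (axis < 0 || axis > 2) stop("axis must be 0, 1 or 2");
  Pair_ff ff = get_ff(eps, sigma, rc, K, rmax);
  std::vector<double> x, y, z;
  mat_to_vecs(pos, x, y, z);
  double Lax = L[axis];
  double dzs = Lax / nslab;
  double area = (L[0] * L[1] * L[2]) / Lax;
  NumericMatrix out(nslab, 6);

  auto axis_coord = [&](int i) {
    return axis == 0 ? x[i] : (axis == 1 ? y[i] : z[i]);
  };
  auto deposit = [&](int i, double dx, double dy, double dz, double fr) {
    // fr = (F/r); tensor component (r_a F_b) = fr * r_a * r_b
    double d[3] = {dx, dy, dz};
    double za = axis_coord(i);
    double zb = za - d[axis]; // minimum-image position of j along the axis (unwrapped)
    double lo = std::min(za, zb), hi = std::max(za, zb);
    // mid-planes at (k + 0.5) dzs, replicated periodically
    int k0 = (int)std::ceil(lo / dzs - 0.5);
    int k1 = (int)std::floor(hi / dzs - 0.5);
    for (int k = k0; k <= k1; ++k) {
      double plane = (k + 0.5) * dzs;
      if (plane <= lo || plane >= hi) continue;
      int kk = ((k % nslab) + nslab) % nslab;
      double w = 1.0 / (2.0 * area);
      out(kk, 0) += w * fr * dx * dx;
      out(kk, 1) += w * fr * dy * dy;
      out(kk, 2) += w * fr * dz * dz;
      out(kk, 3) += w * fr * dx * dy;
      out(kk, 4) += w * fr * dx * dz;
      out(kk, 5) += w * fr * dy * dz;
    }
  };

  for_pairs(x, y, z, L, ff.rc, [&](int i, int j, double dx, double dy, double dz, double r2) {
    double u, fr;
    wca_pair(r2, ff, u, fr);
    if (fr != 0.0) deposit(i, dx, dy, dz, fr);
  });
  int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double dx = min_image(x[i] - x[j], L[0]);
    double dy = min_image(y[i] - y[j], L[1]);
    double dz = min_image(z[i] - z[j], L[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= ff.rmax2) stop("FENE bond overstretched (bond %d)", b + 1);
    double u, fr;
    fene_pair(r2, ff, u, fr);
    // WCA on bonded pairs is already deposited by the pair loop above
    deposit(i, dx, dy, dz, fr);
  }
  return out;
}
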