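// Coarse-grained MD core: harmonic bonds/angles, shifted Morse pairs,
// Ewald-split Coulomb (real space + k-space + self + slab correction),
// and a velocity-Verlet Langevin integrator with anisotropic damping,
// a frozen SUB layer, a rigid translating SUP layer, normal load and a
// spring-driven sliding stage.
//
// Internal units: eV, nm, ps, mass in eV ps^2 nm^-2.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static const double KC = 1.4400;          // eV nm / e^2
static const double SQRT_PI = 1.7724538509055160273;

// ---------------------------------------------------------------- RNG
// Counter-based (stateless) Gaussian noise: splitmix64 hash of
// (seed, step, atom) -> two uniforms -> Box-Muller.  Restart-invariant by
// construction: the noise depends only on the global step index.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97f4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Acklam's rational approximation to the standard normal quantile
// (relative error < 1.2e-9: far below any thermostat requirement)
static inline double probit(double p) {
  static const double a[] = {-3.969683028665376e+01, 2.209460984245205e+02,
    -2.759285104469687e+02, 1.383577518672690e+02, -3.066479806614716e+01,
    2.506628277459239e+00};
  static const double b[] = {-5.447609879822406e+01, 1.615858368580409e+02,
    -1.556989798598866e+02, 6.680131188771972e+01, -1.328068155288572e+01};
  static const double c[] = {-7.784894002430293e-03, -3.223964580411365e-01,
    -2.400758277161838e+00, -2.549732539343734e+00, 4.374664141464968e+00,
    2.938163982698783e+00};
  static const double d[] = {7.784695709041462e-03, 3.224671290700398e-01,
    2.445134137142996e+00, 3.754408661907416e+00};
  const double plow = 0.02425;
  if (p < plow) {
    double q = std::sqrt(-2 * std::log(p));
    return (((((c[0]*q+c[1])*q+c[2])*q+c[3])*q+c[4])*q+c[5]) /
           ((((d[0]*q+d[1])*q+d[2])*q+d[3])*q+1);
  }
  if (p > 1 - plow) {
    double q = std::sqrt(-2 * std::log(1 - p));
    return -(((((c[0]*q+c[1])*q+c[2])*q+c[3])*q+c[4])*q+c[5]) /
            ((((d[0]*q+d[1])*q+d[2])*q+d[3])*q+1);
  }
  double q = p - 0.5, r = q * q;
  return (((((a[0]*r+a[1])*r+a[2])*r+a[3])*r+a[4])*r+a[5])*q /
         (((((b[0]*r+b[1])*r+b[2])*r+b[3])*r+b[4])*r+1);
}

static inline void gauss_pair(uint64_t seed, uint64_t step, uint64_t atom,
                              double *g1, double *g2) {
  uint64_t h = splitmix64(seed ^ (step * 0xA24BAED4963EE407ULL));
  uint64_t a = splitmix64(h ^ (atom * 0x9FB21C651E98DF25ULL));
  uint64_t b = splitmix64(a);
  // uniforms in (0,1)
  double u1 = ((a >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  double u2 = ((b >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  *g1 = probit(u1);
  *g2 = probit(u2);
}

// ---------------------------------------------------------------- system view
struct Sys {
  int n;
  std::vector<double> x, y, z;      // positions
  const int *type;                  // 0-based species codes (0..7, 7 = RIG)
  const int *layer;                 // 0 SUB, 1 SUP
  const int *group;                 // 0 frozen, 1 SUP-rigid, 2 mobile
  const double *q;                  // charges, e
  const int *mol;                   // molecule id, 0 for rigid beads
  const int *chainpos;              // bead index along chain (0..6), -1 rigid
  double lx, ly;
};

static inline double wrapd(double d, double L) {
  return d - L * std::floor(d / L + 0.5);
}

// pair parameter table index
static inline int ptab_idx(int ti, int tj, int same) {
  return (ti * 8 + tj) * 2 + same;
}

struct FF {
  // bonded
  const int *b1, *b2; const double *bk, *br0; int nb;
  const int *a1, *a2, *a3; const double *ak, *ath0; int na;
  // pair
  const double *D0, *r0;            // 128 each
  double alpha_m, rc;               // Morse stiffness, cutoff
  std::vector<double> mshift, mslope; // per-table-entry shift M(Rc), M'(Rc)
  // exclusions: same molecule, |chainpos_i - chainpos_j| <= 3 -> factor
  double excl_f[3];                 // 1-2, 1-3, 1-4 factors
  // coulomb
  bool use_coul;
  double alpha_e;                   // Ewald splitting, nm^-1
  // k-space
  const int *kx, *ky, *kz; const double *ck; int nk;
  double tplx, tply, tplz;          // 2*pi/L
  double volume;
  bool use_slab;
};

static void precompute_morse_tail(FF &ff) {
  ff.mshift.resize(128);
  ff.mslope.resize(128);
  for (int i = 0; i < 128; i++) {
    double D0 = ff.D0[i], r0 = ff.r0[i];
    double e = std::exp(-ff.alpha_m * (ff.rc - r0));
    ff.mshift[i] = D0 * ((1 - e) * (1 - e) - 1);
    ff.mslope[i] = 2 * D0 * ff.alpha_m * e * (1 - e);
  }
}

// ------------------------------------------------------------- bonded terms
static double bond_forces(const Sys &s, const FF &ff,
                          double *fx, double *fy, double *fz) {
  double e = 0;
  for (int m = 0; m < ff.nb; m++) {
    int i = ff.b1[m], j = ff.b2[m];
    double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
    dx = wrapd(dx, s.lx); dy = wrapd(dy, s.ly);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 1e-12) stop("degenerate bond (r = 0) between atoms %d and %d",
                         i + 1, j + 1);
    double r = std::sqrt(r2);
    double dr = r - ff.br0[m];
    e += 0.5 * ff.bk[m] * dr * dr;
    double fp = -ff.bk[m] * dr / r;
    fx[i] += fp * dx; fy[i] += fp * dy; fz[i] += fp * dz;
    fx[j] -= fp * dx; fy[j] -= fp * dy; fz[j] -= fp * dz;
  }
  return e;
}

static double angle_forces(const Sys &s, const FF &ff,
                           double *fx, double *fy, double *fz) {
  double e = 0;
  for (int m = 0; m < ff.na; m++) {
    int i = ff.a1[m], j = ff.a2[m], k = ff.a3[m];
    double d1x = s.x[i] - s.x[j], d1y = s.y[i] - s.y[j], d1z = s.z[i] - s.z[j];
    double d2x = s.x[k] - s.x[j], d2y = s.y[k] - s.y[j], d2z = s.z[k] - s.z[j];
    d1x = wrapd(d1x, s.lx); d1y = wrapd(d1y, s.ly);
    d2x = wrapd(d2x, s.lx); d2y = wrapd(d2y, s.ly);
    double rsq1 = d1x * d1x + d1y * d1y + d1z * d1z;
    double rsq2 = d2x * d2x + d2y * d2y + d2z * d2z;
    if (rsq1 < 1e-12 || rsq2 < 1e-12)
      stop("coincident beads in angle triplet %d", m + 1);
    double r1 = std::sqrt(rsq1), r2 = std::sqrt(rsq2);
    double c = (d1x * d2x + d1y * d2y + d1z * d2z) / (r1 * r2);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double ssin = std::sqrt(1.0 - c * c);
    if (ssin < 1e-8) ssin = 1e-8;
    double dtheta = std::acos(c) - ff.ath0[m];
    e += 0.5 * ff.ak[m] * dtheta * dtheta;
    double a = -ff.ak[m] * dtheta / ssin;   // dE/dcos(theta) factor
    double a11 = a * c / rsq1;
    double a12 = -a / (r1 * r2);
    double a22 = a * c / rsq2;
    double f1x = a11 * d1x + a12 * d2x;
    double f1y = a11 * d1y + a12 * d2y;
    double f1z = a11 * d1z + a12 * d2z;
    double f3x = a22 * d2x + a12 * d1x;
    double f3y = a22 * d2y + a12 * d1y;
    double f3z = a22 * d2z + a12 * d1z;
    fx[i] += f1x; fy[i] += f1y; fz[i] += f1z;
    fx[k] += f3x; fy[k] += f3y; fz[k] += f3z;
    fx[j] -= f1x + f3x; fy[j] -= f1y + f3y; fz[j] -= f1z + f3z;
  }
  return e;
}

// --------------------------------------------------------------- pair terms
// Neighbour list: static pair pruning rules.
// skip if both beads rigid (any combination of groups 0/1);
// skip cross-layer pairs involving a non-head bead (NP1, NP2, RIG):
// cross-layer interactions are restricted to the polar heads.
static inline bool pair_allowed(const Sys &s, int i, int j,
                                bool skip_rigid_rigid) {
  bool rig_i = s.group[i] != 2, rig_j = s.group[j] != 2;
  if (rig_i && rig_j) return false;          // handled as a constant
  (void)skip_rigid_rigid;
  if (s.layer[i] != s.layer[j]) {
    if (s.type[i] >= 5 || s.type[j] >= 5) return false; // NP1=5, NP2=6, RIG=7
  }
  return true;
}

struct NeighList {
  std::vector<int> i, j;
  std::vector<double> sx, sy;      // image shift: r_ij = (xi - xj + sx, ...)
  std::vector<signed char> excl;   // -1 none, 0/1/2 exclusion class (1-2/1-3/1-4)
  double rlist;
};

// Pairs are stored with an explicit periodic-image shift so that cells
// smaller than twice the list cutoff (where one pair interacts with more
// than one image) are handled exactly; for ordinary cells the image loop
// collapses to the single minimum image.
static void build_neighbours(const Sys &s, const FF &ff, double rlist,
                             NeighList &nl) {
  nl.i.clear(); nl.j.clear(); nl.sx.clear(); nl.sy.clear(); nl.excl.clear();
  nl.rlist = rlist;
  double rl2 = rlist * rlist;
  int nix = (int)std::floor(rlist / s.lx + 0.5);
  int niy = (int)std::floor(rlist / s.ly + 0.5);
  for (int i = 0; i < s.n; i++) {
    for (int j = i + 1; j < s.n; j++) {
      if (!pair_allowed(s, i, j, true)) continue;
      signed char ex = -1;
      if (s.mol[i] > 0 && s.mol[i] == s.mol[j]) {
        int d = std::abs(s.chainpos[i] - s.chainpos[j]);
        if (d <= 3) {
          ex = (signed char)(d - 1);
          if (ff.excl_f[d - 1] == 0.0 && (!ff.use_coul ||
              s.q[i] * s.q[j] == 0.0)) continue;  // fully excluded, uncharged
        }
      }
      double dx0 = s.x[i] - s.x[j], dy0 = s.y[i] - s.y[j];
      double bx = wrapd(dx0, s.lx), by = wrapd(dy0, s.ly);
      double dz = s.z[i] - s.z[j];
      for (int ix = -nix; ix <= nix; ix++) {
        double dx = bx + ix * s.lx;
        for (int iy = -niy; iy <= niy; iy++) {
          double dy = by + iy * s.ly;
          if (dx * dx + dy * dy + dz * dz < rl2) {
            nl.i.push_back(i); nl.j.push_back(j);
            nl.sx.push_back(bx - dx0 + ix * s.lx);
            nl.sy.push_back(by - dy0 + iy * s.ly);
            nl.excl.push_back(ex);
          }
        }
      }
    }
  }
}

// Morse + real-space Coulomb over the neighbour list.
static void pair_forces(const Sys &s, const FF &ff, const NeighList &nl,
                        double *fx, double *fy, double *fz,
                        double *e_morse, double *e_creal) {
  double em = 0, ec = 0;
  double rc2 = ff.rc * ff.rc;
  int np = (int)nl.i.size();
  for (int p = 0; p < np; p++) {
    int i = nl.i[p], j = nl.j[p];
    double dx = s.x[i] - s.x[j] + nl.sx[p];
    double dy = s.y[i] - s.y[j] + nl.sy[p];
    double dz = s.z[i] - s.z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) continue;
    double fac = 1.0;
    bool excl_corr = false;
    if (nl.excl[p] >= 0) { fac = ff.excl_f[nl.excl[p]]; excl_corr = true; }
    double r = std::sqrt(r2);
    double fp = 0;  // (scalar force)/r along (ri-rj)
    int idx = ptab_idx(s.type[i], s.type[j],
                       s.layer[i] == s.layer[j] ? 1 : 0);
    double D0 = ff.D0[idx];
    if (D0 > 0.0 && fac > 0.0) {
      double ex = std::exp(-ff.alpha_m * (r - ff.r0[idx]));
      double omx = 1.0 - ex;
      double V = D0 * (omx * omx - 1.0) - ff.mshift[idx]
                 - (r - ff.rc) * ff.mslope[idx];
      double dV = 2.0 * D0 * ff.alpha_m * ex * omx - ff.mslope[idx];
      em += fac * V;
      fp += -fac * dV / r;
    }
    double qq = s.q[i] * s.q[j];
    if (ff.use_coul && qq != 0.0) {
      if (r < 1e-4) stop("overlapping charged beads (r < 1e-4 nm)");
      double ar = ff.alpha_e * r;
      double erfc_ar = std::erfc(ar);
      double gauss = 2.0 * ff.alpha_e / SQRT_PI * std::exp(-ar * ar);
      double pre = KC * qq;
      // scaled real-space term
      ec += fac * pre * erfc_ar / r;
      fp += fac * pre * (erfc_ar / r2 + gauss / r) / r;
      if (excl_corr && fac < 1.0) {
        // cancel the k-space contribution of the excluded fraction
        double erf_ar = 1.0 - erfc_ar;
        ec += -(1.0 - fac) * pre * erf_ar / r;
        fp += -(1.0 - fac) * pre * (erf_ar / r2 - gauss / r) / r;
      }
    }
    if (fp != 0.0) {
      fx[i] += fp * dx; fy[i] += fp * dy; fz[i] += fp * dz;
      fx[j] -= fp * dx; fy[j] -= fp * dy; fz[j] -= fp * dz;
    }
  }
  *e_morse = em;
  *e_creal = ec;
}

// Self-image interactions arise when a box edge is shorter than the
// cutoff: each atom then sees its own periodic images at fixed lattice
// separations.  The distance to any self image is a constant cell vector,
// so the contribution is a constant energy with exactly zero force.
static void self_image_const(const Sys &s, const FF &ff, bool rigid_part,
                             double *e_morse, double *e_coul) {
  int nix = (int)std::floor(ff.rc / s.lx + 0.5);
  int niy = (int)std::floor(ff.rc / s.ly + 0.5);
  if (nix == 0 && niy == 0) return;
  double rc2 = ff.rc * ff.rc;
  for (int i = 0; i < s.n; i++) {
    bool rig = s.group[i] != 2;
    if (rig != rigid_part) continue;
    for (int ix = -nix; ix <= nix; ix++) {
      for (int iy = -niy; iy <= niy; iy++) {
        if (!(ix > 0 || (ix == 0 && iy > 0))) continue;  // half space
        double r2 = (ix * s.lx) * (ix * s.lx) + (iy * s.ly) * (iy * s.ly);
        if (r2 >= rc2) continue;
        double r = std::sqrt(r2);
        int idx = ptab_idx(s.type[i], s.type[i], 1);
        double D0 = ff.D0[idx];
        if (D0 > 0) {
          double ex = std::exp(-ff.alpha_m * (r - ff.r0[idx]));
          double omx = 1.0 - ex;
          *e_morse += D0 * (omx * omx - 1.0) - ff.mshift[idx]
                      - (r - ff.rc) * ff.mslope[idx];
        }
        if (ff.use_coul && s.q[i] != 0.0) {
          *e_coul += KC * s.q[i] * s.q[i] * std::erfc(ff.alpha_e * r) / r;
        }
      }
    }
  }
}

// ------------------------------------------------- tabulated pair kernel
// The integrator evaluates Morse and erfc-Coulomb through cubic Hermite
// tables in r (value and derivative stored at the nodes), so the
// interpolated force is exactly the derivative of the interpolated energy
// and energy conservation is not degraded, while exp/erfc disappear from
// the inner loop.  The static evaluator keeps the analytic forms.
struct PairTables {
  int nbin = 0;
  double r_lo = 0.06, r_hi = 1.0, h = 0, inv_h = 0;
  // flat node arrays, interleaved per class: [V0 M0 V1 M1 ...]
  std::vector<double> VM;
  int stride = 0;                          // 2 * nbin
  int cls[128];                            // ptab entry -> class (-1 none)
  int coul_cls = -1;                       // unit-charge erfc table
};

static void build_pair_tables(const FF &ff, PairTables &pt, int nbin = 2048) {
  pt.nbin = nbin;
  pt.r_hi = ff.rc;
  pt.h = (pt.r_hi - pt.r_lo) / (nbin - 1);
  pt.inv_h = 1.0 / pt.h;
  std::vector<std::pair<double, double>> classes;
  for (int i = 0; i < 128; i++) {
    pt.cls[i] = -1;
    if (ff.D0[i] <= 0) continue;
    std::pair<double, double> key(ff.D0[i], ff.r0[i]);
    int c = -1;
    for (size_t k = 0; k < classes.size(); k++)
      if (classes[k] == key) { c = (int)k; break; }
    if (c < 0) { classes.push_back(key); c = (int)classes.size() - 1; }
    pt.cls[i] = c;
  }
  int nc = (int)classes.size() + (ff.use_coul ? 1 : 0);
  pt.stride = 2 * nbin;
  pt.VM.assign((size_t)nc * pt.stride, 0.0);
  for (size_t c = 0; c < classes.size(); c++) {
    double D0 = classes[c].first, r0 = classes[c].second;
    double erc = std::exp(-ff.alpha_m * (ff.rc - r0));
    double shift = D0 * ((1 - erc) * (1 - erc) - 1);
    double slope = 2 * D0 * ff.alpha_m * erc * (1 - erc);
    double *row = pt.VM.data() + c * pt.stride;
    for (int b = 0; b < nbin; b++) {
      double r = pt.r_lo + b * pt.h;
      double ex = std::exp(-ff.alpha_m * (r - r0));
      row[2 * b] = D0 * ((1 - ex) * (1 - ex) - 1) - shift
                   - (r - ff.rc) * slope;
      row[2 * b + 1] = 2 * D0 * ff.alpha_m * ex * (1 - ex) - slope;
    }
  }
  if (ff.use_coul) {
    pt.coul_cls = (int)classes.size();
    double *row = pt.VM.data() + (size_t)pt.coul_cls * pt.stride;
    for (int b = 0; b < nbin; b++) {
      double r = pt.r_lo + b * pt.h;
      double ar = ff.alpha_e * r;
      double erfc_ar = std::erfc(ar);
      row[2 * b] = KC * erfc_ar / r;
      row[2 * b + 1] = -KC * (erfc_ar / (r * r) +
        2.0 * ff.alpha_e / SQRT_PI * std::exp(-ar * ar) / r);
    }
  }
}

// Hermite lookup: returns V, and dV/dr via *dv
static inline double tab_eval(const PairTables &pt, int c, double r,
                              double *dv) {
  double x = (r - pt.r_lo) * pt.inv_h;
  int b = (int)x;
  if (b < 0) b = 0;
  if (b > pt.nbin - 2) b = pt.nbin - 2;
  double t = x - b;
  const double *n0 = pt.VM.data() + (size_t)c * pt.stride + 2 * b;
  double V0 = n0[0], M0 = n0[1], V1 = n0[2], M1 = n0[3];
  double t2 = t * t, t3 = t2 * t;
  double h00 = 2 * t3 - 3 * t2 + 1, h01 = 1 - h00;
  double h10 = t3 - 2 * t2 + t, h11 = t3 - t2;
  double v = h00 * V0 + h01 * V1 + pt.h * (h10 * M0 + h11 * M1);
  *dv = (6 * t2 - 6 * t) * pt.inv_h * (V0 - V1) +
        (3 * t2 - 4 * t + 1) * M0 + (3 * t2 - 2 * t) * M1;
  return v;
}

// integrator pair kernel: tabulated fast path, analytic fallback for
// excluded pairs and very short distances
static void pair_forces_tab(const Sys &s, const FF &ff, const PairTables &pt,
                            const NeighList &nl,
                            double *fx, double *fy, double *fz,
                            double *e_morse, double *e_creal) {
  double em = 0, ec = 0;
  double rc2 = ff.rc * ff.rc;
  int np = (int)nl.i.size();
  for (int p = 0; p < np; p++) {
    int i = nl.i[p], j = nl.j[p];
    double dx = s.x[i] - s.x[j] + nl.sx[p];
    double dy = s.y[i] - s.y[j] + nl.sy[p];
    double dz = s.z[i] - s.z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) continue;
    double r = std::sqrt(r2);
    double fp = 0;
    if (nl.excl[p] >= 0 || r < pt.r_lo) {
      // slow analytic path (rare)
      double fac = 1.0;
      bool excl_corr = false;
      if (nl.excl[p] >= 0) { fac = ff.excl_f[nl.excl[p]]; excl_corr = true; }
      int idx = ptab_idx(s.type[i], s.type[j],
                         s.layer[i] == s.layer[j] ? 1 : 0);
      double D0 = ff.D0[idx];
      if (D0 > 0.0 && fac > 0.0) {
        double ex = std::exp(-ff.alpha_m * (r - ff.r0[idx]));
        double omx = 1.0 - ex;
        double V = D0 * (omx * omx - 1.0) - ff.mshift[idx]
                   - (r - ff.rc) * ff.mslope[idx];
        double dV = 2.0 * D0 * ff.alpha_m * ex * omx - ff.mslope[idx];
        em += fac * V;
        fp += -fac * dV / r;
      }
      double qq = s.q[i] * s.q[j];
      if (ff.use_coul && qq != 0.0) {
        if (r < 1e-4) stop("overlapping charged beads (r < 1e-4 nm)");
        double ar = ff.alpha_e * r;
        double erfc_ar = std::erfc(ar);
        double gauss = 2.0 * ff.alpha_e / SQRT_PI * std::exp(-ar * ar);
        double pre = KC * qq;
        ec += fac * pre * erfc_ar / r;
        fp += fac * pre * (erfc_ar / r2 + gauss / r) / r;
        if (excl_corr && fac < 1.0) {
          double erf_ar = 1.0 - erfc_ar;
          ec += -(1.0 - fac) * pre * erf_ar / r;
          fp += -(1.0 - fac) * pre * (erf_ar / r2 - gauss / r) / r;
        }
      }
    } else {
      int idx = ptab_idx(s.type[i], s.type[j],
                         s.layer[i] == s.layer[j] ? 1 : 0);
      int c = pt.cls[idx];
      double dv;
      if (c >= 0) {
        em += tab_eval(pt, c, r, &dv);
        fp -= dv / r;
      }
      double qq = s.q[i] * s.q[j];
      if (qq != 0.0) {
        double v = tab_eval(pt, pt.coul_cls, r, &dv);
        ec += qq * v;
        fp -= qq * dv / r;
      }
    }
    if (fp != 0.0) {
      fx[i] += fp * dx; fy[i] += fp * dy; fz[i] += fp * dz;
      fx[j] -= fp * dx; fy[j] -= fp * dy; fz[j] -= fp * dz;
    }
  }
  *e_morse = em;
  *e_creal = ec;
}

// ------------------------------------------------------------ reciprocal part
// Classical Ewald k-space sum over a half-space k list, plus self energy and
// the slab (dipole) correction for 2D-periodic geometry embedded in a
// 3D-periodic padded box.
static double recip_forces(const Sys &s, const FF &ff,
                           const std::vector<int> &qidx,
                           double *fx, double *fy, double *fz,
                           double *e_slab_out) {
  int nq = (int)qidx.size();
  double e = 0;
  if (nq > 0 && ff.nk > 0) {
    int nxmax = 0, nymax = 0, nzmax = 0;
    for (int k = 0; k < ff.nk; k++) {
      nxmax = std::max(nxmax, std::abs(ff.kx[k]));
      nymax = std::max(nymax, std::abs(ff.ky[k]));
      nzmax = std::max(nzmax, std::abs(ff.kz[k]));
    }
    // per-atom phase tables e^{i 2 pi n u / L} for n = 0..nmax
    std::vector<double> cxt((nxmax + 1) * nq), sxt((nxmax + 1) * nq);
    std::vector<double> cyt((nymax + 1) * nq), syt((nymax + 1) * nq);
    std::vector<double> czt((nzmax + 1) * nq), szt((nzmax + 1) * nq);
    for (int a = 0; a < nq; a++) {
      int i = qidx[a];
      double px = ff.tplx * s.x[i], py = ff.tply * s.y[i], pz = ff.tplz * s.z[i];
      double c1 = std::cos(px), s1 = std::sin(px);
      cxt[a] = 1; sxt[a] = 0;
      for (int nn = 1; nn <= nxmax; nn++) {
        cxt[nn * nq + a] = cxt[(nn - 1) * nq + a] * c1 - sxt[(nn - 1) * nq + a] * s1;
        sxt[nn * nq + a] = sxt[(nn - 1) * nq + a] * c1 + cxt[(nn - 1) * nq + a] * s1;
      }
      c1 = std::cos(py); s1 = std::sin(py);
      cyt[a] = 1; syt[a] = 0;
      for (int nn = 1; nn <= nymax; nn++) {
        cyt[nn * nq + a] = cyt[(nn - 1) * nq + a] * c1 - syt[(nn - 1) * nq + a] * s1;
        syt[nn * nq + a] = syt[(nn - 1) * nq + a] * c1 + cyt[(nn - 1) * nq + a] * s1;
      }
      c1 = std::cos(pz); s1 = std::sin(pz);
      czt[a] = 1; szt[a] = 0;
      for (int nn = 1; nn <= nzmax; nn++) {
        czt[nn * nq + a] = czt[(nn - 1) * nq + a] * c1 - szt[(nn - 1) * nq + a] * s1;
        szt[nn * nq + a] = szt[(nn - 1) * nq + a] * c1 + czt[(nn - 1) * nq + a] * s1;
      }
    }
    std::vector<double> pc(nq), ps(nq);  // scratch: e^{i k r_i}
    for (int k = 0; k < ff.nk; k++) {
      int nx = ff.kx[k], ny = ff.ky[k], nz = ff.kz[k];
      int ax = std::abs(nx), ay = std::abs(ny), az = std::abs(nz);
      double Sre = 0, Sim = 0;
      for (int a = 0; a < nq; a++) {
        double cx = cxt[ax * nq + a], sx = sxt[ax * nq + a];
        if (nx < 0) sx = -sx;
        double cy = cyt[ay * nq + a], sy = syt[ay * nq + a];
        if (ny < 0) sy = -sy;
        double cz = czt[az * nq + a], sz = szt[az * nq + a];
        if (nz < 0) sz = -sz;
        double cxy = cx * cy - sx * sy;
        double sxy = sx * cy + cx * sy;
        double cr = cxy * cz - sxy * sz;
        double sr = sxy * cz + cxy * sz;
        pc[a] = cr; ps[a] = sr;
        double q = s.q[qidx[a]];
        Sre += q * cr; Sim += q * sr;
      }
      double c = ff.ck[k];
      e += c * (Sre * Sre + Sim * Sim);
      double kxv = ff.tplx * nx, kyv = ff.tply * ny, kzv = ff.tplz * nz;
      for (int a = 0; a < nq; a++) {
        // Im(e^{i k r_i} S*) = ps*Sre - pc*Sim
        double w = 2.0 * c * s.q[qidx[a]] * (ps[a] * Sre - pc[a] * Sim);
        int i = qidx[a];
        fx[i] += w * kxv; fy[i] += w * kyv; fz[i] += w * kzv;
      }
    }
  }
  // self energy
  double qsq = 0;
  for (int a = 0; a < nq; a++) qsq += s.q[qidx[a]] * s.q[qidx[a]];
  e -= KC * ff.alpha_e / SQRT_PI * qsq;
  // slab correction (Yeh-Berkowitz)
  double eslab = 0;
  if (ff.use_slab) {
    double mz = 0;
    for (int a = 0; a < nq; a++) mz += s.q[qidx[a]] * s.z[qidx[a]];
    double pre = 2.0 * M_PI * KC / ff.volume;
    eslab = pre * mz * mz;
    for (int a = 0; a < nq; a++) {
      int i = qidx[a];
      fz[i] -= 2.0 * pre * s.q[i] * mz;
    }
  }
  *e_slab_out = eslab;
  return e;
}

// ------------------------------------------------------- shared construction
struct Parsed {
  Sys s;
  FF ff;
  std::vector<int> qidx;
  // keep R vectors alive / copies
  IntegerVector type, layer, group, mol, chainpos;
  NumericVector q;
  IntegerVector b1, b2, a1, a2, a3;
  NumericVector bk, br0, ak, ath0, D0, r0v, ck;
  IntegerVector kxv, kyv, kzv;
};

static void parse_system(List sys, List ffp, Parsed &P) {
  NumericMatrix X = sys["positions"];
  int n = X.nrow();
  P.s.n = n;
  P.s.x.resize(n); P.s.y.resize(n); P.s.z.resize(n);
  for (int i = 0; i < n; i++) {
    P.s.x[i] = X(i, 0); P.s.y[i] = X(i, 1); P.s.z[i] = X(i, 2);
  }
  P.type = sys["type0"]; P.layer = sys["layer"]; P.group = sys["group"];
  P.mol = sys["mol_id"]; P.chainpos = sys["chainpos"];
  P.q = sys["charge"];
  P.s.type = INTEGER(P.type); P.s.layer = INTEGER(P.layer);
  P.s.group = INTEGER(P.group); P.s.mol = INTEGER(P.mol);
  P.s.chainpos = INTEGER(P.chainpos);
  P.s.q = REAL(P.q);
  NumericVector box = sys["box"];
  P.s.lx = box[0]; P.s.ly = box[1];

  P.b1 = ffp["b1"]; P.b2 = ffp["b2"]; P.bk = ffp["bk"]; P.br0 = ffp["br0"];
  P.a1 = ffp["a1"]; P.a2 = ffp["a2"]; P.a3 = ffp["a3"];
  P.ak = ffp["ak"]; P.ath0 = ffp["ath0"];
  P.ff.b1 = INTEGER(P.b1); P.ff.b2 = INTEGER(P.b2);
  P.ff.bk = REAL(P.bk); P.ff.br0 = REAL(P.br0);
  P.ff.nb = P.b1.size();
  P.ff.a1 = INTEGER(P.a1); P.ff.a2 = INTEGER(P.a2); P.ff.a3 = INTEGER(P.a3);
  P.ff.ak = REAL(P.ak); P.ff.ath0 = REAL(P.ath0);
  P.ff.na = P.a1.size();
  P.D0 = ffp["D0tab"]; P.r0v = ffp["r0tab"];
  P.ff.D0 = REAL(P.D0); P.ff.r0 = REAL(P.r0v);
  P.ff.alpha_m = as<double>(ffp["morse_alpha"]);
  P.ff.rc = as<double>(ffp["rc"]);
  NumericVector ef = ffp["excl_factors"];
  for (int i = 0; i < 3; i++) P.ff.excl_f[i] = ef[i];
  P.ff.use_coul = as<bool>(ffp["use_coulomb"]);
  P.ff.alpha_e = as<double>(ffp["ewald_alpha"]);
  P.kxv = ffp["kx"]; P.kyv = ffp["ky"]; P.kzv = ffp["kz"];
  P.ck = ffp["ckcoef"];
  P.ff.kx = INTEGER(P.kxv); P.ff.ky = INTEGER(P.kyv); P.ff.kz = INTEGER(P.kzv);
  P.ff.ck = REAL(P.ck);
  P.ff.nk = P.kxv.size();
  P.ff.tplx = as<double>(ffp["tplx"]);
  P.ff.tply = as<double>(ffp["tply"]);
  P.ff.tplz = as<double>(ffp["tplz"]);
  P.ff.volume = as<double>(ffp["volume"]);
  P.ff.use_slab = as<bool>(ffp["use_slab"]);
  precompute_morse_tail(P.ff);
  if (P.ff.use_coul)
    for (int i = 0; i < n; i++)
      if (P.s.q[i] != 0.0) P.qidx.push_back(i);
}

// [[Rcpp::export(name = ".zw_eval_cpp")]]
List zw_eval_cpp(List sys, List ffp, bool include_rigid_rigid = false) {
  Parsed P;
  parse_system(sys, ffp, P);
  int n = P.s.n;
  NumericMatrix Fb(n, 3), Fa(n, 3), Fm(n, 3), Fcr(n, 3), Fk(n, 3);
  std::vector<double> fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);

  double eb = bond_forces(P.s, P.ff, fx.data(), fy.data(), fz.data());
  for (int i = 0; i < n; i++) { Fb(i,0)=fx[i]; Fb(i,1)=fy[i]; Fb(i,2)=fz[i]; }
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  double ea = angle_forces(P.s, P.ff, fx.data(), fy.data(), fz.data());
  for (int i = 0; i < n; i++) { Fa(i,0)=fx[i]; Fa(i,1)=fy[i]; Fa(i,2)=fz[i]; }

  NeighList nl;
  build_neighbours(P.s, P.ff, P.ff.rc, nl);
  // Morse separated from real-space Coulomb for term-wise reporting:
  // run pair_forces twice with masked settings.
  double em = 0, ecr = 0, dummy;
  {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    FF ff_m = P.ff; ff_m.use_coul = false;
    pair_forces(P.s, ff_m, nl, fx.data(), fy.data(), fz.data(), &em, &dummy);
    for (int i = 0; i < n; i++) { Fm(i,0)=fx[i]; Fm(i,1)=fy[i]; Fm(i,2)=fz[i]; }
  }
  double e_self_coul = 0;
  self_image_const(P.s, P.ff, false, &em, &e_self_coul);
  double e_rr = 0;
  if (include_rigid_rigid) {
    // constant same-layer rigid-rigid Morse energy (direct O(Nrig^2) sum,
    // with the same multi-image handling as the neighbour list)
    double rc2 = P.ff.rc * P.ff.rc;
    int nix = (int)std::floor(P.ff.rc / P.s.lx + 0.5);
    int niy = (int)std::floor(P.ff.rc / P.s.ly + 0.5);
    for (int i = 0; i < n; i++) {
      if (P.s.group[i] == 2) continue;
      for (int j = i + 1; j < n; j++) {
        if (P.s.group[j] == 2) continue;
        if (P.s.layer[i] != P.s.layer[j]) continue;  // SUB-SUP masked
        double bx = wrapd(P.s.x[i] - P.s.x[j], P.s.lx);
        double by = wrapd(P.s.y[i] - P.s.y[j], P.s.ly);
        double dz = P.s.z[i] - P.s.z[j];
        int idx = ptab_idx(P.s.type[i], P.s.type[j], 1);
        double D0 = P.ff.D0[idx];
        if (D0 <= 0) continue;
        for (int ix = -nix; ix <= nix; ix++) {
          for (int iy = -niy; iy <= niy; iy++) {
            double dx = bx + ix * P.s.lx, dy = by + iy * P.s.ly;
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 >= rc2) continue;
            double r = std::sqrt(r2);
            double ex = std::exp(-P.ff.alpha_m * (r - P.ff.r0[idx]));
            double omx = 1.0 - ex;
            e_rr += D0 * (omx * omx - 1.0) - P.ff.mshift[idx]
                    - (r - P.ff.rc) * P.ff.mslope[idx];
          }
        }
      }
    }
  }
  if (include_rigid_rigid) {
    double rr_coul_dummy = 0;
    self_image_const(P.s, P.ff, true, &e_rr, &rr_coul_dummy);
  }
  double ek = 0, eslab = 0;
  if (P.ff.use_coul) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    FF ff_c = P.ff;
    // Coulomb real-space only: zero all Morse wells
    std::vector<double> zeroD(128, 0.0);
    ff_c.D0 = zeroD.data();
    precompute_morse_tail(ff_c);
    pair_forces(P.s, ff_c, nl, fx.data(), fy.data(), fz.data(), &dummy, &ecr);
    ecr += e_self_coul;
    for (int i = 0; i < n; i++) { Fcr(i,0)=fx[i]; Fcr(i,1)=fy[i]; Fcr(i,2)=fz[i]; }
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    ek = recip_forces(P.s, P.ff, P.qidx, fx.data(), fy.data(), fz.data(), &eslab);
    for (int i = 0; i < n; i++) { Fk(i,0)=fx[i]; Fk(i,1)=fy[i]; Fk(i,2)=fz[i]; }
  }
  return List::create(
    _["e_bond"] = eb, _["e_angle"] = ea, _["e_morse"] = em,
    _["e_rigid_rigid"] = e_rr,
    _["e_coul_real"] = ecr, _["e_coul_recip"] = ek, _["e_slab"] = eslab,
    _["f_bond"] = Fb, _["f_angle"] = Fa, _["f_morse"] = Fm,
    _["f_coul_real"] = Fcr, _["f_coul_recip"] = Fk,
    _["n_pairs"] = (int)nl.i.size());
}

// ------------------------------------------------------------- integrator
// [[Rcpp::export(name = ".zw_run_cpp")]]
List zw_run_cpp(List sys, List ffp, List dyn) {
  Parsed P;
  parse_system(sys, ffp, P);
  int n = P.s.n;
  PairTables PT;
  build_pair_tables(P.ff, PT);
  double e_self_m = 0, e_self_c = 0;
  self_image_const(P.s, P.ff, false, &e_self_m, &e_self_c);

  NumericMatrix V0 = dyn["velocities"];
  std::vector<double> vx(n), vy(n), vz(n);
  for (int i = 0; i < n; i++) { vx[i]=V0(i,0); vy[i]=V0(i,1); vz[i]=V0(i,2); }
  NumericVector massv = dyn["mass_int"];
  const double *m = REAL(massv);

  double dt = as<double>(dyn["dt"]);
  long nsteps = (long)as<double>(dyn["nsteps"]);
  long step0 = (long)as<double>(dyn["step0"]);
  double t0 = as<double>(dyn["time0"]);
  double gamma = as<double>(dyn["gamma"]);
  double kT = as<double>(dyn["kT"]);             // eV
  uint64_t seed = (uint64_t)as<double>(dyn["seed"]);
  int sample_every = as<int>(dyn["sample_every"]);
  int kspace_every = as<int>(dyn["kspace_every"]);
  double skin = as<double>(dyn["skin"]);
  int drive_mode = as<int>(dyn["drive_mode"]);   // 0 spring, 1 prescribed vx, 2 free
  double v_stage = as<double>(dyn["v_stage"]);   // nm/ps
  double k_spring = as<double>(dyn["k_spring"]); // eV/nm^2
  double stage0 = as<double>(dyn["stage0"]);
  double load_fz = as<double>(dyn["load_fz"]);   // eV/nm, applied along -z (<0)
  double u_const = as<double>(dyn["u_const"]);   // constant rigid-rigid energy
  double area = P.s.lx * P.s.ly;

  // SUP rigid body
  std::vector<int> sup_idx, mob_idx, froz_idx;
  for (int i = 0; i < n; i++) {
    if (P.s.group[i] == 1) sup_idx.push_back(i);
    else if (P.s.group[i] == 2) mob_idx.push_back(i);
    else froz_idx.push_back(i);
  }
  double Msup = 0;
  for (int i : sup_idx) Msup += m[i];
  NumericVector bv = dyn["body_vel"];
  double bvx = bv[0], bvy = bv[1], bvz = bv[2];

  // CA plane bookkeeping for the hooking fraction
  std::vector<int> ca_sub, ca_sup;
  for (int i = 0; i < n; i++) {
    if (P.s.type[i] == 0) {   // CA
      if (P.s.layer[i] == 0) ca_sub.push_back(i); else ca_sup.push_back(i);
    }
  }
  double hook_dz = as<double>(dyn["hook_dz"]);
  double sub_plane_z = 0;
  int nfroz = (int)froz_idx.size();
  for (int i : froz_idx) sub_plane_z += P.s.z[i];
  if (nfroz > 0) sub_plane_z /= nfroz;

  // forces
  std::vector<double> fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
  std::vector<double> fkx(n, 0.0), fky(n, 0.0), fkz(n, 0.0); // cached k-space
  double e_recip_cache = 0, e_slab_cache = 0;
  // optional cached k-space forces carried over a restart
  if (dyn.containsElementNamed("recip_cache") &&
      !Rf_isNull(dyn["recip_cache"])) {
    List rca = dyn["recip_cache"];
    NumericMatrix FK = rca["forces"];
    for (int i = 0; i < n; i++) { fkx[i]=FK(i,0); fky[i]=FK(i,1); fkz[i]=FK(i,2); }
    e_recip_cache = as<double>(rca["e_recip"]);
    e_slab_cache = as<double>(rca["e_slab"]);
  }

  NeighList nl;
  double rlist = P.ff.rc + skin;
  std::vector<double> xr(n), yr(n), zr(n);  // positions at last rebuild
  auto rebuild = [&]() {
    build_neighbours(P.s, P.ff, rlist, nl);
    xr = P.s.x; yr = P.s.y; zr = P.s.z;
  };
  auto max_disp2 = [&]() {
    double md = 0;
    for (int i : mob_idx) {
      double dx = P.s.x[i]-xr[i], dy = P.s.y[i]-yr[i], dz = P.s.z[i]-zr[i];
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 > md) md = d2;
    }
    if (!sup_idx.empty()) {
      int i = sup_idx[0];
      double dx = P.s.x[i]-xr[i], dy = P.s.y[i]-yr[i], dz = P.s.z[i]-zr[i];
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 > md) md = d2;
    }
    return md;
  };

  double e_bond = 0, e_angle = 0, e_morse = 0, e_creal = 0;
  double spring_f = 0;
  double imp_frozen_x = 0, imp_spring_x = 0;  // impulse accumulators

  // body x tracked explicitly (unwrapped; bead coordinates are not wrapped)
  double body_x = as<double>(dyn["body_x"]);
  double body_z = 0;
  if (!sup_idx.empty()) {
    for (int i : sup_idx) body_z += P.s.z[i];
    body_z /= (double)sup_idx.size();
  }

  long nsamp_max = nsteps / std::max(sample_every, 1) + 2;
  NumericMatrix trace(nsamp_max, 12);
  int nsamp = 0;
  int status = 0;

  // initial forces: reuse saved forces on restart (they carry the Langevin
  // contribution evaluated with the velocities of the original run),
  // otherwise compute them fresh
  rebuild();
  bool have_forces = dyn.containsElementNamed("forces") &&
                     !Rf_isNull(dyn["forces"]);
  if (have_forces) {
    NumericMatrix F0 = dyn["forces"];
    for (int i = 0; i < n; i++) { fx[i]=F0(i,0); fy[i]=F0(i,1); fz[i]=F0(i,2); }
  } else {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    e_bond = bond_forces(P.s, P.ff, fx.data(), fy.data(), fz.data());
    e_angle = angle_forces(P.s, P.ff, fx.data(), fy.data(), fz.data());
    pair_forces_tab(P.s, P.ff, PT, nl, fx.data(), fy.data(), fz.data(),
                    &e_morse, &e_creal);
    if (P.ff.use_coul) {
      bool have_cache = dyn.containsElementNamed("recip_cache") &&
                        !Rf_isNull(dyn["recip_cache"]);
      if (!have_cache) {
        e_recip_cache = recip_forces(P.s, P.ff, P.qidx, fkx.data(), fky.data(),
                                     fkz.data(), &e_slab_cache);
      }
      for (int i : P.qidx) { fx[i]+=fkx[i]; fy[i]+=fky[i]; fz[i]+=fkz[i]; }
    }
  }

  auto add_langevin = [&](long gstep) {
    if (gamma <= 0) return;
    double sig = std::sqrt(2.0 * gamma * kT / dt);
    for (size_t a = 0; a < mob_idx.size(); a++) {
      int i = mob_idx[a];
      double g1, g2;
      gauss_pair(seed, (uint64_t)gstep, (uint64_t)i, &g1, &g2);
      double sm = std::sqrt(m[i]) * sig;
      fy[i] += -m[i] * gamma * vy[i] + sm * g1;
      fz[i] += -m[i] * gamma * vz[i] + sm * g2;
    }
  };

  auto body_force = [&](double tnow, double *Fbx, double *Fby, double *Fbz) {
    double sx = 0, sy = 0, sz = 0;
    for (int i : sup_idx) { sx += fx[i]; sy += fy[i]; sz += fz[i]; }
    spring_f = 0;
    if (drive_mode == 0) {
      double xstage = stage0 + v_stage * (tnow - t0);
      spring_f = k_spring * (xstage - body_x);
      sx += spring_f;
    }
    sz += load_fz;
    *Fbx = sx; *Fby = sy; *Fbz = sz;
  };

  // Langevin term for step-0 forces (saved restart forces already carry it)
  if (!have_forces) add_langevin(step0);
  double Fbx, Fby, Fbz;
  body_force(t0, &Fbx, &Fby, &Fbz);

  double tnow = t0;
  long gstep = step0;
  for (long istep = 0; istep < nsteps; istep++) {
    gstep = step0 + istep;
    // half kick
    for (int i : mob_idx) {
      vx[i] += 0.5 * dt * fx[i] / m[i];
      vy[i] += 0.5 * dt * fy[i] / m[i];
      vz[i] += 0.5 * dt * fz[i] / m[i];
    }
    if (!sup_idx.empty()) {
      if (drive_mode == 1) { bvx = v_stage; }
      else { bvx += 0.5 * dt * Fbx / Msup; }
      bvy += 0.5 * dt * Fby / Msup;
      bvz += 0.5 * dt * Fbz / Msup;
    }
    // drift
    for (int i : mob_idx) {
      P.s.x[i] += dt * vx[i];
      P.s.y[i] += dt * vy[i];
      P.s.z[i] += dt * vz[i];
    }
    if (!sup_idx.empty()) {
      for (int i : sup_idx) {
        P.s.x[i] += dt * bvx;
        P.s.y[i] += dt * bvy;
        P.s.z[i] += dt * bvz;
      }
      body_x += dt * bvx;
      body_z += dt * bvz;
    }
    tnow = t0 + (istep + 1) * dt;
    // neighbour refresh
    if (max_disp2() > 0.25 * skin * skin) rebuild();
    // forces at new positions
    {
      std::fill(fx.begin(), fx.end(), 0.0);
      std::fill(fy.begin(), fy.end(), 0.0);
      std::fill(fz.begin(), fz.end(), 0.0);
      e_bond = bond_forces(P.s, P.ff, fx.data(), fy.data(), fz.data());
      e_angle = angle_forces(P.s, P.ff, fx.data(), fy.data(), fz.data());
      pair_forces_tab(P.s, P.ff, PT, nl, fx.data(), fy.data(), fz.data(),
                      &e_morse, &e_creal);
      if (P.ff.use_coul) {
        if (kspace_every <= 1 || ((gstep + 1) % kspace_every == 0)) {
          std::fill(fkx.begin(), fkx.end(), 0.0);
          std::fill(fky.begin(), fky.end(), 0.0);
          std::fill(fkz.begin(), fkz.end(), 0.0);
          e_recip_cache = recip_forces(P.s, P.ff, P.qidx, fkx.data(),
                                       fky.data(), fkz.data(), &e_slab_cache);
        }
        for (int i : P.qidx) { fx[i]+=fkx[i]; fy[i]+=fky[i]; fz[i]+=fkz[i]; }
      }
    }
    add_langevin(gstep + 1);
    body_force(tnow, &Fbx, &Fby, &Fbz);
    // impulse bookkeeping (x only)
    {
      double froz_fx = 0;
      for (int i : froz_idx) froz_fx += fx[i];
      imp_frozen_x += froz_fx * dt;
      imp_spring_x += spring_f * dt;
    }
    // second half kick
    for (int i : mob_idx) {
      vx[i] += 0.5 * dt * fx[i] / m[i];
      vy[i] += 0.5 * dt * fy[i] / m[i];
      vz[i] += 0.5 * dt * fz[i] / m[i];
    }
    if (!sup_idx.empty()) {
      if (drive_mode == 1) { bvx = v_stage; }
      else { bvx += 0.5 * dt * Fbx / Msup; }
      bvy += 0.5 * dt * Fby / Msup;
      bvz += 0.5 * dt * Fbz / Msup;
    }
    // sampling
    if ((istep + 1) % sample_every == 0 || istep == nsteps - 1) {
      double ke = 0, ke_yz = 0;
      for (int i : mob_idx) {
        ke += 0.5 * m[i] * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
        ke_yz += 0.5 * m[i] * (vy[i]*vy[i] + vz[i]*vz[i]);
      }
      if (!sup_idx.empty())
        ke += 0.5 * Msup * (bvx*bvx + bvy*bvy + bvz*bvz);
      double kB = 8.617333262e-5;
      double Tinst = mob_idx.empty() ? 0.0 :
        2.0 * ke_yz / (2.0 * (double)mob_idx.size()) / kB;
      // hooking fraction
      double h = 0;
      if (!ca_sub.empty() && !ca_sup.empty()) {
        double zsub = 0, zsup = 0;
        for (int i : ca_sub) zsub += P.s.z[i];
        for (int i : ca_sup) zsup += P.s.z[i];
        zsub /= ca_sub.size(); zsup /= ca_sup.size();
        int cnt = 0;
        for (int i : ca_sub) if (P.s.z[i] > zsup + hook_dz) cnt++;
        for (int i : ca_sup) if (P.s.z[i] < zsub - hook_dz) cnt++;
        h = 100.0 * cnt / (double)(ca_sub.size() + ca_sup.size());
      }
      double U = e_bond + e_angle + e_morse + e_creal +
                 e_self_m + e_self_c +
                 e_recip_cache + e_slab_cache + u_const;
      double xstage = (drive_mode == 0) ? stage0 + v_stage * (tnow - t0) : body_x;
      double stress_mpa = (drive_mode == 0)
        ? k_spring * (xstage - body_x) / area * 160.2176634 : 0.0;
      double d_inter = body_z - sub_plane_z;
      if (nsamp < nsamp_max) {
        trace(nsamp, 0) = tnow;
        trace(nsamp, 1) = xstage;
        trace(nsamp, 2) = body_x;
        trace(nsamp, 3) = stress_mpa;
        trace(nsamp, 4) = U;
        trace(nsamp, 5) = h;
        trace(nsamp, 6) = d_inter;
        trace(nsamp, 7) = Tinst;
        trace(nsamp, 8) = ke;
        trace(nsamp, 9) = bvz;
        trace(nsamp, 10) = e_recip_cache + e_slab_cache;
        trace(nsamp, 11) = (double)(gstep + 1);
        nsamp++;
      }
      if (!std::isfinite(U) || !std::isfinite(body_x)) { status = 1; break; }
    }
  }

  NumericMatrix Xout(n, 3), Vout(n, 3), Fout(n, 3);
  for (int i = 0; i < n; i++) {
    Xout(i,0)=P.s.x[i]; Xout(i,1)=P.s.y[i]; Xout(i,2)=P.s.z[i];
    Vout(i,0)=vx[i]; Vout(i,1)=vy[i]; Vout(i,2)=vz[i];
    Fout(i,0)=fx[i]; Fout(i,1)=fy[i]; Fout(i,2)=fz[i];
  }
  NumericMatrix FKout(n, 3);
  for (int i = 0; i < n; i++) {
    FKout(i,0)=fkx[i]; FKout(i,1)=fky[i]; FKout(i,2)=fkz[i];
  }
  return List::create(
    _["positions"] = Xout, _["velocities"] = Vout, _["forces"] = Fout,
    _["body_vel"] = NumericVector::create(bvx, bvy, bvz),
    _["body_x"] = body_x,
    _["stage_final"] = stage0 + v_stage * (tnow - t0),
    _["time"] = tnow, _["step"] = (double)(gstep + 1),
    _["trace"] = trace, _["nsamp"] = nsamp,
    _["status"] = status,
    _["imp_frozen_x"] = imp_frozen_x, _["imp_spring_x"] = imp_spring_x,
    _["recip_cache"] = List::create(
        _["forces"] = FKout, _["e_recip"] = e_recip_cache,
        _["e_slab"] = e_slab_cache));
}
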