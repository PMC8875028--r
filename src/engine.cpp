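// Metropolis engine for the two-chain (vesicle ring + linear polymer)
// bead-spring system in open 2D space.
//
// Energy model: FENE bonds, intra-chain Morse excluded volume (non-bonded
// pairs, truncated unshifted), polymer-only bending penalty kappa*(1+cos
// theta), inter-chain Lennard-Jones attraction of well depth eps_vp at
// r = lj_rm (truncated unshifted).  All distances in units of l_max,
// energies in kBT.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

#ifdef __GNUC__
#define RESTRICT __restrict__
#else
#define RESTRICT
#endif

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ with splitmix64 seeding.  Self-contained so that runs and
// replicas are bit-reproducible independently of R's global RNG state.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;   s[3] = rotl(s[3], 45);
    return r;
  }

  // uniform on [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform integer on {0, ..., n-1}; n is small here so the scaled-double
  // method is adequate and fast
  inline int below(int n) {
    int k = (int)(unif() * n);
    return k < n ? k : n - 1;
  }
};

// [[Rcpp::export]]
SEXP cpp_rng_new(double seed) {
  Xoshiro* r = new Xoshiro();
  r->seed((uint64_t)seed);
  XPtr<Xoshiro> p(r, true);
  return p;
}

// state as 8 x uint32 (lo/hi per word), serializable as R integers
// [[Rcpp::export]]
NumericVector cpp_rng_state(SEXP ptr) {
  XPtr<Xoshiro> r(ptr);
  NumericVector out(8);
  for (int i = 0; i < 4; ++i) {
    out[2 * i]     = (double)(uint32_t)(r->s[i] & 0xFFFFFFFFULL);
    out[2 * i + 1] = (double)(uint32_t)(r->s[i] >> 32);
  }
  return out;
}

// [[Rcpp::export]]
SEXP cpp_rng_restore(NumericVector state) {
  if (state.size() != 8) stop("rng state must have 8 words");
  Xoshiro* r = new Xoshiro();
  for (int i = 0; i < 4; ++i) {
    r->s[i] = ((uint64_t)(uint32_t)state[2 * i + 1] << 32) |
              (uint64_t)(uint32_t)state[2 * i];
  }
  XPtr<Xoshiro> p(r, true);
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_runif(SEXP ptr, int n, double lo, double hi) {
  XPtr<Xoshiro> r(ptr);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = lo + (hi - lo) * r->unif();
  return out;
}

// splitmix-based replica seed derivation; result in [0, 2^31)
// [[Rcpp::export]]
double cpp_derive_seed(double base_seed, double index) {
  uint64_t x = (uint64_t)base_seed ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(index + 1));
  uint64_t z = Xoshiro::splitmix(x);
  return (double)(z % 2147483648ULL);
}

// ---------------------------------------------------------------------------
// Model parameters
// ---------------------------------------------------------------------------

struct Params {
  double k, l0, lmin, lmax, r0;
  double alpha, rmin, meps, mcut, mcut2;
  double kappa, epsvp, rm, rm2, ljcut, ljcut2;
  double kBT, maxd;
  bool minter;   // Morse excluded volume also acts between the chains
};

static Params get_params(const List& pl) {
  Params P;
  P.k     = as<double>(pl["fene_k"]);
  P.l0    = as<double>(pl["l0"]);
  P.lmin  = as<double>(pl["l_min"]);
  P.lmax  = as<double>(pl["l_max"]);
  P.r0    = as<double>(pl["r0"]);
  P.alpha = as<double>(pl["morse_alpha"]);
  P.rmin  = as<double>(pl["morse_rmin"]);
  P.meps  = as<double>(pl["morse_eps"]);
  P.mcut  = as<double>(pl["morse_cutoff"]);
  P.kappa = as<double>(pl["kappa"]);
  P.epsvp = as<double>(pl["eps_vp"]);
  P.rm    = as<double>(pl["lj_rm"]);
  P.ljcut = as<double>(pl["lj_cutoff"]);
  P.kBT   = as<double>(pl["kBT"]);
  P.maxd  = as<double>(pl["max_disp"]);
  P.minter = as<double>(pl["morse_inter"]) != 0.0;
  P.mcut2  = P.mcut * P.mcut;
  P.rm2    = P.rm * P.rm;
  P.ljcut2 = P.ljcut * P.ljcut;
  return P;
}

// ---------------------------------------------------------------------------
// Potentials (shared by full and incremental paths)
// ---------------------------------------------------------------------------

static inline double fene_u(double l, const Params& P) {
  if (l <= P.lmin || l >= P.lmax) return R_PosInf;
  const double x = (l - P.l0) / P.r0;
  return -0.5 * P.k * P.r0 * P.r0 * std::log(1.0 - x * x);
}

static inline double morse_u(double r, const Params& P) {
  if (r > P.mcut) return 0.0;
  const double e = std::exp(-P.alpha * (r - P.rmin));
  return P.meps * e * (e - 2.0);
}

// from squared distance; avoids sqrt entirely
static inline double lj_u2(double r2, const Params& P) {
  if (r2 > P.ljcut2) return 0.0;
  const double u = P.rm2 / r2;
  const double u3 = u * u * u;
  return P.epsvp * u3 * (u3 - 2.0);
}

// cos of the interior angle at vertex b of the triple (a, b, c)
static inline double vertex_cos(double ax, double ay, double bx, double by,
                                double cx, double cy) {
  const double ux = ax - bx, uy = ay - by;
  const double wx = cx - bx, wy = cy - by;
  const double nn = (ux * ux + uy * uy) * (wx * wx + wy * wy);
  return (ux * wx + uy * wy) / std::sqrt(nn);
}

static inline double bend_u(double ax, double ay, double bx, double by,
                            double cx, double cy, const Params& P) {
  return P.kappa * (1.0 + vertex_cos(ax, ay, bx, by, cx, cy));
}

// ---------------------------------------------------------------------------
// Full energy
// terms: 0 fene_v 1 fene_p 2 morse_v 3 morse_p 4 bend_p 5 lj 6 morse_inter 7 total
// ---------------------------------------------------------------------------

static void total_energy_impl(const std::vector<double>& vx, const std::vector<double>& vy,
                              const std::vector<double>& px, const std::vector<double>& py,
                              const Params& P, double out[8]) {
  const int nv = (int)vx.size(), np = (int)px.size();
  for (int t = 0; t < 8; ++t) out[t] = 0.0;

  // FENE: vesicle ring has nv bonds (closure included), polymer np-1 bonds
  for (int i = 0; i < nv; ++i) {
    const int j = (i + 1) % nv;
    const double dx = vx[j] - vx[i], dy = vy[j] - vy[i];
    out[0] += fene_u(std::sqrt(dx * dx + dy * dy), P);
  }
  for (int i = 0; i + 1 < np; ++i) {
    const double dx = px[i + 1] - px[i], dy = py[i + 1] - py[i];
    out[1] += fene_u(std::sqrt(dx * dx + dy * dy), P);
  }

  // Morse: intra-chain non-bonded pairs (ring closure pair counts as bonded)
  for (int i = 0; i < nv; ++i)
    for (int j = i + 2; j < nv; ++j) {
      if (i == 0 && j == nv - 1) continue;
      const double dx = vx[j] - vx[i], dy = vy[j] - vy[i];
      const double r2 = dx * dx + dy * dy;
      if (r2 <= P.mcut2) out[2] += morse_u(std::sqrt(r2), P);
    }
  for (int i = 0; i < np; ++i)
    for (int j = i + 2; j < np; ++j) {
      const double dx = px[j] - px[i], dy = py[j] - py[i];
      const double r2 = dx * dx + dy * dy;
      if (r2 <= P.mcut2) out[3] += morse_u(std::sqrt(r2), P);
    }

  // bending: polymer interior vertices only (the vesicle is soft)
  for (int i = 1; i + 1 < np; ++i)
    out[4] += bend_u(px[i - 1], py[i - 1], px[i], py[i], px[i + 1], py[i + 1], P);

  // inter-chain: LJ always, Morse when enabled
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < np; ++j) {
      const double dx = px[j] - vx[i], dy = py[j] - vy[i];
      const double r2 = dx * dx + dy * dy;
      out[5] += lj_u2(r2, P);
      if (P.minter && r2 <= P.mcut2) out[6] += morse_u(std::sqrt(r2), P);
    }

  out[7] = out[0] + out[1] + out[2] + out[3] + out[4] + out[5] + out[6];
}

// [[Rcpp::export]]
NumericVector cpp_total_energy(NumericMatrix ves, NumericMatrix pol, List paramsL) {
  const Params P = get_params(paramsL);
  const int nv = ves.nrow(), np = pol.nrow();
  std::vector<double> vx(nv), vy(nv), px(np), py(np);
  for (int i = 0; i < nv; ++i) { vx[i] = ves(i, 0); vy[i] = ves(i, 1); }
  for (int i = 0; i < np; ++i) { px[i] = pol(i, 0); py[i] = pol(i, 1); }
  double out[8];
  total_energy_impl(vx, vy, px, py, P, out);
  NumericVector res = NumericVector::create(
    _["fene_vesicle"] = out[0], _["fene_polymer"] = out[1],
    _["morse_vesicle"] = out[2], _["morse_polymer"] = out[3],
    _["bend_polymer"] = out[4], _["lj_inter"] = out[5],
    _["morse_inter"] = out[6], _["total"] = out[7]);
  return res;
}

// ---------------------------------------------------------------------------
// Incremental energy difference for a single-bead displacement
// ---------------------------------------------------------------------------

static double local_delta_impl(const std::vector<double>& vx, const std::vector<double>& vy,
                               const std::vector<double>& px, const std::vector<double>& py,
                               const Params& P, int chain, int i,
                               double nx, double ny) {
  const int nv = (int)vx.size(), np = (int)px.size();
  double d = 0.0;

  if (chain == 0) {                       // vesicle bead
    const double ox = vx[i], oy = vy[i];
    const int jm = (i + nv - 1) % nv, jp = (i + 1) % nv;

    // two ring bonds
    for (int pass = 0; pass < 2; ++pass) {
      const int j = pass == 0 ? jm : jp;
      const double dxn = vx[j] - nx, dyn = vy[j] - ny;
      const double ln = std::sqrt(dxn * dxn + dyn * dyn);
      if (ln <= P.lmin || ln >= P.lmax) return R_PosInf;
      const double dxo = vx[j] - ox, dyo = vy[j] - oy;
      d += fene_u(ln, P) - fene_u(std::sqrt(dxo * dxo + dyo * dyo), P);
    }

    // Morse against same-chain non-bonded beads
    for (int j = 0; j < nv; ++j) {
      if (j == i || j == jm || j == jp) continue;
      const double dxo = vx[j] - ox, dyo = vy[j] - oy;
      const double dxn = vx[j] - nx, dyn = vy[j] - ny;
      const double r2o = dxo * dxo + dyo * dyo;
      const double r2n = dxn * dxn + dyn * dyn;
      if (r2n <= P.mcut2) d += morse_u(std::sqrt(r2n), P);
      if (r2o <= P.mcut2) d -= morse_u(std::sqrt(r2o), P);
    }

    // LJ (+ optional Morse) against the polymer
    for (int j = 0; j < np; ++j) {
      const double dxo = px[j] - ox, dyo = py[j] - oy;
      const double dxn = px[j] - nx, dyn = py[j] - ny;
      const double r2o = dxo * dxo + dyo * dyo;
      const double r2n = dxn * dxn + dyn * dyn;
      d += lj_u2(r2n, P) - lj_u2(r2o, P);
      if (P.minter) {
        if (r2n <= P.mcut2) d += morse_u(std::sqrt(r2n), P);
        if (r2o <= P.mcut2) d -= morse_u(std::sqrt(r2o), P);
      }
    }
    return d;
  }

  // polymer bead
  const double ox = px[i], oy = py[i];

  // bonds to existing neighbours
  if (i > 0) {
    const double dxn = px[i - 1] - nx, dyn = py[i - 1] - ny;
    const double ln = std::sqrt(dxn * dxn + dyn * dyn);
    if (ln <= P.lmin || ln >= P.lmax) return R_PosInf;
    const double dxo = px[i - 1] - ox, dyo = py[i - 1] - oy;
    d += fene_u(ln, P) - fene_u(std::sqrt(dxo * dxo + dyo * dyo), P);
  }
  if (i + 1 < np) {
    const double dxn = px[i + 1] - nx, dyn = py[i + 1] - ny;
    const double ln = std::sqrt(dxn * dxn + dyn * dyn);
    if (ln <= P.lmin || ln >= P.lmax) return R_PosInf;
    const double dxo = px[i + 1] - ox, dyo = py[i + 1] - oy;
    d += fene_u(ln, P) - fene_u(std::sqrt(dxo * dxo + dyo * dyo), P);
  }

  // bending terms at the vertices touching bead i
  if (P.kappa != 0.0) {
    for (int v = i - 1; v <= i + 1; ++v) {
      if (v < 1 || v + 1 >= np) continue;
      double ax = px[v - 1], ay = py[v - 1];
      double bx = px[v],     by = py[v];
      double cx = px[v + 1], cy = py[v + 1];
      d -= bend_u(ax, ay, bx, by, cx, cy, P);
      if (v - 1 == i) { ax = nx; ay = ny; }
      if (v == i)     { bx = nx; by = ny; }
      if (v + 1 == i) { cx = nx; cy = ny; }
      d += bend_u(ax, ay, bx, by, cx, cy, P);
    }
  }

  // Morse against same-chain non-bonded beads
  for (int j = 0; j < np; ++j) {
    if (j >= i - 1 && j <= i + 1) continue;
    const double dxo = px[j] - ox, dyo = py[j] - oy;
    const double dxn = px[j] - nx, dyn = py[j] - ny;
    const double r2o = dxo * dxo + dyo * dyo;
    const double r2n = dxn * dxn + dyn * dyn;
    if (r2n <= P.mcut2) d += morse_u(std::sqrt(r2n), P);
    if (r2o <= P.mcut2) d -= morse_u(std::sqrt(r2o), P);
  }

  // LJ (+ optional Morse) against the vesicle
  for (int j = 0; j < nv; ++j) {
    const double dxo = vx[j] - ox, dyo = vy[j] - oy;
    const double dxn = vx[j] - nx, dyn = vy[j] - ny;
    const double r2o = dxo * dxo + dyo * dyo;
    const double r2n = dxn * dxn + dyn * dyn;
    d += lj_u2(r2n, P) - lj_u2(r2o, P);
    if (P.minter) {
      if (r2n <= P.mcut2) d += morse_u(std::sqrt(r2n), P);
      if (r2o <= P.mcut2) d -= morse_u(std::sqrt(r2o), P);
    }
  }
  return d;
}

// [[Rcpp::export]]
double cpp_local_delta(NumericMatrix ves, NumericMatrix pol, List paramsL,
                       int chain, int bead, double newx, double newy) {
  const Params P = get_params(paramsL);
  const int nv = ves.nrow(), np = pol.nrow();
  std::vector<double> vx(nv), vy(nv), px(np), py(np);
  for (int i = 0; i < nv; ++i) { vx[i] = ves(i, 0); vy[i] = ves(i, 1); }
  for (int i = 0; i < np; ++i) { px[i] = pol(i, 0); py[i] = pol(i, 1); }
  return local_delta_impl(vx, vy, px, py, P, chain, bead, newx, newy);
}

// ---------------------------------------------------------------------------
// Move generation / Metropolis rule
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_draw_move(SEXP ptr, int nv, int np, double maxd) {
  XPtr<Xoshiro> r(ptr);
  const int idx = r->below(nv + np);
  const int chain = idx < nv ? 0 : 1;
  const int bead  = chain == 0 ? idx : idx - nv;
  const double dx = maxd * (2.0 * r->unif() - 1.0);
  const double dy = maxd * (2.0 * r->unif() - 1.0);
  return NumericVector::create(chain, bead, dx, dy);
}

// [[Rcpp::export]]
bool cpp_metropolis(SEXP ptr, double delta_u, double kBT) {
  XPtr<Xoshiro> r(ptr);
  if (!std::isfinite(delta_u)) { r->unif(); return false; }
  if (delta_u <= 0.0) { r->unif(); return true; }
  return r->unif() < std::exp(-delta_u / kBT);
}

// ---------------------------------------------------------------------------
// MCS loops
// ---------------------------------------------------------------------------

struct Sys {
  std::vector<double> vx, vy, px, py;
  // caches of per-bond FENE and per-vertex bending energies: only the
  // moved side of each term is recomputed per trial, the old side is read
  // from here; updated on acceptance
  std::vector<double> vb_e;     // nv ring bonds, bond k joins beads k, k+1 mod nv
  std::vector<double> pb_e;     // np-1 chain bonds
  std::vector<double> bend_e;   // polymer vertices, valid 1..np-2
  // Verlet neighbour lists (cutoff + skin), rebuilt when any bead has
  // drifted more than `trigger` since the last rebuild; `trigger` is sized
  // so that drift_i + drift_j + one trial displacement stays below `skin`
  std::vector<std::vector<int>> m_nbr[2];  // same-chain Morse partners
  std::vector<std::vector<int>> l_nbr[2];  // other-chain LJ partners
  std::vector<double> refx[2], refy[2];    // positions at last rebuild
  double skin, trigger2;
  int nv, np;
};

static void load_sys(Sys& S, const NumericMatrix& ves, const NumericMatrix& pol) {
  S.nv = ves.nrow(); S.np = pol.nrow();
  S.vx.resize(S.nv); S.vy.resize(S.nv);
  S.px.resize(S.np); S.py.resize(S.np);
  for (int i = 0; i < S.nv; ++i) { S.vx[i] = ves(i, 0); S.vy[i] = ves(i, 1); }
  for (int i = 0; i < S.np; ++i) { S.px[i] = pol(i, 0); S.py[i] = pol(i, 1); }
}

// are beads i, j of a chain bonded (adjacent, incl. the ring closure)?
static inline bool bonded(int i, int j, int n, bool ring) {
  const int d = i > j ? i - j : j - i;
  if (d == 1) return true;
  return ring && d == n - 1;
}

static void rebuild_lists(Sys& S, const Params& P) {
  const double rm2 = (P.mcut + S.skin) * (P.mcut + S.skin);
  const double rl2 = (P.ljcut + S.skin) * (P.ljcut + S.skin);
  const double* xs[2] = { S.vx.data(), S.px.data() };
  const double* ys[2] = { S.vy.data(), S.py.data() };
  const int ns[2] = { S.nv, S.np };
  for (int c = 0; c < 2; ++c) {
    const int n = ns[c], no = ns[1 - c];
    const bool ring = c == 0;
    S.m_nbr[c].resize(n); S.l_nbr[c].resize(n);
    S.refx[c].assign(xs[c], xs[c] + n);
    S.refy[c].assign(ys[c], ys[c] + n);
    for (int i = 0; i < n; ++i) {
      std::vector<int>& mn = S.m_nbr[c][i]; mn.clear();
      for (int j = 0; j < n; ++j) {
        if (j == i || bonded(i, j, n, ring)) continue;
        const double dx = xs[c][j] - xs[c][i], dy = ys[c][j] - ys[c][i];
        if (dx * dx + dy * dy <= rm2) mn.push_back(j);
      }
      std::vector<int>& ln = S.l_nbr[c][i]; ln.clear();
      for (int j = 0; j < no; ++j) {
        const double dx = xs[1 - c][j] - xs[c][i], dy = ys[1 - c][j] - ys[c][i];
        if (dx * dx + dy * dy <= rl2) ln.push_back(j);
      }
    }
  }
}

static void init_caches_bonds(Sys& S, const Params& P) {
  S.vb_e.resize(S.nv);
  for (int k = 0; k < S.nv; ++k) {
    const int j = (k + 1) % S.nv;
    const double dx = S.vx[j] - S.vx[k], dy = S.vy[j] - S.vy[k];
    S.vb_e[k] = fene_u(std::sqrt(dx * dx + dy * dy), P);
  }
  S.pb_e.resize(S.np - 1);
  for (int k = 0; k + 1 < S.np; ++k) {
    const double dx = S.px[k + 1] - S.px[k], dy = S.py[k + 1] - S.py[k];
    S.pb_e[k] = fene_u(std::sqrt(dx * dx + dy * dy), P);
  }
  S.bend_e.assign(S.np, 0.0);
  for (int v = 1; v + 1 < S.np; ++v)
    S.bend_e[v] = bend_u(S.px[v - 1], S.py[v - 1], S.px[v], S.py[v],
                         S.px[v + 1], S.py[v + 1], P);
}

static void init_caches(Sys& S, const Params& P) {
  init_caches_bonds(S, P);
  // a listed pair stays valid while drift_i + drift_j + one trial
  // displacement (max_disp * sqrt(2)) is below the skin; the rebuild
  // trigger is sized accordingly (skin 1.0, trigger 0.3 at the default
  // max_disp = 0.25)
  const double trial = P.maxd * 1.4142135623730951;
  S.skin = trial + 1.5 > 2.0 ? trial + 1.5 : 2.0;
  const double trig = (S.skin - trial) / 2.0 - 1e-9;
  S.trigger2 = trig * trig;
  rebuild_lists(S, P);
}

// non-bonded energy difference for bead i of chain c moving (ox,oy)->(nx,ny),
// scanning only its Verlet lists
static inline double nonbonded_delta(const Sys& S, const Params& P, int c,
                                     int i, double ox, double oy,
                                     double nx, double ny) {
  const double* xs = c == 0 ? S.vx.data() : S.px.data();
  const double* ys = c == 0 ? S.vy.data() : S.py.data();
  const double* xo = c == 0 ? S.px.data() : S.vx.data();
  const double* yo = c == 0 ? S.py.data() : S.vy.data();
  double d = 0.0;

  const std::vector<int>& mn = S.m_nbr[c][i];
  for (size_t t = 0; t < mn.size(); ++t) {
    const int j = mn[t];
    const double aox = xs[j] - ox, aoy = ys[j] - oy;
    const double anx = xs[j] - nx, any_ = ys[j] - ny;
    const double r2o = aox * aox + aoy * aoy;
    const double r2n = anx * anx + any_ * any_;
    if (r2n <= P.mcut2) d += morse_u(std::sqrt(r2n), P);
    if (r2o <= P.mcut2) d -= morse_u(std::sqrt(r2o), P);
  }
  const std::vector<int>& ln = S.l_nbr[c][i];
  for (size_t t = 0; t < ln.size(); ++t) {
    const int j = ln[t];
    const double aox = xo[j] - ox, aoy = yo[j] - oy;
    const double anx = xo[j] - nx, any_ = yo[j] - ny;
    const double r2o = aox * aox + aoy * aoy;
    const double r2n = anx * anx + any_ * any_;
    if (r2n <= P.ljcut2) d += lj_u2(r2n, P);
    if (r2o <= P.ljcut2) d -= lj_u2(r2o, P);
    if (P.minter) {
      if (r2n <= P.mcut2) d += morse_u(std::sqrt(r2n), P);
      if (r2o <= P.mcut2) d -= morse_u(std::sqrt(r2o), P);
    }
  }
  return d;
}

// one MCS = (nv + np) attempted single-bead displacements
static long long do_mcs(Sys& S, const Params& P, Xoshiro& R,
                        double& running) {
  const int ntot = S.nv + S.np;
  const int nv = S.nv, np = S.np;
  long long acc = 0;

  for (int t = 0; t < ntot; ++t) {
    const int idx = R.below(ntot);
    const double dx = P.maxd * (2.0 * R.unif() - 1.0);
    const double dy = P.maxd * (2.0 * R.unif() - 1.0);

    if (idx < nv) {                       // ---- vesicle bead ----
      const int i = idx;
      const double ox = S.vx[i], oy = S.vy[i];
      const double nx = ox + dx, ny = oy + dy;
      const int jm = (i + nv - 1) % nv, jp = (i + 1) % nv;
      const int km = jm, kp = i;          // touched bond indices

      const double d1x = S.vx[jm] - nx, d1y = S.vy[jm] - ny;
      const double d2x = S.vx[jp] - nx, d2y = S.vy[jp] - ny;
      const double l1 = std::sqrt(d1x * d1x + d1y * d1y);
      const double l2 = std::sqrt(d2x * d2x + d2y * d2y);
      if (l1 <= P.lmin || l1 >= P.lmax || l2 <= P.lmin || l2 >= P.lmax) {
        R.unif(); continue;
      }
      const double fe1 = fene_u(l1, P), fe2 = fene_u(l2, P);
      double d = fe1 + fe2 - S.vb_e[km] - S.vb_e[kp];
      d += nonbonded_delta(S, P, 0, i, ox, oy, nx, ny);

      bool ok;
      if (d <= 0.0) { R.unif(); ok = true; }
      else           ok = R.unif() < std::exp(-d / P.kBT);
      if (ok) {
        S.vx[i] = nx; S.vy[i] = ny;
        S.vb_e[km] = fe1; S.vb_e[kp] = fe2;
        running += d; ++acc;
        const double ex = nx - S.refx[0][i], ey = ny - S.refy[0][i];
        if (ex * ex + ey * ey > S.trigger2) rebuild_lists(S, P);
      }
    } else {                              // ---- polymer bead ----
      const int i = idx - nv;
      const double ox = S.px[i], oy = S.py[i];
      const double nx = ox + dx, ny = oy + dy;

      double d = 0.0, fe1 = 0.0, fe2 = 0.0;
      bool bad = false;
      if (i > 0) {
        const double ax = S.px[i - 1] - nx, ay = S.py[i - 1] - ny;
        const double l = std::sqrt(ax * ax + ay * ay);
        if (l <= P.lmin || l >= P.lmax) bad = true;
        else { fe1 = fene_u(l, P); d += fe1 - S.pb_e[i - 1]; }
      }
      if (!bad && i + 1 < np) {
        const double ax = S.px[i + 1] - nx, ay = S.py[i + 1] - ny;
        const double l = std::sqrt(ax * ax + ay * ay);
        if (l <= P.lmin || l >= P.lmax) bad = true;
        else { fe2 = fene_u(l, P); d += fe2 - S.pb_e[i]; }
      }
      if (bad) { R.unif(); continue; }

      const int v0 = i - 1 < 1 ? 1 : i - 1;
      const int v1 = i + 1 > np - 2 ? np - 2 : i + 1;
      double nbend[3] = {0, 0, 0};
      if (P.kappa != 0.0) {
        for (int v = v0; v <= v1; ++v) {
          double ax = S.px[v - 1], ay = S.py[v - 1];
          double bx = S.px[v],     by = S.py[v];
          double cx = S.px[v + 1], cy = S.py[v + 1];
          if (v - 1 == i) { ax = nx; ay = ny; }
          if (v == i)     { bx = nx; by = ny; }
          if (v + 1 == i) { cx = nx; cy = ny; }
          nbend[v - v0] = bend_u(ax, ay, bx, by, cx, cy, P);
          d += nbend[v - v0] - S.bend_e[v];
        }
      }

      d += nonbonded_delta(S, P, 1, i, ox, oy, nx, ny);

      bool ok;
      if (d <= 0.0) { R.unif(); ok = true; }
      else           ok = R.unif() < std::exp(-d / P.kBT);
      if (ok) {
        S.px[i] = nx; S.py[i] = ny;
        if (i > 0) S.pb_e[i - 1] = fe1;
        if (i + 1 < np) S.pb_e[i] = fe2;
        if (P.kappa != 0.0)
          for (int v = v0; v <= v1; ++v) S.bend_e[v] = nbend[v - v0];
        running += d; ++acc;
        const double ex = nx - S.refx[1][i], ey = ny - S.refy[1][i];
        if (ex * ex + ey * ey > S.trigger2) rebuild_lists(S, P);
      }
    }
  }
  return acc;
}

// [[Rcpp::export]]
List cpp_run_mcs(NumericMatrix ves, NumericMatrix pol, List paramsL,
                 SEXP ptr, double n_mcs) {
  const Params P = get_params(paramsL);
  XPtr<Xoshiro> R(ptr);
  Sys S; load_sys(S, ves, pol);
  init_caches(S, P);
  double running = 0.0;       // accumulated accepted deltas only
  long long acc = 0;
  const long long n = (long long)n_mcs;
  for (long long m = 0; m < n; ++m) acc += do_mcs(S, P, *R, running);
  NumericMatrix vout(S.nv, 2), pout(S.np, 2);
  for (int i = 0; i < S.nv; ++i) { vout(i, 0) = S.vx[i]; vout(i, 1) = S.vy[i]; }
  for (int i = 0; i < S.np; ++i) { pout(i, 0) = S.px[i]; pout(i, 1) = S.py[i]; }
  return List::create(_["vesicle_xy"] = vout, _["polymer_xy"] = pout,
                      _["accepted"] = (double)acc,
                      _["trials"] = (double)(n * (S.nv + S.np)),
                      _["delta_sum"] = running);
}

// ---------------------------------------------------------------------------
// Observables used inside the sampling loop
// ---------------------------------------------------------------------------

static double lj_inter_only(const Sys& S, const Params& P) {
  double u = 0.0;
  for (int i = 0; i < S.nv; ++i)
    for (int j = 0; j < S.np; ++j) {
      const double dx = S.px[j] - S.vx[i], dy = S.py[j] - S.vy[i];
      u += lj_u2(dx * dx + dy * dy, P);
    }
  return u;
}

static double asphericity_of(const std::vector<double>& x, const std::vector<double>& y) {
  const int n = (int)x.size();
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sxx = 0, syy = 0, sxy = 0;
  for (int i = 0; i < n; ++i) {
    const double dx = x[i] - mx, dy = y[i] - my;
    sxx += dx * dx; syy += dy * dy; sxy += dx * dy;
  }
  sxx /= n; syy /= n; sxy /= n;
  const double tr = sxx + syy;
  const double disc = (sxx - syy) * (sxx - syy) + 4.0 * sxy * sxy;
  return disc / (tr * tr);
}

static double mean_cos_polymer(const Sys& S) {
  if (S.np < 3) return NA_REAL;
  double s = 0.0;
  for (int i = 1; i + 1 < S.np; ++i)
    s += vertex_cos(S.px[i - 1], S.py[i - 1], S.px[i], S.py[i],
                    S.px[i + 1], S.py[i + 1]);
  return s / (S.np - 2);
}

// ring tangent-tangent correlation, accumulated into crow[0..L-1]
static void tt_corr_ring(const Sys& S, bool normalized, double* crow) {
  const int L = S.nv;
  std::vector<double> tx(L), ty(L);
  for (int k = 0; k < L; ++k) {
    const int j = (k + 1) % L;
    double dx = S.vx[j] - S.vx[k], dy = S.vy[j] - S.vy[k];
    if (normalized) {
      const double l = std::sqrt(dx * dx + dy * dy);
      dx /= l; dy /= l;
    }
    tx[k] = dx; ty[k] = dy;
  }
  for (int s = 0; s < L; ++s) {
    double c = 0.0;
    for (int k = 0; k < L; ++k) {
      const int j = (k + s) % L;
      c += tx[k] * tx[j] + ty[k] * ty[j];
    }
    crow[s] = c / L;
  }
}

// ---------------------------------------------------------------------------
// Full run: equilibrate, then measure on a fixed schedule.
// Running energy is resynchronized against a full recompute every
// resync_every MCS to bound floating-point drift.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(NumericMatrix ves, NumericMatrix pol, List paramsL, SEXP ptr,
             double equil_mcs, double measure_every, int n_measurements,
             bool store_corr, bool normalize_corr, double resync_every) {
  const Params P = get_params(paramsL);
  XPtr<Xoshiro> R(ptr);
  Sys S; load_sys(S, ves, pol);
  init_caches(S, P);

  double full[8];
  total_energy_impl(S.vx, S.vy, S.px, S.py, P, full);
  if (!std::isfinite(full[7])) stop("initial conformation has infinite energy");
  double running = full[7];
  double max_drift = 0.0;

  const long long nequil = (long long)equil_mcs;
  const long long every  = (long long)measure_every;
  const long long resync = resync_every > 0 ? (long long)resync_every : 10000;
  long long acc = 0, mcs_done = 0, since_resync = 0;

  NumericMatrix rec(n_measurements, 5);
  NumericMatrix corr(store_corr ? n_measurements : 1, S.nv);
  std::vector<double> corr_mean(S.nv, 0.0), crow(S.nv);

  auto advance = [&](long long n) {
    for (long long m = 0; m < n; ++m) {
      acc += do_mcs(S, P, *R, running);
      ++mcs_done;
      if (++since_resync >= resync) {
        total_energy_impl(S.vx, S.vy, S.px, S.py, P, full);
        const double drift = std::fabs(running - full[7]);
        if (drift > max_drift) max_drift = drift;
        running = full[7];
        since_resync = 0;
      }
    }
  };

  advance(nequil);
  for (int m = 0; m < n_measurements; ++m) {
    advance(every);
    rec(m, 0) = (double)mcs_done;
    rec(m, 1) = lj_inter_only(S, P);
    rec(m, 2) = std::hypot(S.px[S.np - 1] - S.px[0], S.py[S.np - 1] - S.py[0]);
    rec(m, 3) = asphericity_of(S.vx, S.vy);
    rec(m, 4) = mean_cos_polymer(S);
    tt_corr_ring(S, normalize_corr, crow.data());
    for (int s = 0; s < S.nv; ++s) {
      corr_mean[s] += crow[s] / n_measurements;
      if (store_corr) corr(m, s) = crow[s];
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix vout(S.nv, 2), pout(S.np, 2);
  for (int i = 0; i < S.nv; ++i) { vout(i, 0) = S.vx[i]; vout(i, 1) = S.vy[i]; }
  for (int i = 0; i < S.np; ++i) { pout(i, 0) = S.px[i]; pout(i, 1) = S.py[i]; }
  colnames(rec) = CharacterVector::create("mcs", "u_vl", "r_ee",
                                          "asphericity", "mean_cos");
  return List::create(
    _["records"] = rec,
    _["tt_corr"] = store_corr ? (SEXP)corr : R_NilValue,
    _["tt_corr_mean"] = NumericVector(corr_mean.begin(), corr_mean.end()),
    _["vesicle_xy"] = vout, _["polymer_xy"] = pout,
    _["accepted"] = (double)acc,
    _["trials"] = (double)(mcs_done * (S.nv + S.np)),
    _["max_energy_drift"] = max_drift);
}
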