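// Core simulation kernels: WCA fluid in 2D with three nonequilibrium drivings
// (thermostatted channel, ergostatted obstacle flow, driven active fluid),
// plus per-bin color-current accumulation for local dissipation.
//
// All quantities are in reduced Lennard-Jones units (sigma, epsilon, m = 1).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based deterministic RNG: xoshiro256++ seeded through splitmix64.
// Normals via Box-Muller so streams are reproducible across platforms.
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  bool has_spare;
  double spare;

  static uint64_t sm64(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) : has_spare(false), spare(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = sm64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() {  // open (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// Independent per-trajectory streams derived from (base_seed, index).
static uint64_t mix_seed(uint64_t base, uint64_t idx) {
  uint64_t x = base ^ (0x632BE59BD9B4E019ULL * (idx + 1ULL));
  return Xoshiro::sm64(x);
}

// ---------------------------------------------------------------------------
// Simulation container
// ---------------------------------------------------------------------------
struct Sim {
  int N;
  std::vector<double> x, y, px, py, ax, ay, xi;
  std::vector<int> col, wall;

  // scenario parameters
  int kind;           // 0 channel, 1 obstacle, 2 active
  double Fe, beta, kspring, tau, signoise, dt;
  double Lx, Ly;
  bool periodic_y;
  bool has_obstacle;
  double oR, ocx, ocy;

  // effective (phase-dependent) driving: equilibration runs field-free
  double eFe;
  bool eActive;
  int eThermo;        // 0 walls isokinetic, 1 all isokinetic, 2 ergostat

  // WCA cutoff
  const double rc2 = std::pow(2.0, 1.0 / 3.0);  // (2^{1/6})^2

  // force buffers (conservative part: pair + tether + obstacle)
  std::vector<double> fx, fy;
  double Upair, Uteth, Uobst;

  // constraint targets
  double K0sub;       // isokinetic target (subset kinetic energy)
  double H0;          // ergostat target (total internal energy)

  // cell list (used to rebuild the Verlet pair list)
  int ncx, ncy;
  double cwx, cwy;
  std::vector<int> head, nxt;

  // Verlet neighbor list: flat (i, j) pairs within rc + skin, refreshed when
  // any particle has moved more than skin/2 since the last rebuild
  const double skin = 0.3;
  double rl2;                       // (rc + skin)^2
  std::vector<int> pairs;
  std::vector<double> xref, yref;
  bool nl_valid;

  void initFromR(const List& state, const List& par) {
    NumericVector X = state["x"], Y = state["y"],
                  PX = state["px"], PY = state["py"];
    IntegerVector C = state["c"], W = state["wall"];
    NumericVector AX = state["ax"], AY = state["ay"], XI = state["xi"];
    N = X.size();
    x.assign(X.begin(), X.end());   y.assign(Y.begin(), Y.end());
    px.assign(PX.begin(), PX.end()); py.assign(PY.begin(), PY.end());
    ax.assign(AX.begin(), AX.end()); ay.assign(AY.begin(), AY.end());
    xi.assign(XI.begin(), XI.end());
    col.assign(C.begin(), C.end()); wall.assign(W.begin(), W.end());

    kind = as<int>(par["kind"]);
    Fe = as<double>(par["Fe"]);
    beta = as<double>(par["beta"]);
    kspring = as<double>(par["k"]);
    tau = as<double>(par["tau"]);
    signoise = as<double>(par["sigma_noise"]);
    Lx = as<double>(par["Lx"]);
    Ly = as<double>(par["Ly"]);
    periodic_y = as<bool>(par["periodic_y"]);
    has_obstacle = as<bool>(par["has_obstacle"]);
    oR = as<double>(par["obstacle_R"]);
    ocx = as<double>(par["obstacle_cx"]);
    ocy = as<double>(par["obstacle_cy"]);

    fx.assign(N, 0.0); fy.assign(N, 0.0);

    double rl = std::sqrt(rc2) + skin;
    rl2 = rl * rl;
    ncx = std::max(1, (int)std::floor(Lx / rl));
    ncy = std::max(1, (int)std::floor(Ly / rl));
    cwx = Lx / ncx; cwy = Ly / ncy;
    head.assign(ncx * ncy, -1);
    nxt.assign(N, -1);
    xref.assign(N, 0.0); yref.assign(N, 0.0);
    nl_valid = false;
    pairs.reserve(16 * N);
    setDriven();
  }

  void setDriven() {
    eFe = Fe;
    eActive = (kind == 2);
    eThermo = (kind == 0) ? 0 : ((kind == 1) ? 2 : 1);
  }
  // Equilibration: field off, activity off; walls-only isokinetic for the
  // channel, all-particle isokinetic otherwise (the ergostat reduces to free
  // dynamics at Fe = 0 and would not thermalize).
  void setEquil() {
    eFe = 0.0;
    eActive = false;
    eThermo = (kind == 0) ? 0 : 1;
  }

  inline double wrapx(double v) const {
    v -= Lx * std::floor(v / Lx);
    if (v >= Lx) v -= Lx;   // guard against floor roundoff at the edge
    return v;
  }
  inline double mimx(double d) const {
    if (d >  0.5 * Lx) d -= Lx;
    if (d < -0.5 * Lx) d += Lx;
    return d;
  }
  inline double mimy(double d) const {
    if (!periodic_y) return d;
    if (d >  0.5 * Ly) d -= Ly;
    if (d < -0.5 * Ly) d += Ly;
    return d;
  }

  void buildCells() {
    std::fill(head.begin(), head.end(), -1);
    for (int i = 0; i < N; ++i) {
      int ix = (int)std::floor(wrapx(x[i]) / cwx);
      if (ix >= ncx) ix = ncx - 1;
      int iy = (int)std::floor((y[i] + 0.5 * Ly) / cwy);
      if (periodic_y) {
        iy %= ncy; if (iy < 0) iy += ncy;
      } else {
        if (iy < 0) iy = 0;
        if (iy >= ncy) iy = ncy - 1;
      }
      int c = iy * ncx + ix;
      nxt[i] = head[c];
      head[c] = i;
    }
  }

  inline void wcaPairAccum(int i, int j, std::vector<double>& gx,
                           std::vector<double>& gy, double& U) {
    if (wall[i] && wall[j]) return;  // tethered wall atoms do not interact
    double dx = mimx(x[i] - x[j]);
    double dy = mimy(y[i] - y[j]);
    double r2 = dx * dx + dy * dy;
    if (r2 >= rc2) return;
    if (r2 < 0.16)
      stop("particle overlap (r < 0.4) between particles %d and %d", i + 1, j + 1);
    double sr2 = 1.0 / r2;
    double sr6 = sr2 * sr2 * sr2;
    U += 4.0 * sr6 * (sr6 - 1.0) + 1.0;
    double fs = 24.0 * sr6 * (2.0 * sr6 - 1.0) * sr2;
    gx[i] += fs * dx; gy[i] += fs * dy;
    gx[j] -= fs * dx; gy[j] -= fs * dy;
  }

  inline void nlPush(int i, int j) {
    if (wall[i] && wall[j]) return;  // tethered wall atoms do not interact
    double dx = mimx(x[i] - x[j]);
    double dy = mimy(y[i] - y[j]);
    if (dx * dx + dy * dy < rl2) { pairs.push_back(i); pairs.push_back(j); }
  }

  void buildNeighborList() {
    pairs.clear();
    // a cell list needs >= 3 cells per periodic direction to avoid counting
    // a neighbor twice through the wrap; fall back to all pairs otherwise
    if (ncx < 3 || (periodic_y && ncy < 3)) {
      for (int i = 0; i < N; ++i)
        for (int j = i + 1; j < N; ++j)
          nlPush(i, j);
    } else {
      buildCells();
      // half-neighbor offsets (plus same cell handled with i<j chain order)
      const int offx[4] = {1, 1, 0, -1};
      const int offy[4] = {0, 1, 1, 1};
      for (int cy0 = 0; cy0 < ncy; ++cy0) {
        for (int cx0 = 0; cx0 < ncx; ++cx0) {
          int c0 = cy0 * ncx + cx0;
          for (int i = head[c0]; i >= 0; i = nxt[i])
            for (int j = nxt[i]; j >= 0; j = nxt[j])
              nlPush(i, j);
          for (int k = 0; k < 4; ++k) {
            int cx1 = cx0 + offx[k], cy1 = cy0 + offy[k];
            // x always periodic
            if (cx1 < 0) cx1 += ncx;
            if (cx1 >= ncx) cx1 -= ncx;
            if (periodic_y) {
              if (cy1 >= ncy) cy1 -= ncy;
            } else {
              if (cy1 >= ncy) continue;
            }
            // degenerate single-cell directions would double count
            if (ncx == 1 && (offx[k] != 0)) continue;
            if (ncy == 1 && (offy[k] != 0)) continue;
            int c1 = cy1 * ncx + cx1;
            if (c1 == c0) continue;
            for (int i = head[c0]; i >= 0; i = nxt[i])
              for (int j = head[c1]; j >= 0; j = nxt[j])
                nlPush(i, j);
          }
        }
      }
    }
    xref = x; yref = y;
    nl_valid = true;
  }

  bool listStale() const {
    if (!nl_valid) return true;
    double lim = 0.25 * skin * skin;  // (skin/2)^2
    for (int i = 0; i < N; ++i) {
      double dx = mimx(x[i] - xref[i]);
      double dy = mimy(y[i] - yref[i]);
      if (dx * dx + dy * dy > lim) return true;
    }
    return false;
  }

  void pairForces(std::vector<double>& gx, std::vector<double>& gy, double& U) {
    U = 0.0;
    if (listStale()) buildNeighborList();
    size_t np = pairs.size();
    for (size_t k = 0; k < np; k += 2)
      wcaPairAccum(pairs[k], pairs[k + 1], gx, gy, U);
  }

  void tetherForces(std::vector<double>& gx, std::vector<double>& gy, double& U) {
    U = 0.0;
    if (kspring <= 0) return;
    for (int i = 0; i < N; ++i) {
      if (!wall[i]) continue;
      double dx = mimx(x[i] - ax[i]);
      double dy = y[i] - ay[i];
      gx[i] -= kspring * dx;
      gy[i] -= kspring * dy;
      U += 0.5 * kspring * (dx * dx + dy * dy);
    }
  }

  void obstacleForces(std::vector<double>& gx, std::vector<double>& gy, double& U) {
    U = 0.0;
    if (!has_obstacle) return;
    for (int i = 0; i < N; ++i) {
      double dx = mimx(x[i] - ocx);
      double dy = mimy(y[i] - ocy);
      double r = std::sqrt(dx * dx + dy * dy);
      double d = r - oR;
      if (d <= 0.2)
        stop("particle %d penetrated the obstacle (surface distance %.3f)", i + 1, d);
      if (d * d >= rc2) continue;
      double sr2 = 1.0 / (d * d);
      double sr6 = sr2 * sr2 * sr2;
      U += 4.0 * sr6 * (sr6 - 1.0) + 1.0;
      double fmag = 24.0 * sr6 * (2.0 * sr6 - 1.0) / d;  // radial, outward
      gx[i] += fmag * dx / r;
      gy[i] += fmag * dy / r;
    }
  }

  // conservative forces (pair + tether + obstacle) into fx, fy
  void computeForces() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    pairForces(fx, fy, Upair);
    tetherForces(fx, fy, Uteth);
    obstacleForces(fx, fy, Uobst);
  }

  double potentialEnergy() const { return Upair + Uteth + Uobst; }

  double kineticAll() const {
    double K = 0.0;
    for (int i = 0; i < N; ++i) K += px[i] * px[i] + py[i] * py[i];
    return 0.5 * K;
  }
  double kineticSubset(bool wallsOnly) const {
    double K = 0.0;
    for (int i = 0; i < N; ++i) {
      if (wallsOnly && !wall[i]) continue;
      K += px[i] * px[i] + py[i] * py[i];
    }
    return 0.5 * K;
  }

  // Exact flow of the Gaussian isokinetic kick dp/dt = F - (p.F/p.p) p over
  // duration h with F held fixed, applied to the subset (wallsOnly or all).
  // Conserves the subset kinetic energy to machine precision.
  void isoKick(double h, const std::vector<double>& Fx,
               const std::vector<double>& Fy, bool wallsOnly) {
    double b = 0.0, twoK = 0.0, c2 = 0.0;
    for (int i = 0; i < N; ++i) {
      if (wallsOnly && !wall[i]) continue;
      b += px[i] * Fx[i] + py[i] * Fy[i];
      twoK += px[i] * px[i] + py[i] * py[i];
      c2 += Fx[i] * Fx[i] + Fy[i] * Fy[i];
    }
    if (twoK <= 0.0)
      stop("isokinetic constraint undefined: zero kinetic energy in subset");
    if (c2 < 1e-28) return;  // no force on the subset
    double om = std::sqrt(c2 / twoK);
    double ch = std::cosh(om * h), sh = std::sinh(om * h);
    double g = b / (twoK * om);
    double r = ch + g * sh;
    double q = sh / om + g * (ch - 1.0) / om;
    double inv = 1.0 / r;
    double twoKnew = 0.0;
    for (int i = 0; i < N; ++i) {
      if (wallsOnly && !wall[i]) continue;
      px[i] = (px[i] + Fx[i] * q) * inv;
      py[i] = (py[i] + Fy[i] * q) * inv;
      twoKnew += px[i] * px[i] + py[i] * py[i];
    }
    // remove residual roundoff so the constraint cannot random-walk
    double s = std::sqrt(twoK / twoKnew);
    for (int i = 0; i < N; ++i) {
      if (wallsOnly && !wall[i]) continue;
      px[i] *= s; py[i] *= s;
    }
  }

  void plainKickFluid(double h) {  // channel fluid: conservative + color field
    for (int i = 0; i < N; ++i) {
      if (wall[i]) continue;
      px[i] += h * (fx[i] + col[i] * eFe);
      py[i] += h * fy[i];
    }
  }
  void plainKickAll(double h) {   // ergostat splitting: conservative forces
    for (int i = 0; i < N; ++i) {
      px[i] += h * fx[i];
      py[i] += h * fy[i];
    }
  }

  void drift(double h) {
    for (int i = 0; i < N; ++i) {
      x[i] += h * px[i];
      if (x[i] >= Lx || x[i] < 0) x[i] = wrapx(x[i]);
      y[i] += h * py[i];
      if (periodic_y) {
        if (y[i] >= 0.5 * Ly) y[i] -= Ly;
        else if (y[i] < -0.5 * Ly) y[i] += Ly;
      } else if (std::abs(y[i]) > 0.5 * Ly) {
        stop("particle %d escaped the channel (y = %.3f)", i + 1, y[i]);
      }
    }
  }

  void ouUpdate(double h, Xoshiro& rng) {
    double e = std::exp(-h / tau);
    double amp = signoise * std::sqrt(1.0 - e * e);
    for (int i = 0; i < N; ++i)
      xi[i] = xi[i] * e + amp * rng.norm();
  }

  // field (+ active) force vectors for iso/ergostat kicks
  void fieldForce(std::vector<double>& Fx, std::vector<double>& Fy) const {
    for (int i = 0; i < N; ++i) {
      Fx[i] = col[i] * eFe + (eActive ? xi[i] : 0.0);
      Fy[i] = 0.0;
    }
  }
  void totalForceActive(std::vector<double>& Fx, std::vector<double>& Fy) const {
    for (int i = 0; i < N; ++i) {
      Fx[i] = fx[i] + col[i] * eFe + (eActive ? xi[i] : 0.0);
      Fy[i] = fy[i];
    }
  }

  // instantaneous thermostat multiplier (diagnostic log)
  double alphaNow() const {
    double num = 0.0, den = 0.0;
    if (eThermo == 0) {
      for (int i = 0; i < N; ++i) {
        if (!wall[i]) continue;
        num += px[i] * fx[i] + py[i] * fy[i];
        den += px[i] * px[i] + py[i] * py[i];
      }
    } else if (eThermo == 2) {
      for (int i = 0; i < N; ++i) {
        num += col[i] * eFe * px[i];
        den += px[i] * px[i] + py[i] * py[i];
      }
    } else {
      for (int i = 0; i < N; ++i) {
        num += px[i] * (fx[i] + col[i] * eFe + (eActive ? xi[i] : 0.0)) + py[i] * fy[i];
        den += px[i] * px[i] + py[i] * py[i];
      }
    }
    return den > 0 ? num / den : 0.0;
  }

  void captureTargets() {
    if (eThermo == 0) K0sub = kineticSubset(true);
    else K0sub = kineticAll();
    H0 = kineticAll() + potentialEnergy();
  }

  // one full timestep of the scenario's equations of motion
  void stepOnce(double h, Xoshiro& rng,
                std::vector<double>& bFx, std::vector<double>& bFy) {
    if (eThermo == 0) {
      // channel: walls-only Gaussian isokinetic; fluid Hamiltonian + field
      isoKick(0.5 * h, fx, fy, true);   // wall force = pair + tether (c=0)
      plainKickFluid(0.5 * h);
      drift(h);
      computeForces();
      isoKick(0.5 * h, fx, fy, true);
      plainKickFluid(0.5 * h);
      double Kw = kineticSubset(true);
      double s = std::sqrt(K0sub / Kw);
      for (int i = 0; i < N; ++i)
        if (wall[i]) { px[i] *= s; py[i] *= s; }
    } else if (eThermo == 2) {
      // ergostat: symmetric split C(h/2) D(h/2) A(h) D(h/2) C(h/2) + exact
      // projection onto the H = H0 shell
      fieldForce(bFx, bFy);
      plainKickAll(0.5 * h);
      isoKick(0.5 * h, bFx, bFy, false);
      drift(h);
      computeForces();
      isoKick(0.5 * h, bFx, bFy, false);
      plainKickAll(0.5 * h);
      double Kt = H0 - potentialEnergy();
      if (Kt <= 0.0) stop("ergostat projection failed: target kinetic energy <= 0");
      double s = std::sqrt(Kt / kineticAll());
      for (int i = 0; i < N; ++i) { px[i] *= s; py[i] *= s; }
    } else {
      // active (or all-fluid isokinetic equilibration): isokinetic kick with
      // the full force, exact OU refresh of the propulsion between halves
      totalForceActive(bFx, bFy);
      isoKick(0.5 * h, bFx, bFy, false);
      drift(h);
      if (eActive) ouUpdate(h, rng);
      computeForces();
      totalForceActive(bFx, bFy);
      isoKick(0.5 * h, bFx, bFy, false);
      double K = kineticAll();
      double s = std::sqrt(K0sub / K);
      for (int i = 0; i < N; ++i) { px[i] *= s; py[i] *= s; }
    }
  }

  double constraintDrift() const {
    if (eThermo == 2) {
      double H = kineticAll() + potentialEnergy();
      return std::abs(H - H0) / std::max(1.0, std::abs(H0));
    }
    double K = kineticSubset(eThermo == 0);
    return std::abs(K - K0sub) / std::max(1.0, K0sub);
  }

  // Maxwell-Boltzmann momenta at temperature T = 1/beta
  void drawMomenta(Xoshiro& rng) {
    double sd = std::sqrt(1.0 / beta);
    for (int i = 0; i < N; ++i) {
      px[i] = sd * rng.norm();
      py[i] = sd * rng.norm();
    }
  }
  void drawXi(Xoshiro& rng) {
    for (int i = 0; i < N; ++i) xi[i] = signoise * rng.norm();
  }

  List stateAsList() const {
    return List::create(
      _["x"] = NumericVector(x.begin(), x.end()),
      _["y"] = NumericVector(y.begin(), y.end()),
      _["px"] = NumericVector(px.begin(), px.end()),
      _["py"] = NumericVector(py.begin(), py.end()),
      _["c"] = IntegerVector(col.begin(), col.end()),
      _["wall"] = IntegerVector(wall.begin(), wall.end()),
      _["ax"] = NumericVector(ax.begin(), ax.end()),
      _["ay"] = NumericVector(ay.begin(), ay.end()),
      _["xi"] = NumericVector(xi.begin(), xi.end()));
  }
};

// per-step sampling of currents on a fine x-grid (trapezoidal accumulation)
struct FineAccum {
  int nf;
  double w, Lx, dt;
  std::vector<double> jprev, jcur, aprev, acur, nprev, ncur;
  std::vector<double> J, A, Nav;   // integrals
  double jg_prev, ag_prev;
  double Jg, Ag;
  bool first;

  void init(int n_fine, double Lx_, double dt_) {
    nf = n_fine; Lx = Lx_; w = Lx_ / n_fine; dt = dt_;
    jprev.assign(nf, 0.0); jcur.assign(nf, 0.0);
    aprev.assign(nf, 0.0); acur.assign(nf, 0.0);
    nprev.assign(nf, 0.0); ncur.assign(nf, 0.0);
    J.assign(nf, 0.0); A.assign(nf, 0.0); Nav.assign(nf, 0.0);
    Jg = Ag = 0.0; jg_prev = ag_prev = 0.0;
    first = true;
  }
  // returns global instantaneous color current
  double sample(const Sim& s, bool active) {
    std::fill(jcur.begin(), jcur.end(), 0.0);
    std::fill(ncur.begin(), ncur.end(), 0.0);
    if (active) std::fill(acur.begin(), acur.end(), 0.0);
    double jg = 0.0, ag = 0.0;
    for (int i = 0; i < s.N; ++i) {
      if (s.wall[i]) continue;
      double xw = s.x[i];
      int ic = (int)std::floor(xw / w);
      if (ic >= nf) ic = nf - 1;
      if (ic < 0) ic = 0;
      double jc = s.col[i] * s.px[i];
      jcur[ic] += jc; jg += jc;
      ncur[ic] += 1.0;
      if (active) {
        double ac = s.xi[i] * s.px[i];
        acur[ic] += ac; ag += ac;
      }
    }
    if (!std::isfinite(jg)) stop("non-finite current: integration diverged");
    if (!first) {
      for (int c = 0; c < nf; ++c) {
        J[c] += 0.5 * dt * (jprev[c] + jcur[c]);
        Nav[c] += 0.5 * dt * (nprev[c] + ncur[c]);
      }
      Jg += 0.5 * dt * (jg_prev + jg);
      if (active) {
        for (int c = 0; c < nf; ++c) A[c] += 0.5 * dt * (aprev[c] + acur[c]);
        Ag += 0.5 * dt * (ag_prev + ag);
      }
    }
    jprev.swap(jcur); nprev.swap(ncur);
    if (active) aprev.swap(acur);
    jg_prev = jg; ag_prev = ag;
    first = false;
    return jg;
  }
};

// optional 2D-grid accumulation (for dissipation / entropy-production maps)
struct GridAccum {
  int nx, ny;
  double wx, wy, Ly, dt;
  bool on;
  std::vector<double> jprev, jcur, nprev, ncur, J, Nav;
  bool first;
  void init(int nx_, int ny_, double Lx_, double Ly_, double dt_) {
    on = (nx_ > 0 && ny_ > 0);
    if (!on) return;
    nx = nx_; ny = ny_; wx = Lx_ / nx; wy = Ly_ / ny; Ly = Ly_; dt = dt_;
    int m = nx * ny;
    jprev.assign(m, 0.0); jcur.assign(m, 0.0);
    nprev.assign(m, 0.0); ncur.assign(m, 0.0);
    J.assign(m, 0.0); Nav.assign(m, 0.0);
    first = true;
  }
  void sample(const Sim& s) {
    if (!on) return;
    std::fill(jcur.begin(), jcur.end(), 0.0);
    std::fill(ncur.begin(), ncur.end(), 0.0);
    for (int i = 0; i < s.N; ++i) {
      if (s.wall[i]) continue;
      int ix = (int)std::floor(s.x[i] / wx);
      if (ix >= nx) ix = nx - 1; if (ix < 0) ix = 0;
      int iy = (int)std::floor((s.y[i] + 0.5 * Ly) / wy);
      if (iy >= ny) iy = ny - 1; if (iy < 0) iy = 0;
      int c = iy * nx + ix;
      jcur[c] += s.col[i] * s.px[i];
      ncur[c] += 1.0;
    }
    if (!first) {
      int m = nx * ny;
      for (int c = 0; c < m; ++c) {
        J[c] += 0.5 * dt * (jprev[c] + jcur[c]);
        Nav[c] += 0.5 * dt * (nprev[c] + ncur[c]);
      }
    }
    jprev.swap(jcur); nprev.swap(ncur);
    first = false;
  }
};

// ---------------------------------------------------------------------------
// Exported kernels
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_eval_forces(List state, List par) {
  Sim s; s.initFromR(state, par);
  std::vector<double> gx(s.N, 0.0), gy(s.N, 0.0);
  double Up = 0.0, Ut = 0.0, Uo = 0.0;
  s.pairForces(gx, gy, Up);
  NumericMatrix fpair(s.N, 2);
  for (int i = 0; i < s.N; ++i) { fpair(i, 0) = gx[i]; fpair(i, 1) = gy[i]; }

  std::fill(gx.begin(), gx.end(), 0.0); std::fill(gy.begin(), gy.end(), 0.0);
  s.tetherForces(gx, gy, Ut);
  NumericMatrix fteth(s.N, 2);
  for (int i = 0; i < s.N; ++i) { fteth(i, 0) = gx[i]; fteth(i, 1) = gy[i]; }

  std::fill(gx.begin(), gx.end(), 0.0); std::fill(gy.begin(), gy.end(), 0.0);
  s.obstacleForces(gx, gy, Uo);
  NumericMatrix fobst(s.N, 2);
  for (int i = 0; i < s.N; ++i) { fobst(i, 0) = gx[i]; fobst(i, 1) = gy[i]; }

  NumericMatrix fcol(s.N, 2);
  for (int i = 0; i < s.N; ++i) { fcol(i, 0) = s.col[i] * s.Fe; fcol(i, 1) = 0.0; }

  return List::create(
    _["pair_forces"] = fpair, _["pair_energy"] = Up,
    _["tether_forces"] = fteth, _["tether_energy"] = Ut,
    _["obstacle_forces"] = fobst, _["obstacle_energy"] = Uo,
    _["color_forces"] = fcol);
}

// [[Rcpp::export]]
List cpp_run_trajectory(List state, List par, int n_steps, double dt,
                        int stride, NumericVector part_edges, int n_fine,
                        double seed) {
  Sim s; s.initFromR(state, par);
  s.dt = dt;
  s.setDriven();
  Xoshiro rng(mix_seed((uint64_t)seed, 0));
  std::vector<double> bFx(s.N), bFy(s.N);

  s.computeForces();
  s.captureTargets();

  bool active = s.eActive;
  FineAccum fa; fa.init(n_fine, s.Lx, dt);

  int nb = std::max(1, (int)part_edges.size() - 1);
  int n_out = n_steps / std::max(1, stride) + 1;
  NumericVector t_out(n_out), jg_out(n_out), ag_out(n_out),
                K_out(n_out), H_out(n_out), alpha_out(n_out);
  NumericMatrix jbin_out(n_out, nb), abin_out(n_out, nb);

  double maxdrift = 0.0;
  int iout = 0;
  auto record_state = [&](int stepidx) {
    double jg = fa.sample(s, active);
    if (stepidx % std::max(1, stride) == 0 && iout < n_out) {
      t_out[iout] = stepidx * dt;
      jg_out[iout] = jg;
      K_out[iout] = (s.eThermo == 0) ? s.kineticSubset(true) : s.kineticAll();
      H_out[iout] = s.kineticAll() + s.potentialEnergy();
      alpha_out[iout] = s.alphaNow();
      double agl = 0.0;
      for (int b = 0; b < nb; ++b) { jbin_out(iout, b) = 0.0; abin_out(iout, b) = 0.0; }
      if (part_edges.size() >= 2) {
        for (int i = 0; i < s.N; ++i) {
          if (s.wall[i]) continue;
          double xw = s.x[i];
          int b = (int)(std::upper_bound(part_edges.begin(), part_edges.end(), xw)
                        - part_edges.begin()) - 1;
          if (b < 0) b = 0;
          if (b >= nb) b = nb - 1;
          jbin_out(iout, b) += s.col[i] * s.px[i];
          if (active) abin_out(iout, b) += s.xi[i] * s.px[i];
        }
      }
      if (active) for (int i = 0; i < s.N; ++i)
        if (!s.wall[i]) agl += s.xi[i] * s.px[i];
      ag_out[iout] = agl;
      ++iout;
    }
  };

  record_state(0);
  for (int st = 1; st <= n_steps; ++st) {
    s.stepOnce(dt, rng, bFx, bFy);
    double d = s.constraintDrift();
    if (d > maxdrift) maxdrift = d;
    record_state(st);
  }

  return List::create(
    _["t"] = t_out,
    _["j_global"] = jg_out,
    _["a_global"] = ag_out,
    _["j_bins"] = jbin_out,
    _["a_bins"] = abin_out,
    _["K_constrained"] = K_out,
    _["H"] = H_out,
    _["alpha"] = alpha_out,
    _["J_fine"] = NumericVector(fa.J.begin(), fa.J.end()),
    _["A_fine"] = NumericVector(fa.A.begin(), fa.A.end()),
    _["navg_fine"] = NumericVector(fa.Nav.begin(), fa.Nav.end()),
    _["J_global"] = fa.Jg,
    _["A_global"] = fa.Ag,
    _["K0"] = s.K0sub,
    _["H0"] = s.H0,
    _["max_constraint_drift"] = maxdrift,
    _["final_state"] = s.stateAsList());
}

// Equilibration chain: field-free thermostatted dynamics with periodic
// Maxwell momentum refreshes; returns decorrelated configuration snapshots.
// [[Rcpp::export]]
List cpp_equilibrate(List state, List par, int n_samples, double dt,
                     int burn_steps, int spacing_steps, int redraw_every,
                     double seed) {
  Sim s; s.initFromR(state, par);
  s.dt = dt;
  s.setEquil();
  Xoshiro rng(mix_seed((uint64_t)seed, 0));
  std::vector<double> bFx(s.N), bFy(s.N);

  s.drawMomenta(rng);
  s.computeForces();
  s.captureTargets();

  List out(n_samples);
  NumericVector upot(n_samples);
  auto run = [&](int nst) {
    for (int st = 0; st < nst; ++st) {
      if (redraw_every > 0 && st % redraw_every == 0 && st > 0) {
        s.drawMomenta(rng);
        s.captureTargets();
      }
      s.stepOnce(dt, rng, bFx, bFy);
    }
  };
  run(burn_steps);
  for (int k = 0; k < n_samples; ++k) {
    run(spacing_steps);
    s.drawMomenta(rng);            // fresh Maxwell momenta for each sample
    s.captureTargets();
    if (s.kind == 2) s.drawXi(rng);
    out[k] = s.stateAsList();
    upot[k] = s.potentialEnergy();
  }
  return List::create(_["states"] = out, _["potential_energy"] = upot);
}

// Full ensemble driver: one equilibration chain; after each spacing segment a
// driven trajectory is launched from the current configuration with fresh
// Maxwell momenta (independent per-trajectory noise streams), then the chain
// resumes from the saved configuration.
// [[Rcpp::export]]
List cpp_run_ensemble(List state, List par, int n_traj, int traj_steps,
                      double dt, double equil_dt, int burn_steps,
                      int spacing_steps, int redraw_every, int n_fine,
                      double seed, int grid_nx, int grid_ny,
                      bool keep_series) {
  Sim s; s.initFromR(state, par);
  s.dt = dt;
  Xoshiro chain(mix_seed((uint64_t)seed, 0));
  std::vector<double> bFx(s.N), bFy(s.N);
  bool active = (s.kind == 2);
  bool use_grid = (grid_nx > 0 && grid_ny > 0);

  NumericMatrix Jfine(n_traj, n_fine), Afine(active ? n_traj : 1,
                                             active ? n_fine : 1);
  NumericVector Jglob(n_traj), Aglob(n_traj), drift(n_traj);
  NumericVector nav_sum(n_fine);
  NumericVector jser_sum(keep_series ? traj_steps + 1 : 1);
  NumericMatrix Jgrid(use_grid ? n_traj : 1, use_grid ? grid_nx * grid_ny : 1);
  NumericVector ngrid_sum(use_grid ? grid_nx * grid_ny : 1);

  // burn-in of the equilibration chain
  s.setEquil();
  s.drawMomenta(chain);
  s.computeForces();
  s.captureTargets();
  for (int st = 0; st < burn_steps; ++st) {
    if (redraw_every > 0 && st % redraw_every == 0 && st > 0) {
      s.drawMomenta(chain);
      s.captureTargets();
    }
    s.stepOnce(equil_dt, chain, bFx, bFy);
  }

  std::vector<double> xs(s.N), ys(s.N);
  FineAccum fa;
  GridAccum ga;

  for (int tr = 0; tr < n_traj; ++tr) {
    // decorrelate along the chain
    for (int st = 0; st < spacing_steps; ++st) {
      if (redraw_every > 0 && st % redraw_every == 0) {
        s.drawMomenta(chain);
        s.captureTargets();
      }
      s.stepOnce(equil_dt, chain, bFx, bFy);
    }
    xs = s.x; ys = s.y;

    Xoshiro trng(mix_seed((uint64_t)seed, (uint64_t)(tr + 1)));
    s.drawMomenta(trng);
    if (active) s.drawXi(trng);
    s.setDriven();
    s.computeForces();
    s.captureTargets();

    fa.init(n_fine, s.Lx, dt);
    ga.init(use_grid ? grid_nx : 0, use_grid ? grid_ny : 0, s.Lx, s.Ly, dt);
    double jg = fa.sample(s, active);
    ga.sample(s);
    if (keep_series) jser_sum[0] += jg;
    double mx = 0.0;
    for (int st = 1; st <= traj_steps; ++st) {
      s.stepOnce(dt, trng, bFx, bFy);
      double d = s.constraintDrift();
      if (d > mx) mx = d;
      jg = fa.sample(s, active);
      ga.sample(s);
      if (keep_series) jser_sum[st] += jg;
    }
    drift[tr] = mx;
    for (int c = 0; c < n_fine; ++c) {
      Jfine(tr, c) = fa.J[c];
      nav_sum[c] += fa.Nav[c];
      if (active) Afine(tr, c) = fa.A[c];
    }
    Jglob[tr] = fa.Jg;
    if (active) Aglob[tr] = fa.Ag;
    if (use_grid) {
      int m = grid_nx * grid_ny;
      for (int c = 0; c < m; ++c) {
        Jgrid(tr, c) = ga.J[c];
        ngrid_sum[c] += ga.Nav[c];
      }
    }

    // restore the equilibrium chain configuration and continue
    s.x = xs; s.y = ys;
    s.setEquil();
    s.drawMomenta(chain);
    s.computeForces();
    s.captureTargets();
    if (tr % 64 == 0) Rcpp::checkUserInterrupt();
  }

  double T = traj_steps * dt;
  return List::create(
    _["J_fine"] = Jfine,
    _["A_fine"] = Afine,
    _["J_global"] = Jglob,
    _["A_global"] = Aglob,
    _["navg_fine"] = nav_sum,          // summed over trajectories; /(n*T) in R
    _["j_series_sum"] = jser_sum,
    _["J_grid"] = Jgrid,
    _["ngrid_sum"] = ngrid_sum,
    _["max_constraint_drift"] = drift,
    _["duration"] = T);
}
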