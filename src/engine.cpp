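// On-lattice tumour-immune engine.
//
// Voxel state codes (shared with the R side and the snapshot schema):
//   0 empty, 1 PDL1- cancer, 2 PDL1+ cancer, 3 dead cancer,
//   4 effector T cell, 5 cytotoxic T cell, 6 suppressed T cell.
// T cells occupy one voxel; cancer cells occupy an aligned 2x2x2 block whose
// anchor is the lowest-index corner. All randomness is drawn from R's RNG
// stream (unif_rand / rpois) so set.seed() on the R side fixes trajectories.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Agents {
  std::vector<int> st;        // state code, 0 = removed
  std::vector<int> x, y, z;   // anchor voxel (0-based)
  std::vector<double> cooldown, age, deadTimer;
  std::vector<int> divisions;
  int size() const { return (int) st.size(); }
  int add(int s, int ax, int ay, int az, double cd) {
    st.push_back(s); x.push_back(ax); y.push_back(ay); z.push_back(az);
    cooldown.push_back(cd); age.push_back(0.0); deadTimer.push_back(0.0);
    divisions.push_back(0);
    return size() - 1;
  }
};

inline bool isCancer(int s) { return s >= 1 && s <= 3; }
inline bool isLivingCancer(int s) { return s == 1 || s == 2; }
inline bool isT(int s) { return s >= 4 && s <= 6; }

struct Engine {
  int N;
  std::vector<int> occ;  // voxel -> agent index + 1, 0 = empty
  Agents ag;
  double clock;          // hours
  double cumDead;        // cumulative dead cancer cells (any cause)
  double forfeits;       // recruitment arrivals forfeited (no free entry voxel)
  std::vector<double> cyto;
  std::vector<int> entry;  // entry voxels, 0-based linear index

  // neighbourhood offsets (Moore, 26)
  int odx[26], ody[26], odz[26];

  Engine(int n) : N(n) {
    int k = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dx || dy || dz) { odx[k] = dx; ody[k] = dy; odz[k] = dz; ++k; }
  }

  inline int idx(int x, int y, int z) const { return x + N * (y + N * z); }
  inline bool inb(int c) const { return c >= 0 && c < N; }
  inline bool inb(int x, int y, int z) const { return inb(x) && inb(y) && inb(z); }

  inline int edge(int i) const { return isCancer(ag.st[i]) ? 2 : 1; }

  void paint(int i, int val) {
    int e = edge(i);
    for (int dz = 0; dz < e; ++dz)
      for (int dy = 0; dy < e; ++dy)
        for (int dx = 0; dx < e; ++dx)
          occ[idx(ag.x[i] + dx, ag.y[i] + dy, ag.z[i] + dz)] = val;
  }

  // free aligned block of size e at anchor (ax,ay,az), ignoring agent `self`
  bool blockFree(int ax, int ay, int az, int e, int self) const {
    if (!inb(ax) || !inb(ay) || !inb(az) || !inb(ax + e - 1) || !inb(ay + e - 1) || !inb(az + e - 1))
      return false;
    for (int dz = 0; dz < e; ++dz)
      for (int dy = 0; dy < e; ++dy)
        for (int dx = 0; dx < e; ++dx) {
          int o = occ[idx(ax + dx, ay + dy, az + dz)];
          if (o != 0 && o != self + 1) return false;
        }
    return true;
  }

  // distinct cancer agents (optionally only living / only PDL1+) Moore-adjacent
  // to any voxel of agent i
  void adjacentCancer(int i, std::vector<int>& out, bool livingOnly, bool posOnly) const {
    out.clear();
    int e = edge(i);
    for (int bz = 0; bz < e; ++bz)
      for (int by = 0; by < e; ++by)
        for (int bx = 0; bx < e; ++bx) {
          int vx = ag.x[i] + bx, vy = ag.y[i] + by, vz = ag.z[i] + bz;
          for (int k = 0; k < 26; ++k) {
            int nx = vx + odx[k], ny = vy + ody[k], nz = vz + odz[k];
            if (!inb(nx, ny, nz)) continue;
            int o = occ[idx(nx, ny, nz)];
            if (!o || o == i + 1) continue;
            int j = o - 1, s = ag.st[j];
            if (!isCancer(s)) continue;
            if (livingOnly && !isLivingCancer(s)) continue;
            if (posOnly && s != 2) continue;
            bool seen = false;
            for (int q : out) if (q == j) { seen = true; break; }
            if (!seen) out.push_back(j);
          }
        }
  }

  // Fisher-Yates shuffle driven by R's RNG
  static void shuffle(std::vector<int>& v) {
    for (int i = (int) v.size() - 1; i > 0; --i) {
      int j = (int) std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(v[i], v[j]);
    }
  }

  std::vector<int> livingIndices() const {
    std::vector<int> v;
    for (int i = 0; i < ag.size(); ++i) if (ag.st[i] != 0) v.push_back(i);
    return v;
  }
};

// --- ADE (Saul'yev two-sweep average) diffusion + exponential decay ---------
// Forward sweep: minus-axis neighbours use updated values (boundary ghost =
// old centre value), plus-axis neighbours use old values (boundary ghost =
// new centre value); backward sweep mirrors this. Ghost choices make each
// sweep exactly mass-conserving under zero-flux faces. For a <= 1/3 every
// coefficient is non-negative so positivity is preserved; a final clamp
// guards against round-off.
void adeStepCore(std::vector<double>& u, int nx, int ny, int nz, double a, double decayFactor) {
  const int n = nx * ny * nz;
  std::vector<double> f(n), b(n);
  const int sy = nx, sz = nx * ny;
  const double cc = 1.0 - 3.0 * a;
  // lhs = 1 + 3a - (#boundary ghosts replaced by the new centre) * a
  double inv[4];
  for (int k = 0; k < 4; ++k) inv[k] = 1.0 / (1.0 + 3.0 * a - k * a);

  // forward sweep (ascending linear order: x fastest)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const bool ym = y > 0, yp = y < ny - 1, zm = z > 0, zp = z < nz - 1;
      const int rowB = (yp ? 0 : 1) + (zp ? 0 : 1);
      const int base = nx * (y + ny * z);
      for (int x = 0; x < nx; ++x) {
        const int c = base + x;
        double rhs = cc * u[c] +
          a * ((x > 0 ? f[c - 1] : u[c]) + (ym ? f[c - sy] : u[c]) +
               (zm ? f[c - sz] : u[c]));
        int nb = rowB;
        if (x < nx - 1) rhs += a * u[c + 1]; else ++nb;
        if (yp) rhs += a * u[c + sy];
        if (zp) rhs += a * u[c + sz];
        f[c] = rhs * inv[nb];
      }
    }
  // backward sweep (descending)
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y) {
      const bool ym = y > 0, yp = y < ny - 1, zm = z > 0, zp = z < nz - 1;
      const int rowB = (ym ? 0 : 1) + (zm ? 0 : 1);
      const int base = nx * (y + ny * z);
      for (int x = nx - 1; x >= 0; --x) {
        const int c = base + x;
        double rhs = cc * u[c] +
          a * ((x < nx - 1 ? b[c + 1] : u[c]) + (yp ? b[c + sy] : u[c]) +
               (zp ? b[c + sz] : u[c]));
        int nb = rowB;
        if (x > 0) rhs += a * u[c - 1]; else ++nb;
        if (ym) rhs += a * u[c - sy];
        if (zm) rhs += a * u[c - sz];
        b[c] = rhs * inv[nb];
      }
    }
  for (int c = 0; c < n; ++c) {
    double v = 0.5 * (f[c] + b[c]) * decayFactor;
    u[c] = (v > 0.0) ? v : 0.0;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector cppAdeStep(NumericVector grid, IntegerVector dims, double diffusionCoeff,
                         double decayRate, double dx, double dtPde) {
  // diffusionCoeff um^2/s, decayRate 1/h, dx um, dtPde s
  std::vector<double> u(grid.begin(), grid.end());
  double a = diffusionCoeff * dtPde / (dx * dx);
  double decayFactor = std::exp(-decayRate * dtPde / 3600.0);
  adeStepCore(u, dims[0], dims[1], dims[2], a, decayFactor);
  NumericVector out(u.begin(), u.end());
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
List cppRun(List state, List params, int nSteps, IntegerVector snapshotSteps,
            LogicalVector phases, bool advanceClock) {
  RNGScope scope;

  const int N = as<int>(state["n"]);
  Engine E(N);
  {
    IntegerVector occ = state["occupancy"];
    E.occ.assign(occ.begin(), occ.end());
    NumericVector cy = state["cytokine"];
    E.cyto.assign(cy.begin(), cy.end());
    IntegerVector ent = state["entryVoxels"];
    E.entry.assign(ent.begin(), ent.end());
    List a = state["agents"];
    IntegerVector st = a["state"], ax = a["x"], ay = a["y"], az = a["z"], dv = a["divisions"];
    NumericVector cd = a["cooldown"], age = a["age"], dt_ = a["deadTimer"];
    int m = st.size();
    E.ag.st.assign(st.begin(), st.end());
    E.ag.x.assign(ax.begin(), ax.end());
    E.ag.y.assign(ay.begin(), ay.end());
    E.ag.z.assign(az.begin(), az.end());
    E.ag.cooldown.assign(cd.begin(), cd.end());
    E.ag.age.assign(age.begin(), age.end());
    E.ag.deadTimer.assign(dt_.begin(), dt_.end());
    E.ag.divisions.assign(dv.begin(), dv.end());
    (void) m;
  }
  E.clock = as<double>(state["clockHours"]);
  E.cumDead = as<double>(state["cumulativeDeadCancer"]);
  E.forfeits = as<double>(state["forfeitedArrivals"]);

  // parameters
  const double dt = as<double>(params["dtHours"]);
  const double voxelSize = as<double>(params["voxelSize"]);
  const double pKillNeg = as<double>(params["pKillNeg"]);
  const double pKillPos = as<double>(params["pKillPos"]);
  const double pInduct = as<double>(params["pPdl1Induction"]);
  const bool inductOnContact = as<bool>(params["inductionOnContact"]);
  const double pSupp = as<double>(params["pSupp"]);
  const double il2Thr = as<double>(params["il2DivisionThreshold"]);
  const double tSpeed = as<double>(params["tCellSpeed"]);     // um/min
  const double cSpeed = as<double>(params["cancerSpeed"]);    // um/min
  const double cCycle = as<double>(params["cancerCycleTime"]);  // h
  const double tCycle = as<double>(params["tCellCycleTime"]);   // h
  const double tLife = as<double>(params["tCellLifespan"]);     // h
  const double clearT = as<double>(params["deadClearanceTime"]);  // h
  const double pNecro = as<double>(params["pNecrosis"]);  // per blocked division attempt
  const int maxTDiv = as<int>(params["maxTCellDivisions"]);
  const double kA = as<double>(params["kA"]);
  const double kI = as<double>(params["kI"]);
  const double rBase = as<double>(params["rBase"]);
  // cytokine
  const double D = as<double>(params["diffusionCoeff"]);   // um^2/s
  const double decay = as<double>(params["decayRate"]);    // 1/h
  const double secRate = as<double>(params["secretionRate"]);  // units/h
  const int nSub = as<int>(params["pdeSubsteps"]);
  const int fC = as<int>(params["pdeCoarsen"]);   // IL-2 grid coarsening factor
  // treatment
  const bool trEnabled = as<bool>(params["treatmentEnabled"]);
  const double trStart = as<double>(params["treatmentStartDay"]);  // days
  const double mSupp = as<double>(params["mSupp"]);

  const bool phRecruit = phases[0], phCyto = phases[1], phContact = phases[2],
             phDivide = phases[3], phMigrate = phases[4], phClear = phases[5];

  const int Nc = N / fC;                       // cytokine grid edge
  const double volC = (double) fC * fC * fC;   // cell voxels per cytokine voxel
  const double dtPdeSec = dt * 3600.0 / nSub;
  const double dxC = voxelSize * fC;
  const double aPde = D * dtPdeSec / (dxC * dxC);
  const double decayFactor = std::exp(-decay * (dt / nSub));
  // coarse-grid index of a cell voxel; grid values are concentrations per
  // cell voxel, so secretion deposits are divided by the coarse cell volume
  auto cidx = [&](int x, int y, int z) {
    return (x / fC) + Nc * ((y / fC) + Nc * (z / fC));
  };
  if ((int) E.cyto.size() != Nc * Nc * Nc)
    stop("cytokine grid size does not match nVoxels / pdeCoarsen");

  const double tMoves = tSpeed * 60.0 * dt / voxelSize;   // lattice moves per step
  const double cMoves = cSpeed * 60.0 * dt / voxelSize;

  // per-step records
  const int TS_NC = 7, EV_NC = 11;
  NumericMatrix ts(nSteps, TS_NC), ev(nSteps, EV_NC);
  List snapLabels, snapIds, snapCyto;
  std::vector<int> snapAt(snapshotSteps.begin(), snapshotSteps.end());

  std::vector<int> adj, cand;
  // the IL-2 field stays identically zero (and needs no solver work) until
  // the first secretion event; restarts also detect an existing field
  bool fieldActive = false;
  for (double v : E.cyto) if (v != 0.0) { fieldActive = true; break; }

  for (int step = 0; step < nSteps; ++step) {
    double recruits = 0, activations = 0, kills = 0, suppressions = 0, inductions = 0,
           divC = 0, divT = 0, spont = 0, cleared = 0, tDeaths = 0, forfeitStep = 0;

    // 1. recruitment -------------------------------------------------------
    if (phRecruit && rBase > 0) {
      double rate = (E.cumDead > 0) ? rBase * kA * (kI * E.cumDead) / (1.0 + kI * E.cumDead) : 0.0;
      int nArr = (rate > 0) ? (int) R::rpois(rate * dt) : 0;
      if (nArr > 0) {
        std::vector<int> freeEntry;
        for (int v : E.entry) if (E.occ[v] == 0) freeEntry.push_back(v);
        for (int k = 0; k < nArr; ++k) {
          if (freeEntry.empty()) { E.forfeits += 1; forfeitStep += 1; continue; }
          int j = (int) std::floor(unif_rand() * freeEntry.size());
          if (j >= (int) freeEntry.size()) j = (int) freeEntry.size() - 1;
          int v = freeEntry[j];
          freeEntry[j] = freeEntry.back(); freeEntry.pop_back();
          int vx = v % N, vy = (v / N) % N, vz = v / (N * N);
          int ai = E.ag.add(4, vx, vy, vz, tCycle);
          E.occ[v] = ai + 1;
          recruits += 1;
        }
      }
    }

    // 2. cytokine: secretion then diffusion/decay --------------------------
    if (phCyto) {
      bool anySource = false;
      for (int i = 0; i < E.ag.size(); ++i)
        if (E.ag.st[i] == 5) {
          E.cyto[cidx(E.ag.x[i], E.ag.y[i], E.ag.z[i])] += secRate * dt / volC;
          anySource = true;
        }
      if (anySource) fieldActive = true;
      if (fieldActive && (D > 0 || decay > 0))
        for (int s = 0; s < nSub; ++s)
          adeStepCore(E.cyto, Nc, Nc, Nc, aPde, decayFactor);
    }

    // effective suppression probability under anti-PDL1 blockade
    double pSuppEff = pSupp;
    if (trEnabled && (E.clock / 24.0) >= trStart) pSuppEff = pSupp * (1.0 - mSupp);

    // 3. contact interactions ---------------------------------------------
    if (phContact) {
      std::vector<int> tcells;
      for (int i = 0; i < E.ag.size(); ++i)
        if (E.ag.st[i] == 4 || E.ag.st[i] == 5) tcells.push_back(i);
      Engine::shuffle(tcells);
      for (int i : tcells) {
        if (E.ag.st[i] == 6 || E.ag.st[i] == 0) continue;  // may have been suppressed meanwhile
        E.adjacentCancer(i, adj, true, false);
        if (adj.empty()) continue;
        if (E.ag.st[i] == 4) { E.ag.st[i] = 5; activations += 1; }
        // one kill attempt against one uniformly chosen adjacent living target
        int j = adj[(int) std::floor(unif_rand() * adj.size())];
        if (isLivingCancer(E.ag.st[j])) {
          double p = (E.ag.st[j] == 1) ? pKillNeg : pKillPos;
          bool killed = unif_rand() < p;
          if (killed) {
            E.ag.st[j] = 3;
            E.ag.deadTimer[j] = clearT;
            E.cumDead += 1;
            kills += 1;
          } else if (E.ag.st[j] == 1 && !inductOnContact) {
            // default mode: PDL1 induction conditioned on a failed kill attempt
            if (unif_rand() < pInduct) { E.ag.st[j] = 2; inductions += 1; }
          }
        }
        if (inductOnContact) {
          // alternative mode: every adjacent PDL1- cancer cell draws induction
          // on contact, independent of the kill attempt
          E.adjacentCancer(i, adj, true, false);
          for (int q : adj)
            if (E.ag.st[q] == 1 && unif_rand() < pInduct) { E.ag.st[q] = 2; inductions += 1; }
        }
        // independent suppression draw against adjacent PDL1+ cells
        E.adjacentCancer(i, adj, true, true);
        if (!adj.empty() && unif_rand() < pSuppEff) {
          E.ag.st[i] = 6;
          suppressions += 1;
        }
      }
    }

    // 4. divisions ---------------------------------------------------------
    if (phDivide) {
      std::vector<int> liv = E.livingIndices();
      Engine::shuffle(liv);
      for (int i : liv) {
        int s = E.ag.st[i];
        if (s == 0 || s == 3 || s == 6) continue;
        E.ag.cooldown[i] -= dt;
        if (E.ag.cooldown[i] > 0) continue;
        bool isTcell = isT(s);
        if (isTcell) {
          if (E.ag.divisions[i] >= maxTDiv) continue;
          if (E.cyto[cidx(E.ag.x[i], E.ag.y[i], E.ag.z[i])] < il2Thr) continue;
        }
        int e = E.edge(i), stepLen = isTcell ? 1 : 2;
        cand.clear();
        for (int k = 0; k < 26; ++k) {
          int ax = E.ag.x[i] + E.odx[k] * stepLen,
              ay = E.ag.y[i] + E.ody[k] * stepLen,
              az = E.ag.z[i] + E.odz[k] * stepLen;
          if (E.blockFree(ax, ay, az, e, -2)) cand.push_back(k);
        }
        double cyc = isTcell ? tCycle : cCycle;
        if (cand.empty()) {
          // contact inhibition: re-attempt next cycle; a fully enclosed
          // cancer cell may instead die (necrotic core turnover), which
          // seeds the dead-cell signal driving recruitment
          E.ag.cooldown[i] = cyc;
          if (!isTcell && pNecro > 0 && unif_rand() < pNecro) {
            E.ag.st[i] = 3; E.ag.deadTimer[i] = clearT; E.cumDead += 1; spont += 1;
          }
          continue;
        }
        int k = cand[(int) std::floor(unif_rand() * cand.size())];
        int ax = E.ag.x[i] + E.odx[k] * stepLen,
            ay = E.ag.y[i] + E.ody[k] * stepLen,
            az = E.ag.z[i] + E.odz[k] * stepLen;
        int d = E.ag.add(s, ax, ay, az, cyc);
        E.ag.divisions[d] = E.ag.divisions[i] + 1;
        E.ag.divisions[i] += 1;
        E.ag.cooldown[i] = cyc;
        E.paint(d, d + 1);
        if (isTcell) divT += 1; else divC += 1;
      }
    }

    // 5. migration ---------------------------------------------------------
    if (phMigrate) {
      std::vector<int> liv = E.livingIndices();
      Engine::shuffle(liv);
      for (int i : liv) {
        int s = E.ag.st[i];
        if (s == 0 || s == 3) continue;  // dead cells do not move
        double mv = isT(s) ? tMoves : cMoves;
        if (mv <= 0) continue;
        int nm = (int) std::floor(mv);
        if (unif_rand() < mv - nm) ++nm;
        int e = E.edge(i);
        for (int m = 0; m < nm; ++m) {
          int k = (int) std::floor(unif_rand() * 26.0);
          if (k > 25) k = 25;
          int ax = E.ag.x[i] + E.odx[k], ay = E.ag.y[i] + E.ody[k], az = E.ag.z[i] + E.odz[k];
          if (!E.blockFree(ax, ay, az, e, i)) continue;  // blocked move forfeited
          E.paint(i, 0);
          E.ag.x[i] = ax; E.ag.y[i] = ay; E.ag.z[i] = az;
          E.paint(i, i + 1);
        }
      }
    }

    // 6. death and clearance ----------------------------------------------
    if (phClear) {
      for (int i = 0; i < E.ag.size(); ++i) {
        int s = E.ag.st[i];
        if (s == 0) continue;
        E.ag.age[i] += dt;
        if (isT(s)) {
          if (E.ag.age[i] >= tLife || E.ag.divisions[i] >= maxTDiv) {
            E.paint(i, 0); E.ag.st[i] = 0; tDeaths += 1;
          }
        } else if (s == 3) {
          E.ag.deadTimer[i] -= dt;
          if (E.ag.deadTimer[i] <= 0) { E.paint(i, 0); E.ag.st[i] = 0; cleared += 1; }
        }
      }
    }

    if (advanceClock) E.clock += dt;

    // record ---------------------------------------------------------------
    double cnt[7] = {0, 0, 0, 0, 0, 0, 0};
    for (int i = 0; i < E.ag.size(); ++i) {
      int s = E.ag.st[i];
      if (s >= 1 && s <= 6) cnt[s - 1] += 1;
    }
    double mass = 0;
    for (double v : E.cyto) mass += v;
    mass *= volC;
    for (int c = 0; c < 6; ++c) ts(step, c) = cnt[c];
    ts(step, 6) = mass;
    double evRow[EV_NC] = {recruits, forfeitStep, activations, kills, suppressions,
                           inductions, divC, divT, spont, cleared, tDeaths};
    for (int c = 0; c < EV_NC; ++c) ev(step, c) = evRow[c];

    for (size_t q = 0; q < snapAt.size(); ++q) {
      if (snapAt[q] == step + 1) {
        IntegerVector lab(N * N * N, 0), ids(N * N * N, 0);
        for (int v = 0; v < N * N * N; ++v) {
          int o = E.occ[v];
          if (o) { lab[v] = E.ag.st[o - 1]; ids[v] = o; }
        }
        IntegerVector d3 = IntegerVector::create(N, N, N);
        lab.attr("dim") = d3; ids.attr("dim") = d3;
        NumericVector cy(E.cyto.begin(), E.cyto.end());
        cy.attr("dim") = IntegerVector::create(Nc, Nc, Nc);
        snapLabels.push_back(lab); snapIds.push_back(ids); snapCyto.push_back(cy);
      }
    }
  }

  // compact agents (drop removed slots, reindex occupancy)
  std::vector<int> remap(E.ag.size(), 0);
  int nOut = 0;
  for (int i = 0; i < E.ag.size(); ++i) if (E.ag.st[i] != 0) remap[i] = ++nOut;
  IntegerVector ost(nOut), ox(nOut), oy(nOut), oz(nOut), odv(nOut);
  NumericVector ocd(nOut), oage(nOut), odt(nOut);
  for (int i = 0; i < E.ag.size(); ++i) {
    if (!remap[i]) continue;
    int j = remap[i] - 1;
    ost[j] = E.ag.st[i]; ox[j] = E.ag.x[i]; oy[j] = E.ag.y[i]; oz[j] = E.ag.z[i];
    ocd[j] = E.ag.cooldown[i]; oage[j] = E.ag.age[i]; odt[j] = E.ag.deadTimer[i];
    odv[j] = E.ag.divisions[i];
  }
  IntegerVector oocc(N * N * N);
  for (int v = 0; v < N * N * N; ++v) oocc[v] = E.occ[v] ? remap[E.occ[v] - 1] : 0;
  oocc.attr("dim") = IntegerVector::create(N, N, N);
  NumericVector ocy(E.cyto.begin(), E.cyto.end());
  ocy.attr("dim") = IntegerVector::create(Nc, Nc, Nc);

  List agentsOut = List::create(
      _["state"] = ost, _["x"] = ox, _["y"] = oy, _["z"] = oz,
      _["cooldown"] = ocd, _["age"] = oage, _["deadTimer"] = odt, _["divisions"] = odv);

  colnames(ts) = CharacterVector::create("pdl1neg", "pdl1pos", "deadCancer",
                                         "effector", "cytotoxic", "suppressed", "il2Mass");
  colnames(ev) = CharacterVector::create("recruits", "forfeits", "activations", "kills",
                                         "suppressions", "inductions", "cancerDivisions",
                                         "tCellDivisions", "necroticDeaths", "cleared",
                                         "tCellDeaths");

  return List::create(
      _["occupancy"] = oocc, _["agents"] = agentsOut, _["cytokine"] = ocy,
      _["clockHours"] = E.clock, _["cumulativeDeadCancer"] = E.cumDead,
      _["forfeitedArrivals"] = E.forfeits, _["timeSeries"] = ts, _["events"] = ev,
      _["snapshotLabels"] = snapLabels, _["snapshotIds"] = snapIds,
      _["snapshotCytokine"] = snapCyto);
}

// [[Rcpp::export]]
IntegerVector cppFloodBackground(IntegerVector vol, IntegerVector dims) {
  // 6-connected flood fill of zero voxels seeded from all lattice faces.
  // Returns binary volume: 1 = tumour region (complement of edge-connected
  // background), 0 = background.
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> bg(n, 0);
  std::vector<int> stack;
  stack.reserve(n / 4);
  auto id = [&](int x, int y, int z) { return x + nx * (y + ny * z); };
  auto seed = [&](int x, int y, int z) {
    int c = id(x, y, z);
    if (!vol[c] && !bg[c]) { bg[c] = 1; stack.push_back(c); }
  };
  for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) { seed(x, y, 0); seed(x, y, nz - 1); }
  for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x) { seed(x, 0, z); seed(x, ny - 1, z); }
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) { seed(0, y, z); seed(nx - 1, y, z); }
  while (!stack.empty()) {
    int c = stack.back(); stack.pop_back();
    int x = c % nx, y = (c / nx) % ny, z = c / (nx * ny);
    const int xs[6] = {x - 1, x + 1, x, x, x, x};
    const int ys[6] = {y, y, y - 1, y + 1, y, y};
    const int zs[6] = {z, z, z, z, z - 1, z + 1};
    for (int k = 0; k < 6; ++k) {
      if (xs[k] < 0 || xs[k] >= nx || ys[k] < 0 || ys[k] >= ny || zs[k] < 0 || zs[k] >= nz) continue;
      int c2 = id(xs[k], ys[k], zs[k]);
      if (!vol[c2] && !bg[c2]) { bg[c2] = 1; stack.push_back(c2); }
    }
  }
  IntegerVector out(n);
  for (int c = 0; c < n; ++c) out[c] = bg[c] ? 0 : 1;
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
IntegerVector cppBoxSmooth(IntegerVector vol, IntegerVector dims) {
  // Unweighted 3x3x3 moving average with zero padding, thresholded at >= 0.5.
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(nx * ny * nz);
  auto id = [&](int x, int y, int z) { return x + nx * (y + ny * z); };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int s = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int X = x + dx, Y = y + dy, Z = z + dz;
              if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
              s += vol[id(X, Y, Z)];
            }
        out[id(x, y, z)] = (s / 27.0 >= 0.5) ? 1 : 0;
      }
  out.attr("dim") = dims;
  return out;
}
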