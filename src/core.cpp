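// Coarse-grained peptide model: backbone N/CA/C per residue plus one
// side-chain bead (SB) off CA, two virtual cap atoms so that phi of the
// first and psi of the last residue are defined.  Chain layout (row index,
// 0-based) in every coordinate matrix produced here:
//   row 0            : C cap preceding residue 1
//   rows 1+4i..4+4i  : N, CA, C, SB of residue i (0-based)
//   row 4n+1         : N cap following residue n
// Units: Angstrom, degrees at the R boundary (radians internally), kT.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <cstring>
#include <vector>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// fixed ideal backbone geometry
static const double B_N_CA  = 1.458;
static const double B_CA_C  = 1.525;
static const double B_C_N   = 1.329;
static const double B_CA_SB = 1.80;
static const double A_N_CA_C  = 111.2 * DEG;
static const double A_CA_C_N  = 116.2 * DEG;
static const double A_C_N_CA  = 121.7 * DEG;
static const double A_N_CA_SB = 110.5 * DEG;
static const double D_IMP_SB  = 122.5 * DEG; // dihedral(C, N, CA, SB)
static const double OMEGA     = 180.0 * DEG;

// Ramachandran basin bounds (degrees); the recorded constants of the model
static const double H_PHI_LO = -100.0, H_PHI_HI = -30.0;
static const double H_PSI_LO = -67.0,  H_PSI_HI = -7.0;
static const double E_PHI_LO = -180.0, E_PHI_HI = -50.0;
static const double E_PSI_LO = 90.0,   E_PSI_HI = 180.0;

static inline bool in_helix(double phi, double psi) {
  return phi >= H_PHI_LO && phi <= H_PHI_HI && psi >= H_PSI_LO && psi <= H_PSI_HI;
}
static inline bool in_extended(double phi, double psi) {
  return phi >= E_PHI_LO && phi <= E_PHI_HI && psi >= E_PSI_LO && psi <= E_PSI_HI;
}

// ---------------------------------------------------------------- RNG ----
// splitmix64-seeded xoshiro256** with one substream per (base_seed, run_id);
// platform-independent, independent of R's RNG.

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  Rng(uint64_t base_seed, uint64_t stream) {
    uint64_t st = base_seed * 0x9E3779B97F4A7C15ULL + stream * 0xD1B54A32D192ED03ULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(st);
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  double unif(double lo, double hi) { return lo + (hi - lo) * unif(); }
  int unif_int(int n) { int k = (int)(unif() * n); return k >= n ? n - 1 : k; }
};

// ----------------------------------------------------------- geometry ----

static inline void vsub(const double *a, const double *b, double *o) {
  o[0] = a[0] - b[0]; o[1] = a[1] - b[1]; o[2] = a[2] - b[2];
}
static inline void vcross(const double *a, const double *b, double *o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vdot(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double vnorm(const double *a) { return std::sqrt(vdot(a, a)); }
static inline void vscale(double *a, double s) { a[0] *= s; a[1] *= s; a[2] *= s; }

// NeRF placement: put D at |CD| = bond, angle(B,C,D) = ang, dihedral(A,B,C,D) = tor
static void place_atom(const double *A, const double *B, const double *C,
                       double bond, double ang, double tor, double *D) {
  double bc[3], ab[3], n[3], m[3];
  vsub(C, B, bc); vscale(bc, 1.0 / vnorm(bc));
  vsub(B, A, ab);
  vcross(ab, bc, n); vscale(n, 1.0 / vnorm(n));
  vcross(n, bc, m);
  const double d0 = -bond * std::cos(ang);
  const double d1 =  bond * std::sin(ang) * std::cos(tor);
  const double d2 =  bond * std::sin(ang) * std::sin(tor);
  for (int k = 0; k < 3; ++k) D[k] = C[k] + d0 * bc[k] + d1 * m[k] + d2 * n[k];
}

// IUPAC dihedral of a-b-c-d, radians in (-pi, pi]
static double dihedral4(const double *a, const double *b, const double *c, const double *d) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], m1[3];
  vsub(b, a, b1); vsub(c, b, b2); vsub(d, c, b3);
  vcross(b1, b2, n1); vcross(b2, b3, n2);
  double b2n[3] = { b2[0], b2[1], b2[2] };
  vscale(b2n, 1.0 / vnorm(b2));
  vcross(n1, b2n, m1);
  return std::atan2(-vdot(m1, n2), vdot(n1, n2));
}

// Build full chain (row-major (4n+2) x 3) from phi/psi in radians.
static void build_chain(int n, const double *phi, const double *psi, double *X) {
  double *row = X; // helper lambdas over raw layout
  auto R = [&](int r) { return row + 3 * r; };
  const int iN = 1, iCA = 2, iC = 3, iSB = 4;
  auto res = [&](int i, int atom) { return R(1 + 4 * i + (atom - 1)); };

  // residue 0 in a canonical frame
  double *N0 = res(0, iN), *CA0 = res(0, iCA), *C0r = res(0, iC);
  N0[0] = 0; N0[1] = 0; N0[2] = 0;
  CA0[0] = B_N_CA; CA0[1] = 0; CA0[2] = 0;
  C0r[0] = B_N_CA - B_CA_C * std::cos(A_N_CA_C);
  C0r[1] = B_CA_C * std::sin(A_N_CA_C);
  C0r[2] = 0;
  // leading C cap defines phi of residue 0: dihedral(Ccap, N0, CA0, C0) = phi0
  place_atom(C0r, CA0, N0, B_C_N, A_C_N_CA, phi[0], R(0));
  // side bead of residue 0
  place_atom(C0r, N0, CA0, B_CA_SB, A_N_CA_SB, D_IMP_SB, res(0, iSB));

  for (int i = 1; i < n; ++i) {
    place_atom(res(i - 1, iN), res(i - 1, iCA), res(i - 1, iC),
               B_C_N, A_CA_C_N, psi[i - 1], res(i, iN));
    place_atom(res(i - 1, iCA), res(i - 1, iC), res(i, iN),
               B_N_CA, A_C_N_CA, OMEGA, res(i, iCA));
    place_atom(res(i - 1, iC), res(i, iN), res(i, iCA),
               B_CA_C, A_N_CA_C, phi[i], res(i, iC));
    place_atom(res(i, iC), res(i, iN), res(i, iCA),
               B_CA_SB, A_N_CA_SB, D_IMP_SB, res(i, iSB));
  }
  // trailing N cap defines psi of last residue
  place_atom(res(n - 1, iN), res(n - 1, iCA), res(n - 1, iC),
             B_C_N, A_CA_C_N, psi[n - 1], R(4 * n + 1));
}

static void extract_dihedrals(int n, const double *X, double *phi, double *psi) {
  auto R = [&](int r) { return X + 3 * r; };
  auto res = [&](int i, int atom) { return X + 3 * (1 + 4 * i + (atom - 1)); };
  const int iN = 1, iCA = 2, iC = 3;
  for (int i = 0; i < n; ++i) {
    const double *Cprev = (i == 0) ? R(0) : res(i - 1, iC);
    const double *Nnext = (i == n - 1) ? R(4 * n + 1) : res(i + 1, iN);
    phi[i] = dihedral4(Cprev, res(i, iN), res(i, iCA), res(i, iC));
    psi[i] = dihedral4(res(i, iN), res(i, iCA), res(i, iC), Nnext);
  }
}

// ------------------------------------------------------------- energy ----

struct EnergyModel {
  int n;
  const double *q;      // side-chain formal charge per residue
  const double *sbr;    // side-bead steric radius per residue
  double car;           // CA bead steric radius
  const double *hw;     // helix propensity weight per residue
  bool sterics, elec, helix, attraction;
  double lambda_d, bjerrum, k_rep, att_eps, att_range;
};

// steric/attraction bead set: CA and SB beads on the virtual bond graph
// CA(i)-CA(i+1), CA(i)-SB(i); pairs >= 3 bonds apart interact:
//   CA-CA |i-j| >= 3, CA-SB |i-j| >= 2, SB-SB |i-j| >= 1
static void chain_energy(const double *X, const double *phi, const double *psi,
                         const EnergyModel &em, double out[5]) {
  const int n = em.n;
  double e_st = 0, e_el = 0, e_hx = 0, e_at = 0;
  auto CA = [&](int i) { return X + 3 * (2 + 4 * i); };
  auto SB = [&](int i) { return X + 3 * (4 + 4 * i); };
  auto d2 = [](const double *a, const double *b) {
    const double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
    return dx * dx + dy * dy + dz * dz;
  };
  if (em.sterics || em.attraction) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        const int sep = j - i;
        if (em.sterics) {
          if (sep >= 3) { // CA-CA
            const double s = em.car + em.car, dd = d2(CA(i), CA(j));
            if (dd < s * s) { const double t = 1.0 - dd / (s * s); e_st += em.k_rep * t * t; }
          }
          if (sep >= 2) { // CA-SB both directions
            double s = em.car + em.sbr[j], dd = d2(CA(i), SB(j));
            if (dd < s * s) { const double t = 1.0 - dd / (s * s); e_st += em.k_rep * t * t; }
            s = em.sbr[i] + em.car; dd = d2(SB(i), CA(j));
            if (dd < s * s) { const double t = 1.0 - dd / (s * s); e_st += em.k_rep * t * t; }
          }
          { // SB-SB, sep >= 1
            const double s = em.sbr[i] + em.sbr[j], dd = d2(SB(i), SB(j));
            if (dd < s * s) { const double t = 1.0 - dd / (s * s); e_st += em.k_rep * t * t; }
          }
        }
        if (em.attraction && sep >= 3) {
          const double dd = d2(CA(i), CA(j));
          e_at -= em.att_eps * std::exp(-dd / (em.att_range * em.att_range));
        }
      }
    }
  }
  if (em.elec) {
    for (int i = 0; i < n; ++i) {
      if (em.q[i] == 0) continue;
      for (int j = i + 1; j < n; ++j) {
        if (em.q[j] == 0) continue;
        const double d = std::sqrt(d2(SB(i), SB(j)));
        e_el += em.bjerrum * em.q[i] * em.q[j] * std::exp(-d / em.lambda_d) / d;
      }
    }
  }
  if (em.helix) {
    for (int i = 0; i < n; ++i) {
      if (em.hw[i] > 0 && in_helix(phi[i] / DEG, psi[i] / DEG)) e_hx -= std::log(em.hw[i]);
    }
  }
  out[0] = e_st + e_el + e_hx + e_at;
  out[1] = e_st; out[2] = e_el; out[3] = e_hx; out[4] = e_at;
}

// all real beads (rows 1..4n) within droplet_radius of their centroid
static bool droplet_ok(const double *X, int n, double radius) {
  const int nb = 4 * n;
  double c[3] = {0, 0, 0};
  for (int r = 1; r <= nb; ++r)
    for (int k = 0; k < 3; ++k) c[k] += X[3 * r + k];
  for (int k = 0; k < 3; ++k) c[k] /= nb;
  const double r2 = radius * radius;
  for (int r = 1; r <= nb; ++r) {
    const double dx = X[3 * r] - c[0], dy = X[3 * r + 1] - c[1], dz = X[3 * r + 2] - c[2];
    if (dx * dx + dy * dy + dz * dz > r2) return false;
  }
  return true;
}

// basin-mixture proposal for one residue; weights w[0]=helix, w[1]=extended,
// w[2]=other; uniform within the chosen basin (rejection for "other")
static void propose_pair(Rng &rng, const double *w, double &phi, double &psi) {
  const double tot = w[0] + w[1] + w[2];
  const double u = rng.unif() * tot;
  if (u < w[0]) {
    phi = rng.unif(H_PHI_LO, H_PHI_HI); psi = rng.unif(H_PSI_LO, H_PSI_HI);
  } else if (u < w[0] + w[1]) {
    phi = rng.unif(E_PHI_LO, E_PHI_HI); psi = rng.unif(E_PSI_LO, E_PSI_HI);
  } else {
    do {
      phi = rng.unif(-180.0, 180.0); psi = rng.unif(-180.0, 180.0);
    } while (in_helix(phi, psi) || in_extended(phi, psi));
  }
}

// ------------------------------------------------------------ exports ----

// [[Rcpp::export]]
NumericMatrix cpp_build_chain(NumericVector phi, NumericVector psi) {
  const int n = phi.size();
  if (psi.size() != n) stop("phi and psi must have equal length");
  std::vector<double> ph(n), ps(n), X((4 * n + 2) * 3);
  for (int i = 0; i < n; ++i) { ph[i] = phi[i] * DEG; ps[i] = psi[i] * DEG; }
  build_chain(n, ph.data(), ps.data(), X.data());
  NumericMatrix out(4 * n + 2, 3);
  for (int r = 0; r < 4 * n + 2; ++r)
    for (int k = 0; k < 3; ++k) out(r, k) = X[3 * r + k];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_dihedrals(NumericMatrix coords) {
  const int nr = coords.nrow();
  if ((nr - 2) % 4 != 0 || nr < 6) stop("coordinate matrix has invalid row count");
  const int n = (nr - 2) / 4;
  std::vector<double> X(nr * 3), phi(n), psi(n);
  for (int r = 0; r < nr; ++r)
    for (int k = 0; k < 3; ++k) X[3 * r + k] = coords(r, k);
  extract_dihedrals(n, X.data(), phi.data(), psi.data());
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = phi[i] / DEG; out(i, 1) = psi[i] / DEG; }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_energy(NumericMatrix coords, NumericVector phi, NumericVector psi,
                         NumericVector charge, NumericVector sb_radius, double ca_radius,
                         NumericVector helix_w, LogicalVector flags,
                         double lambda_d, double bjerrum, double k_rep,
                         double att_eps, double att_range) {
  const int n = phi.size();
  if (coords.nrow() != 4 * n + 2) stop("coords/sequence length mismatch");
  std::vector<double> X(coords.nrow() * 3), ph(n), ps(n);
  for (int r = 0; r < coords.nrow(); ++r)
    for (int k = 0; k < 3; ++k) X[3 * r + k] = coords(r, k);
  for (int i = 0; i < n; ++i) { ph[i] = phi[i] * DEG; ps[i] = psi[i] * DEG; }
  EnergyModel em { n, charge.begin(), sb_radius.begin(), ca_radius, helix_w.begin(),
                   (bool)flags[0], (bool)flags[1], (bool)flags[2], (bool)flags[3],
                   lambda_d, bjerrum, k_rep, att_eps, att_range };
  double out[5];
  chain_energy(X.data(), ph.data(), ps.data(), em, out);
  NumericVector res = NumericVector::create(out[0], out[1], out[2], out[3], out[4]);
  res.names() = CharacterVector::create("total", "steric", "electrostatic", "helix", "attraction");
  return res;
}

// [[Rcpp::export]]
List cpp_sample_run(int n, NumericMatrix basin_w, NumericVector charge,
                    NumericVector sb_radius, double ca_radius, NumericVector helix_w,
                    LogicalVector flags, double lambda_d, double bjerrum, double k_rep,
                    double att_eps, double att_range, double droplet_radius,
                    double tscale, int equil_steps, int production_steps, int interval,
                    int base_seed, int run_id) {
  if (production_steps % interval != 0) stop("sampling_interval must divide production_steps");
  const int nconf = production_steps / interval;
  const int nrow = 4 * n + 2;
  Rng rng((uint64_t)(uint32_t)base_seed, (uint64_t)(uint32_t)run_id);

  EnergyModel em { n, charge.begin(), sb_radius.begin(), ca_radius, helix_w.begin(),
                   (bool)flags[0], (bool)flags[1], (bool)flags[2], (bool)flags[3],
                   lambda_d, bjerrum, k_rep, att_eps, att_range };

  std::vector<double> phi(n), psi(n), cur(nrow * 3), prop(nrow * 3);
  // initial conformation: independent basin draw, must satisfy the droplet
  bool ok = false;
  for (int attempt = 0; attempt < 1000 && !ok; ++attempt) {
    for (int i = 0; i < n; ++i) {
      double ph, ps;
      propose_pair(rng, &basin_w(0, i), ph, ps);
      phi[i] = ph * DEG; psi[i] = ps * DEG;
    }
    build_chain(n, phi.data(), psi.data(), cur.data());
    ok = droplet_ok(cur.data(), n, droplet_radius);
  }
  if (!ok) stop("could not place an initial conformation inside the droplet");

  double ecur[5], enew[5];
  chain_energy(cur.data(), phi.data(), psi.data(), em, ecur);

  NumericMatrix out_phi(nconf, n), out_psi(nconf, n);
  NumericVector out_coords((R_xlen_t)nrow * 3 * nconf);
  NumericVector out_energy(nconf);
  long accepted = 0, accepted_equil = 0;
  const long total = (long)equil_steps + production_steps;
  int rec = 0;

  for (long step = 1; step <= total; ++step) {
    const int r = rng.unif_int(n);
    const double old_phi = phi[r], old_psi = psi[r];
    double ph, ps;
    propose_pair(rng, &basin_w(0, r), ph, ps);
    phi[r] = ph * DEG; psi[r] = ps * DEG;
    build_chain(n, phi.data(), psi.data(), prop.data());
    bool accept = false;
    if (droplet_ok(prop.data(), n, droplet_radius)) {
      chain_energy(prop.data(), phi.data(), psi.data(), em, enew);
      const double de = enew[0] - ecur[0];
      if (de <= 0 || rng.unif() < std::exp(-de * tscale)) accept = true;
    }
    if (accept) {
      std::memcpy(cur.data(), prop.data(), sizeof(double) * nrow * 3);
      std::memcpy(ecur, enew, sizeof(ecur));
      ++accepted;
      if (step <= equil_steps) ++accepted_equil;
    } else {
      phi[r] = old_phi; psi[r] = old_psi;
    }
    if (step == equil_steps && equil_steps > 0 && accepted_equil == 0)
      stop("zero Metropolis acceptance over the entire equilibration phase");
    if (step > equil_steps && (step - equil_steps) % interval == 0) {
      for (int i = 0; i < n; ++i) {
        out_phi(rec, i) = phi[i] / DEG;
        out_psi(rec, i) = psi[i] / DEG;
      }
      double *slab = REAL(out_coords) + (R_xlen_t)rec * nrow * 3;
      // column-major (nrow x 3) slab for this conformation
      for (int rr = 0; rr < nrow; ++rr)
        for (int k = 0; k < 3; ++k) slab[rr + nrow * k] = cur[3 * rr + k];
      out_energy[rec] = ecur[0];
      ++rec;
    }
  }
  out_coords.attr("dim") = IntegerVector::create(nrow, 3, nconf);
  return List::create(_["phi"] = out_phi, _["psi"] = out_psi,
                      _["coords"] = out_coords, _["energy"] = out_energy,
                      _["acceptance_rate"] = (double)accepted / (double)total);
}
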