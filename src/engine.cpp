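// Compiled core of the simulator: hexagonal geometry, three-direction ADI
// diffusion on the masked (moving) domain, explicit reaction and actin
// transport steps, and the Metropolis edge-update sweep with the actin and
// concentration bookkeeping that keeps molecule numbers conserved.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- parameter vector layout (must match .param_order in R/params.R) ----
enum {
  P_TOT_C, P_TOT_R, P_TOT_H, P_BAS_C, P_BAS_R, P_BAS_H,
  P_A_RHO, P_A_CDC, P_N_GTP, P_ALPHA, P_BETA, P_D_GTP,
  P_I_C, P_I_R, P_I_H,
  P_DACT, P_DINACT, P_DPI, P_DARP,
  P_ETA, P_FB_HILL, P_FB_HALF_REL, P_FB_ON_AMP,
  P_BAS_PIP, P_BAS_PIP2, P_BAS_PIP3, P_D_PI, P_K21, P_K3,
  P_K5, P_KPTEN, P_I_PIP, P_RAC2X, P_RHO2X,
  P_KARP, P_KARPC, P_N_ARP, P_P2ARP, P_DARP_DEC,
  P_KNUC, P_KNUCSAT, P_SCFC, P_SCCB, P_VPOLY, P_DF,
  P_KCAP, P_CAPRED, P_CAPLE, P_LEPIP2, P_P2CAP, P_NCAP,
  P_NPAR
};
// cpm vector layout (must match .cpm_vec)
enum {
  C_J, C_LAMA, C_A0, C_LAMP, C_P0, C_HY, C_TEMP, C_LAMC, C_RHOTH,
  C_WF, C_ORDER, C_NCPM
};
// concentration columns
enum { S_CA, S_RA, S_HA, S_CI, S_RI, S_HI, S_P1, S_P2, S_P3, S_ARP, NSP };

// ---------------------------------------------------------------- geometry
static inline int mod(int a, int m) { return ((a % m) + m) % m; }

// [[Rcpp::export]]
List make_geometry_cpp(int nr, int nc) {
  const int n = nr * nc;
  // axial offsets ordered by angle 0,60,...,300
  const int dq[6] = { 1, 0, -1, -1, 0, 1 };
  const int dr[6] = { 0, 1, 1, 0, -1, -1 };
  IntegerMatrix nbr(n, 6);
  for (int r = 0; r < nr; ++r)
    for (int q = 0; q < nc; ++q) {
      int s = r * nc + q;
      for (int k = 0; k < 6; ++k)
        nbr(s, k) = mod(r + dr[k], nr) * nc + mod(q + dq[k], nc);
    }
  // second hex ring (lattice distance 2): 12 offsets
  const int dq2[12] = { 2, 1, 0, -1, -2, -2, -2, -1, 0, 1, 2, 2 };
  const int dr2[12] = { 0, 1, 2, 2, 2, 1, 0, -1, -2, -2, -2, -1 };
  IntegerMatrix nbr2(n, 12);
  for (int r = 0; r < nr; ++r)
    for (int q = 0; q < nc; ++q) {
      int s = r * nc + q;
      for (int k = 0; k < 12; ++k)
        nbr2(s, k) = mod(r + dr2[k], nr) * nc + mod(q + dq2[k], nc);
    }
  // ring decomposition along the three principal axes (directions k = 0,1,2)
  List chains(3);
  for (int a = 0; a < 3; ++a) {
    std::vector<int> order; order.reserve(n);
    std::vector<int> start;
    std::vector<bool> seen(n, false);
    for (int s0 = 0; s0 < n; ++s0) {
      if (seen[s0]) continue;
      start.push_back((int)order.size());
      int s = s0;
      do {
        seen[s] = true;
        order.push_back(s);
        s = nbr(s, a);
      } while (s != s0);
    }
    start.push_back((int)order.size());
    chains[a] = List::create(_["order"] = wrap(order), _["start"] = wrap(start));
  }
  return List::create(_["nbr"] = nbr, _["nbr2"] = nbr2, _["chains"] = chains);
}

// ------------------------------------------------------------- ADI solver
// Implicit solve of (I - alpha * L1d) u = rhs on a no-flux segment (Thomas).
static void thomas_neumann(std::vector<double>& u, double alpha) {
  const int m = (int)u.size();
  if (m == 1 || alpha == 0.0) return;
  static thread_local std::vector<double> c1, d1;
  c1.assign(m, 0.0); d1.assign(m, 0.0);
  // row 0: (1+alpha) u0 - alpha u1
  double b0 = 1.0 + alpha;
  c1[0] = -alpha / b0; d1[0] = u[0] / b0;
  for (int i = 1; i < m; ++i) {
    double bi = (i == m - 1) ? (1.0 + alpha) : (1.0 + 2.0 * alpha);
    double denom = bi + alpha * c1[i - 1];
    c1[i] = -alpha / denom;
    d1[i] = (u[i] + alpha * d1[i - 1]) / denom;
  }
  u[m - 1] = d1[m - 1];
  for (int i = m - 2; i >= 0; --i) u[i] = d1[i] - c1[i] * u[i + 1];
}

// Cyclic (periodic) tridiagonal solve via Sherman-Morrison.
static void thomas_cyclic(std::vector<double>& u, double alpha) {
  const int m = (int)u.size();
  if (m < 3 || alpha == 0.0) { return; }
  const double b = 1.0 + 2.0 * alpha, a = -alpha;
  // modified system per Sherman-Morrison with gamma = -b
  double gamma = -b;
  std::vector<double> bb(m, b), x(u), z(m, 0.0);
  bb[0] = b - gamma; bb[m - 1] = b - a * a / gamma;
  z[0] = gamma; z[m - 1] = a;
  // generic Thomas for variable diagonal
  auto solve = [&](std::vector<double>& rhs) {
    static thread_local std::vector<double> c1, d1;
    c1.assign(m, 0.0); d1.assign(m, 0.0);
    c1[0] = a / bb[0]; d1[0] = rhs[0] / bb[0];
    for (int i = 1; i < m; ++i) {
      double denom = bb[i] - a * c1[i - 1];
      c1[i] = a / denom;
      d1[i] = (rhs[i] - a * d1[i - 1]) / denom;
    }
    rhs[m - 1] = d1[m - 1];
    for (int i = m - 2; i >= 0; --i) rhs[i] = d1[i] - c1[i] * rhs[i + 1];
  };
  solve(x);
  solve(z);
  double fact = (x[0] + a * x[m - 1] / gamma) /
    (1.0 + z[0] + a * z[m - 1] / gamma);
  for (int i = 0; i < m; ++i) u[i] = x[i] - fact * z[i];
}

// one ADI pass along axis a over dt/3 for one field (in place)
static void adi_pass(double* f, const int* mask, double alpha,
                     const int* order, const int* start, int nring) {
  std::vector<double> seg; seg.reserve(512);
  std::vector<int> idx; idx.reserve(512);
  for (int rng = 0; rng < nring; ++rng) {
    int lo = start[rng], hi = start[rng + 1], len = hi - lo;
    // find a site outside the mask to anchor run extraction
    int anchor = -1;
    for (int i = lo; i < hi; ++i)
      if (!mask[order[i]]) { anchor = i; break; }
    if (anchor < 0) {
      // full ring inside the mask: cyclic solve
      seg.clear(); idx.clear();
      for (int i = lo; i < hi; ++i) { idx.push_back(order[i]); seg.push_back(f[order[i]]); }
      thomas_cyclic(seg, alpha);
      for (size_t i = 0; i < idx.size(); ++i) f[idx[i]] = seg[i];
      continue;
    }
    // walk the ring once starting just after the anchor, extracting runs
    seg.clear(); idx.clear();
    for (int step = 1; step <= len; ++step) {
      int i = lo + (anchor - lo + step) % len;
      int s = order[i];
      if (mask[s]) { idx.push_back(s); seg.push_back(f[s]); }
      if ((!mask[s] || step == len) && !idx.empty()) {
        thomas_neumann(seg, alpha);
        for (size_t j2 = 0; j2 < idx.size(); ++j2) f[idx[j2]] = seg[j2];
        seg.clear(); idx.clear();
      }
    }
  }
}

static void adi_field(double* f, const int* mask, double D, double dt,
                      double dx, const List& chains) {
  if (D <= 0.0) return;
  double alpha = 2.0 * D * (dt / 3.0) / (dx * dx);
  for (int a = 0; a < 3; ++a) {
    List ch = chains[a];
    IntegerVector order = ch["order"], start = ch["start"];
    adi_pass(f, mask, alpha, &order[0], &start[0], start.size() - 1);
  }
}

// [[Rcpp::export]]
NumericVector adi_step_cpp(NumericVector field, IntegerVector mask, double D,
                           double dt, double dx, List chains) {
  NumericVector f = clone(field);
  adi_field(&f[0], &mask[0], D, dt, dx, chains);
  return f;
}

// --------------------------------------------------------------- kinetics
static inline double hill_inh(double x, double a, double n) {
  return 1.0 / (1.0 + std::pow(x / a, n));
}
static inline double fb_factor(double p2, const double* p) {
  double eta = p[P_ETA];
  if (eta == 0.0) return 1.0;
  double K = p[P_FB_HALF_REL] * p[P_BAS_PIP2], m = p[P_FB_HILL];
  double Km = std::pow(K, m), bm = std::pow(p[P_BAS_PIP2], m);
  double pm = std::pow(p2, m);
  double S = (pm / (Km + pm)) * (Km + bm) / bm;
  return (1.0 - eta) + eta * S;
}
static inline double cap_rate(double p2, bool le, const double* p) {
  double h = std::pow(p2, p[P_NCAP]);
  double red = p[P_CAPRED] * h / (std::pow(p[P_P2CAP], p[P_NCAP]) + h);
  double k = p[P_KCAP] * (1.0 - red);
  return le ? p[P_CAPLE] * k : k;
}
static inline double arp_act(double ca, double p2, const double* p) {
  double h = std::pow(p2, p[P_N_ARP]);
  double hill = h / (std::pow(p[P_P2ARP], p[P_N_ARP]) + h);
  return (p[P_KARP] + p[P_KARPC] * ca) * hill;
}
static inline double nuc_rate(double arp, double Ftot, const double* p) {
  double x = arp * p[P_SCFC] * Ftot;
  return p[P_KNUC] * p[P_SCCB] * x / (p[P_KNUCSAT] + x);
}

// explicit reaction step for the ten concentration species (in place)
static void reaction_step(NumericMatrix conc, const int* mask, int n,
                          const double* p, double dt, const double* stim,
                          double stim_on) {
  for (int i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    double ca = conc(i, S_CA), ra = conc(i, S_RA), ha = conc(i, S_HA);
    double ci = conc(i, S_CI), ri = conc(i, S_RI), hi = conc(i, S_HI);
    double p1 = conc(i, S_P1), p2 = conc(i, S_P2), p3 = conc(i, S_P3);
    double arp = conc(i, S_ARP);
    double g = fb_factor(p2, p);
    double sm = stim_on > 0.5 ? stim[i] : 1.0;
    double aC = sm * p[P_I_C] * hill_inh(ha, p[P_A_RHO], p[P_N_GTP]) * g;
    double ga = 1.0 + p[P_FB_ON_AMP] * (g - 1.0);
    double aR = p[P_I_R] * g + p[P_ALPHA] * ca * ga;
    double aH = std::max(0.0, p[P_I_H] + p[P_BETA] * ra) *
      hill_inh(ca, p[P_A_CDC], p[P_N_GTP]);
    double dC = aC * ci - p[P_D_GTP] * ca;
    double dR = aR * ri - p[P_D_GTP] * ra;
    double dH = aH * hi - p[P_D_GTP] * ha;
    double fR = 1.0 + ra / p[P_RAC2X], fH = 1.0 + ha / p[P_RHO2X];
    double dP1 = p[P_I_PIP] - p[P_D_PI] * p1 - p[P_K5] * fR * p1 + p[P_K21] * p2;
    double dP2 = p[P_K5] * fR * p1 - (p[P_D_PI] + p[P_K21]) * p2 -
      p[P_K3] * fR * p2 + p[P_KPTEN] * fH * p3;
    double dP3 = p[P_K3] * fR * p2 - p[P_KPTEN] * fH * p3;
    double dA = arp_act(ca, p2, p) - p[P_DARP_DEC] * arp;
    conc(i, S_CA) = std::max(0.0, ca + dt * dC);
    conc(i, S_CI) = std::max(0.0, ci - dt * dC);
    conc(i, S_RA) = std::max(0.0, ra + dt * dR);
    conc(i, S_RI) = std::max(0.0, ri - dt * dR);
    conc(i, S_HA) = std::max(0.0, ha + dt * dH);
    conc(i, S_HI) = std::max(0.0, hi - dt * dH);
    conc(i, S_P1) = std::max(0.0, p1 + dt * dP1);
    conc(i, S_P2) = std::max(0.0, p2 + dt * dP2);
    conc(i, S_P3) = std::max(0.0, p3 + dt * dP3);
    conc(i, S_ARP) = std::max(0.0, arp + dt * dA);
  }
}

// [[Rcpp::export]]
void reaction_step_cpp(NumericMatrix conc, IntegerVector mask,
                       NumericVector pvec, double dt,
                       NumericVector stim, double stim_on) {
  reaction_step(conc, &mask[0], mask.size(), &pvec[0], dt, &stim[0], stim_on);
}

// boundary outward normal from first-order occupancy (nx, ny); returns false
// if the pattern cancels (degenerate)
static bool site_normal(int s, const int* mask, const IntegerMatrix& nbr,
                        const double* evx, const double* evy,
                        double& nx, double& ny) {
  nx = 0.0; ny = 0.0;
  for (int k = 0; k < 6; ++k) {
    int j = nbr(s, k);
    if (!mask[j]) { nx += evx[k]; ny += evy[k]; }
  }
  double nv = std::sqrt(nx * nx + ny * ny);
  if (nv < 1e-12) { nx = 1.0; ny = 0.0; return false; }
  nx /= nv; ny /= nv;
  return true;
}

// explicit actin step: branching, capping, polymerization, upwind barbed-end
// transport with edge flux feeding the pushing pool (in place)
static void actin_step(NumericMatrix Fd, NumericMatrix Bd, NumericMatrix Bp,
                       const NumericMatrix& conc, const int* mask, int n,
                       const IntegerMatrix& nbr, const double* p,
                       const double* cpm, double dt, double dx,
                       const double* evx, const double* evy) {
  const double lam = p[P_VPOLY] * dt / dx;       // advection CFL number
  const double toBp = std::sqrt(3.0) / 2.0 * dx; // per-area -> per-edge-length
  static thread_local std::vector<double> dB;
  dB.assign((size_t)n * 6, 0.0);
  for (int i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    bool boundary = false;
    for (int k = 0; k < 6; ++k) if (!mask[nbr(i, k)]) { boundary = true; break; }
    // leading edge: boundary site with PIP2 above basal (front marker)
    bool le = boundary &&
      conc(i, S_P2) > p[P_LEPIP2] * p[P_BAS_PIP2];
    double Ftot = 0.0;
    for (int k = 0; k < 6; ++k) Ftot += Fd(i, k);
    double nuc = nuc_rate(conc(i, S_ARP), Ftot, p);
    double kc = cap_rate(conc(i, S_P2), le, p);
    for (int k = 0; k < 6; ++k) {
      // branching: daughters split between the classes +-60 deg off mothers
      double gain = 0.0;
      if (Ftot > 0.0)
        gain = 0.5 * nuc * (Fd(i, (k + 5) % 6) + Fd(i, (k + 1) % 6)) / Ftot;
      double b = Bd(i, k);
      double bnew = b + dt * (gain - kc * b);
      if (bnew < 0.0) bnew = 0.0;
      // polymerization builds F from the local barbed ends
      double fnew = Fd(i, k) + dt * (p[P_SCFC] * p[P_VPOLY] * b - p[P_DF] * Fd(i, k));
      Fd(i, k) = fnew > 0.0 ? fnew : 0.0;
      // upwind transport along the class orientation
      double out = lam * bnew;
      dB[(size_t)i * 6 + k] += bnew - out;
      int j = nbr(i, k);
      if (mask[j]) dB[(size_t)j * 6 + k] += out;
      else Bp(i, k) += out * toBp;   // blocked flux becomes pushing ends
      // pushing ends cap at the (leading-edge) reduced rate
      if (Bp(i, k) > 0.0) {
        double bp = Bp(i, k) * (1.0 - dt * kc);
        Bp(i, k) = bp > 0.0 ? bp : 0.0;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    for (int k = 0; k < 6; ++k) Bd(i, k) = dB[(size_t)i * 6 + k];
  }
}

// [[Rcpp::export]]
void actin_step_cpp(NumericMatrix Fd, NumericMatrix Bd, NumericMatrix Bp,
                    NumericMatrix conc, IntegerVector mask, IntegerMatrix nbr1,
                    NumericVector pvec, NumericVector cpmvec,
                    double dt, double dx, NumericVector evx, NumericVector evy) {
  IntegerMatrix nbr0(nbr1.nrow(), 6);
  for (int i = 0; i < nbr1.nrow(); ++i)
    for (int k = 0; k < 6; ++k) nbr0(i, k) = nbr1(i, k) - 1;
  actin_step(Fd, Bd, Bp, conc, &mask[0], mask.size(), nbr0, &pvec[0],
             &cpmvec[0], dt, dx, &evx[0], &evy[0]);
}

// ------------------------------------------------------- Potts shape engine
// mismatch pairs involving site s against occupancy value v
static int mismatches(int s, int v, const int* mask, const IntegerMatrix& nbr,
                      const IntegerMatrix& nbr2, int order) {
  int m = 0;
  for (int k = 0; k < 6; ++k) m += (mask[nbr(s, k)] != v);
  if (order >= 2)
    for (int k = 0; k < 12; ++k) m += (mask[nbr2(s, k)] != v);
  return m;
}

// [[Rcpp::export]]
double hamiltonian_cpp(IntegerVector mask, IntegerMatrix nbr1, IntegerMatrix nbr2_1,
                       NumericVector cpmvec) {
  const double* cpm = &cpmvec[0];
  int n = mask.size();
  long pairs = 0, perim = 0, area = 0;
  for (int s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    ++area;
    for (int k = 0; k < 6; ++k) {
      int j = nbr1(s, k) - 1;
      if (!mask[j]) { ++pairs; ++perim; }
    }
    if ((int)cpm[C_ORDER] >= 2)
      for (int k = 0; k < 12; ++k) {
        int j = nbr2_1(s, k) - 1;
        if (!mask[j]) ++pairs;
      }
  }
  if (area == 0) return 0.0;
  double da = area - cpm[C_A0], dp = perim - cpm[C_P0];
  return cpm[C_J] * pairs + cpm[C_LAMA] * da * da + cpm[C_LAMP] * dp * dp;
}

struct McsLog {
  int acc_prot = 0, acc_retr = 0, proposals = 0;
};

// single Metropolis sweep; updates mask/conc/actin in place
static void mcs_sweep(int* mask, const int* obstacle, NumericMatrix conc,
                      NumericMatrix Fd, NumericMatrix Bd, NumericMatrix Bp,
                      const IntegerMatrix& nbr, const IntegerMatrix& nbr2,
                      const double* cpm, double dx,
                      long& area, long& perim, long& pairs,
                      const double* evx, const double* evy,
                      int edge_scheme, McsLog& log) {
  const int n = conc.nrow();
  const int order = (int)cpm[C_ORDER];
  const double asite = std::sqrt(3.0) / 2.0 * dx * dx;
  static thread_local std::vector<int> idx;
  idx.resize(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = n - 1; i > 0; --i) {     // Fisher-Yates with the run's RNG
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
  for (int ii = 0; ii < n; ++ii) {
    int s = idx[ii];
    // only sites adjacent to the interface can change
    int occn = 0;
    for (int k = 0; k < 6; ++k) occn += mask[nbr(s, k)];
    if (mask[s] ? occn == 6 : occn == 0) continue;
    int k = (int)std::floor(unif_rand() * 6.0);
    if (k > 5) k = 5;
    int t = nbr(s, k);
    if (mask[t] == mask[s]) continue;
    bool prot = mask[s] == 0;           // copying an occupied neighbour into s
    if (prot && obstacle[s]) continue;  // obstacle sites can never be occupied
    if (!prot && area <= 1) continue;
    ++log.proposals;
    // Hamiltonian change
    int newv = 1 - mask[s];
    int mm_old = mismatches(s, mask[s], mask, nbr, nbr2, order);
    int mm_new = mismatches(s, newv, mask, nbr, nbr2, order);
    long dpairs = mm_new - mm_old;
    int dp1 = 0;
    for (int kk = 0; kk < 6; ++kk) {
      int j = nbr(s, kk);
      dp1 += (mask[j] != newv) - (mask[j] != mask[s]);
    }
    double da_term = prot
      ? cpm[C_LAMA] * (2.0 * (area - cpm[C_A0]) + 1.0)
      : cpm[C_LAMA] * (-2.0 * (area - cpm[C_A0]) + 1.0);
    double dp_term = cpm[C_LAMP] * (2.0 * (perim - cpm[C_P0]) * dp1 + (double)dp1 * dp1);
    double dH = cpm[C_J] * dpairs + da_term + dp_term;
    // force bias: pushing ends favour protrusion, Rho contraction retraction
    double bias = 0.0;
    if (prot) {
      // ends at the source pixel t pushing toward s
      int kts = (k + 3) % 6;            // direction t -> s
      double push = 0.0;
      for (int kk = 0; kk < 6; ++kk) {
        double d = evx[kk] * evx[kts] + evy[kk] * evy[kts];
        if (d > 0) push += Bp(t, kk) * d;
      }
      double con = cpm[C_LAMC] * std::max(0.0, conc(t, S_HA) - cpm[C_RHOTH]);
      bias = push - con;
    } else {
      // ends at s pushing toward the empty target resist, Rho pulls inward
      double push = 0.0;
      for (int kk = 0; kk < 6; ++kk) {
        double d = evx[kk] * evx[k] + evy[kk] * evy[k];
        if (d > 0) push += Bp(s, kk) * d;
      }
      double con = cpm[C_LAMC] * std::max(0.0, conc(s, S_HA) - cpm[C_RHOTH]);
      bias = con - push;
    }
    double dHt = dH - cpm[C_WF] * bias;
    bool accept;
    if (dHt <= -cpm[C_HY]) accept = true;
    else accept = unif_rand() < std::exp(-(dHt + cpm[C_HY]) / cpm[C_TEMP]);
    if (!accept) continue;
    // ---- commit ----
    mask[s] = newv;
    pairs += dpairs;
    perim += dp1;
    if (prot) {
      ++log.acc_prot; ++area;
      // concentrations at the new pixel
      for (int c = 0; c < NSP; ++c) {
        if (edge_scheme == 0) conc(s, c) = conc(t, c);            // copy
        else if (edge_scheme == 1) conc(s, c) = 0.0;              // heap
        else { conc(s, c) = conc(t, c) / 2.0; conc(t, c) /= 2.0; } // split
      }
      // actin starts empty at the new pixel
      for (int kk = 0; kk < 6; ++kk) { Fd(s, kk) = 0; Bd(s, kk) = 0; Bp(s, kk) = 0; }
      // pushing ends whose outlet was covered are demoted to free ends
      for (int kk = 0; kk < 6; ++kk) {
        int j = nbr(s, kk);
        if (!mask[j]) continue;
        int kjs = (kk + 3) % 6;         // direction j -> s
        if (Bp(j, kjs) > 0.0) {
          Bd(j, kjs) += Bp(j, kjs) * dx / asite;
          Bp(j, kjs) = 0.0;
        }
      }
    } else {
      ++log.acc_retr; --area;
      // pile actin up on the occupied neighbours, orientations preserved;
      // ends whose outlet at the receiving site is open become pushing ends
      int recv[6], nr_ = 0;
      for (int kk = 0; kk < 6; ++kk) if (mask[nbr(s, kk)]) recv[nr_++] = nbr(s, kk);
      if (nr_ > 0) {
        double share = 1.0 / nr_;
        for (int kk = 0; kk < 6; ++kk) {
          double fmass = Fd(s, kk) * share;
          double bmass = (Bd(s, kk) + Bp(s, kk) * dx / asite) * share;
          for (int rj = 0; rj < nr_; ++rj) {
            int j = recv[rj];
            Fd(j, kk) += fmass;
            if (!mask[nbr(j, kk)]) Bp(j, kk) += bmass * asite / dx;
            else Bd(j, kk) += bmass;
          }
        }
      }
      for (int kk = 0; kk < 6; ++kk) { Fd(s, kk) = 0; Bd(s, kk) = 0; Bp(s, kk) = 0; }
      // default scheme discards the pixel's concentrations (renormalization
      // restores the totals); the alternative schemes heap them up locally
      if (edge_scheme != 0 && nr_ > 0) {
        for (int c = 0; c < NSP; ++c) {
          double m = conc(s, c) / nr_;
          for (int rj = 0; rj < nr_; ++rj) conc(recv[rj], c) += m;
        }
      }
      for (int c = 0; c < NSP; ++c) conc(s, c) = 0.0;
      // a neighbour whose outlet toward s opened keeps its free ends; the
      // advection step promotes them when their flux hits the new edge
    }
  }
}

// largest-component relabelling; returns number of components
static int keep_largest_component(int* mask, const IntegerMatrix& nbr, int n,
                                  NumericMatrix conc, NumericMatrix Fd,
                                  NumericMatrix Bd, NumericMatrix Bp) {
  std::vector<int> lab(n, 0);
  std::vector<int> stack;
  int ncomp = 0;
  std::vector<int> size;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++ncomp;
    int sz = 0;
    stack.push_back(s); lab[s] = ncomp;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back(); ++sz;
      for (int k = 0; k < 6; ++k) {
        int j = nbr(u, k);
        if (mask[j] && !lab[j]) { lab[j] = ncomp; stack.push_back(j); }
      }
    }
    size.push_back(sz);
  }
  if (ncomp <= 1) return ncomp;
  int best = 1;
  for (int c = 2; c <= ncomp; ++c) if (size[c - 1] > size[best - 1]) best = c;
  for (int s = 0; s < n; ++s) {
    if (mask[s] && lab[s] != best) {
      mask[s] = 0;
      for (int c = 0; c < NSP; ++c) conc(s, c) = 0.0;
      for (int k = 0; k < 6; ++k) { Fd(s, k) = 0; Bd(s, k) = 0; Bp(s, k) = 0; }
    }
  }
  return ncomp;
}

// [[Rcpp::export]]
IntegerVector components_cpp(IntegerVector mask, IntegerMatrix nbr0) {
  int n = mask.size();
  std::vector<int> lab(n, 0), stack, size;
  int ncomp = 0;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++ncomp; int sz = 0;
    stack.push_back(s); lab[s] = ncomp;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back(); ++sz;
      for (int k = 0; k < 6; ++k) {
        int j = nbr0(u, k);
        if (mask[j] && !lab[j]) { lab[j] = ncomp; stack.push_back(j); }
      }
    }
    size.push_back(sz);
  }
  // relabel so that 1 = largest
  std::vector<int> ord(ncomp);
  for (int c = 0; c < ncomp; ++c) ord[c] = c + 1;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return size[a - 1] > size[b - 1];
  });
  std::vector<int> newlab(ncomp + 1, 0);
  for (int r = 0; r < ncomp; ++r) newlab[ord[r]] = r + 1;
  IntegerVector out(n);
  for (int s = 0; s < n; ++s) out[s] = mask[s] ? newlab[lab[s]] : 0;
  return out;
}

// ----------------------------------------------------------- main stepper
// [[Rcpp::export]]
List advance_cpp(List state, List geom, NumericVector pvec, NumericVector cpmvec,
                 List ctrl) {
  NumericMatrix conc = state["conc"];
  NumericMatrix Fd = state["F"], Bd = state["B"], Bp = state["Bp"];
  IntegerVector maskv = state["mask"], obstaclev = state["obstacle"];
  IntegerMatrix nbr1 = geom["nbr"];      // 0-based from make_geometry_cpp
  IntegerMatrix nbr2 = geom["nbr2"];
  List chains = geom["chains"];
  const double* p = &pvec[0];
  const double* cpm = &cpmvec[0];
  const int n = conc.nrow();
  int* mask = &maskv[0];
  const int* obstacle = &obstaclev[0];

  const int nsteps = as<int>(ctrl["nsteps"]);
  const double dt = as<double>(ctrl["dt"]);
  const double dx = as<double>(ctrl["dx"]);
  double t = as<double>(ctrl["t0"]);
  const bool frozen = as<bool>(ctrl["frozen"]);
  const bool do_reaction = as<bool>(ctrl["do_reaction"]);
  const bool do_diffusion = as<bool>(ctrl["do_diffusion"]);
  const bool do_actin = as<bool>(ctrl["do_actin"]);
  NumericVector stim = ctrl["stim_field"];
  const double stim_t0 = as<double>(ctrl["stim_t0"]);
  const double stim_t1 = as<double>(ctrl["stim_t1"]);
  const double guard = as<double>(ctrl["renorm_guard"]);
  const bool strict = as<bool>(ctrl["strict_guard"]);

  double evx[6], evy[6];
  for (int k = 0; k < 6; ++k) {
    evx[k] = std::cos(k * M_PI / 3.0);
    evy[k] = std::sin(k * M_PI / 3.0);
  }
  // running geometry tallies
  long area = 0, perim = 0, pairs = 0;
  for (int s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    ++area;
    for (int k = 0; k < 6; ++k) if (!mask[nbr1(s, k)]) { ++perim; ++pairs; }
    if ((int)cpm[C_ORDER] >= 2)
      for (int k = 0; k < 12; ++k) if (!mask[nbr2(s, k)]) ++pairs;
  }
  const double Dcol[NSP] = { p[P_DACT], p[P_DACT], p[P_DACT],
                             p[P_DINACT], p[P_DINACT], p[P_DINACT],
                             p[P_DPI], p[P_DPI], p[P_DPI], p[P_DARP] };
  NumericVector renorm_max(nsteps);
  IntegerVector acc_prot(nsteps), acc_retr(nsteps);
  int frag_events = 0;
  double worst_renorm = 0.0;
  std::vector<double> tot_before(NSP);

  for (int step = 0; step < nsteps; ++step) {
    double stim_on = (t >= stim_t0 && t < stim_t1) ? 1.0 : 0.0;
    if (do_reaction)
      reaction_step(conc, mask, n, p, dt, &stim[0], stim_on);
    if (do_actin)
      actin_step(Fd, Bd, Bp, conc, mask, n, nbr1, p, cpm, dt, dx, evx, evy);
    if (do_diffusion) {
      double* base = conc.begin();
      for (int c = 0; c < NSP; ++c)
        adi_field(base + (size_t)c * n, mask, Dcol[c], dt, dx, chains);
    }
    double rmax = 0.0;
    if (!frozen) {
      for (int c = 0; c < NSP; ++c) {
        double tot = 0.0;
        for (int s = 0; s < n; ++s) if (mask[s]) tot += conc(s, c);
        tot_before[c] = tot;
      }
      McsLog log;
      mcs_sweep(mask, obstacle, conc, Fd, Bd, Bp, nbr1, nbr2, cpm, dx,
                area, perim, pairs, evx, evy,
                as<int>(ctrl["edge_scheme"]), log);
      acc_prot[step] = log.acc_prot;
      acc_retr[step] = log.acc_retr;
      // fragmentation: keep the largest component, log the event
      if (log.acc_retr > 0) {
        int nc = keep_largest_component(mask, nbr1, n, conc, Fd, Bd, Bp);
        if (nc > 1) {
          ++frag_events;
          // geometry tallies must be rebuilt after losing a fragment
          area = 0; perim = 0; pairs = 0;
          for (int s = 0; s < n; ++s) {
            if (!mask[s]) continue;
            ++area;
            for (int k = 0; k < 6; ++k) if (!mask[nbr1(s, k)]) { ++perim; ++pairs; }
            if ((int)cpm[C_ORDER] >= 2)
              for (int k = 0; k < 12; ++k) if (!mask[nbr2(s, k)]) ++pairs;
          }
        }
      }
      // renormalize every concentration species to its pre-sweep total
      for (int c = 0; c < NSP; ++c) {
        double tot = 0.0;
        for (int s = 0; s < n; ++s) if (mask[s]) tot += conc(s, c);
        if (tot > 0.0 && tot_before[c] > 0.0) {
          double f = tot_before[c] / tot;
          if (std::abs(f - 1.0) > rmax) rmax = std::abs(f - 1.0);
          for (int s = 0; s < n; ++s) if (mask[s]) conc(s, c) *= f;
        }
      }
      if (rmax > worst_renorm) worst_renorm = rmax;
      if (strict && rmax > guard)
        stop("mass-conservation correction %g exceeded the guard %g; "
             "use a smaller timestep or finer grid", rmax, guard);
    }
    renorm_max[step] = rmax;
    t += dt;
  }
  return List::create(
    _["t"] = t, _["renorm_max"] = renorm_max,
    _["worst_renorm"] = worst_renorm,
    _["acc_prot"] = acc_prot, _["acc_retr"] = acc_retr,
    _["frag_events"] = frag_events,
    _["area"] = (double)area, _["perimeter"] = (double)perim);
}
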