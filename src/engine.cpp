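// DPD engine: pairwise soft-repulsion + pair thermostat, wormlike-chain /
// power-law membrane elasticity, bending, global area/volume constraints,
// membrane pair viscosity, harmonic bonds/angles, cosine torsions, frozen
// walls with bounce-back reflection on signed distance functions, and a
// modified velocity-Verlet integrator (lambda = 1/2).
//
// Positions are kept unwrapped; the minimum-image convention is applied in
// every pairwise distance, and wall SDFs wrap coordinates internally.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>
using namespace Rcpp;

static const int NTYPE = 5; // fluid=1 filament=2 membrane=3 nucleus=4 wall=5

// ---------------------------------------------------------------- utilities

struct Box {
  double L[3];
  double invL[3];
  bool per[3];
  inline void minimg(double* d) const {
    for (int k = 0; k < 3; ++k)
      if (per[k] && L[k] > 0) {
        double q = d[k] * invL[k];
        d[k] -= L[k] * (double)(long long)(q + (q >= 0 ? 0.5 : -0.5));
      }
  }
  inline double wrap(double x, int k) const {
    if (!per[k] || L[k] <= 0) return x;
    double w = x - L[k] * std::floor(x / L[k]);
    if (w >= L[k]) w -= L[k];
    return w;
  }
};

static Box parse_box(const NumericVector& box, const LogicalVector& periodic) {
  Box b;
  for (int k = 0; k < 3; ++k) {
    b.L[k] = box[k];
    b.invL[k] = box[k] > 0 ? 1.0 / box[k] : 0.0;
    b.per[k] = periodic[k];
  }
  return b;
}

struct RNG {
  std::mt19937_64 eng;
  std::normal_distribution<double> nd{0.0, 1.0};
  explicit RNG(uint64_t seed) : eng(seed) {}
  inline double normal() { return nd(eng); }
  inline double unif() {
    return std::uniform_real_distribution<double>(0.0, 1.0)(eng);
  }
  // zero-mean unit-variance uniform variate: the standard fast choice for
  // the DPD pair noise (only the first two moments matter for the
  // thermostat)
  inline double pair_noise() {
    double u = (eng() >> 11) * 1.1102230246251565e-16; // [0,1)
    return 3.4641016151377544 * (u - 0.5);
  }
};

// w_R(r) = (1 - r/rc)^s ; s = 0.25 fast-pathed as two square roots
static inline double weight_wR(double one_minus, double s) {
  if (s == 0.25) return std::sqrt(std::sqrt(one_minus));
  if (s == 0.5) return std::sqrt(one_minus);
  if (s == 1.0) return one_minus;
  return std::pow(one_minus, s);
}

// ------------------------------------------------------------ SDF primitives

struct SDFPrim {
  int kind; // 1 slab, 2 pipette, 3 pillar row
  double p[8];
};

struct SDF {
  std::vector<SDFPrim> prims;
  // positive inside solid, negative in fluid (approximate distance)
  double eval(double x, double y, double z, const Box& bx) const {
    if (prims.empty()) return -1e30;
    double s = -1e30;
    for (const auto& pr : prims) {
      double v = -1e30;
      if (pr.kind == 1) { // slab: solid outside [lo,hi] along axis
        int ax = (int)pr.p[0];
        double c = (ax == 0 ? x : (ax == 1 ? y : z));
        v = std::max(pr.p[1] - c, c - pr.p[2]);
      } else if (pr.kind == 2) { // pipette: annular tube, axis +x from x0
        double x0 = pr.p[0], Rp = pr.p[1], tw = pr.p[2], cy = pr.p[3],
               cz = pr.p[4];
        double rho = std::sqrt((y - cy) * (y - cy) + (z - cz) * (z - cz));
        double m1 = x - x0, m2 = rho - Rp, m3 = Rp + tw - rho;
        v = std::min(m1, std::min(m2, m3));
      } else if (pr.kind == 3) { // equilateral pillar, apex upstream (-x),
                                 // replicated with period p[3] along y
        double xc = pr.p[0], yc = pr.p[1], side = pr.p[2], period = pr.p[3];
        double h = 0.8660254037844386 * side; // sqrt(3)/2 * side
        double dx = x - xc;
        double dy = y - yc;
        if (period > 0) dy -= period * std::round(dy / period);
        // triangle with apex at (-2h/3, 0), base corners (h/3, +-side/2)
        // margins of the three inward half-planes (positive inside)
        double m1 = h / 3.0 - dx; // base edge at dx = h/3, inward -x
        // slanted edges: from apex (-2h/3,0) to (h/3, +-side/2)
        // inward normals (pointing to triangle interior)
        double ex = h, ey = side / 2.0, el = std::sqrt(ex * ex + ey * ey);
        // upper edge normal (pointing down-right interior): (ey, -ex)/el
        double m2 = (ey * (dx + 2.0 * h / 3.0) - ex * dy) / el;
        double m3 = (ey * (dx + 2.0 * h / 3.0) + ex * dy) / el;
        v = std::min(m1, std::min(m2, m3));
      }
      s = std::max(s, v);
    }
    return s;
  }
};

static SDF parse_sdf(SEXP sdfspec) {
  SDF s;
  if (Rf_isNull(sdfspec)) return s;
  List lst(sdfspec);
  for (int i = 0; i < lst.size(); ++i) {
    List pr(lst[i]);
    std::string kind = as<std::string>(pr["kind"]);
    SDFPrim q{};
    if (kind == "slab") {
      q.kind = 1;
      q.p[0] = as<double>(pr["axis"]) - 1; // R axis 1..3
      q.p[1] = as<double>(pr["lo"]);
      q.p[2] = as<double>(pr["hi"]);
    } else if (kind == "pipette") {
      q.kind = 2;
      q.p[0] = as<double>(pr["x0"]);
      q.p[1] = as<double>(pr["radius"]);
      q.p[2] = as<double>(pr["thickness"]);
      q.p[3] = as<double>(pr["cy"]);
      q.p[4] = as<double>(pr["cz"]);
    } else if (kind == "pillars") {
      q.kind = 3;
      q.p[0] = as<double>(pr["xc"]);
      q.p[1] = as<double>(pr["yc"]);
      q.p[2] = as<double>(pr["side"]);
      q.p[3] = as<double>(pr["period"]);
    } else {
      stop("unknown SDF primitive kind: %s", kind.c_str());
    }
    s.prims.push_back(q);
  }
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_sdf_eval(SEXP sdfspec, NumericMatrix pts, NumericVector box,
                           LogicalVector periodic) {
  SDF s = parse_sdf(sdfspec);
  Box bx = parse_box(box, periodic);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = s.eval(bx.wrap(pts(i, 0), 0), bx.wrap(pts(i, 1), 1),
                    bx.wrap(pts(i, 2), 2), bx);
  return out;
}

// ---------------------------------------------------------- neighbour lists

static void cell_pairs(const double* r, int n, const Box& bx, double cutoff,
                       std::vector<std::pair<int, int>>& pairs) {
  pairs.clear();
  int nb[3];
  double bw[3], lo[3];
  bool gridded = true;
  for (int k = 0; k < 3; ++k) {
    if (bx.per[k]) {
      lo[k] = 0.0;
      nb[k] = std::max(1, (int)std::floor(bx.L[k] / cutoff));
      bw[k] = bx.L[k] / nb[k];
      if (nb[k] < 3) gridded = false; // too few cells for minimum image grid
    } else {
      double mn = 1e30, mxv = -1e30;
      for (int i = 0; i < n; ++i) {
        mn = std::min(mn, r[3 * i + k]);
        mxv = std::max(mxv, r[3 * i + k]);
      }
      lo[k] = mn - 1e-9;
      double span = std::max(mxv - mn + 2e-9, cutoff);
      nb[k] = std::max(1, (int)std::floor(span / cutoff));
      bw[k] = span / nb[k];
    }
  }
  if (!gridded || (double)nb[0] * nb[1] * nb[2] > 5e7) {
    // fall back to O(n^2)
    double c2 = cutoff * cutoff;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double d[3] = {r[3 * i] - r[3 * j], r[3 * i + 1] - r[3 * j + 1],
                       r[3 * i + 2] - r[3 * j + 2]};
        bx.minimg(d);
        if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] < c2)
          pairs.emplace_back(i, j);
      }
    return;
  }
  size_t ncell = (size_t)nb[0] * nb[1] * nb[2];
  std::vector<int> head(ncell, -1), nxt(n, -1), cidx(n);
  for (int i = 0; i < n; ++i) {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      double x = bx.per[k] ? bx.wrap(r[3 * i + k], k) : r[3 * i + k] - lo[k];
      int ci = (int)std::floor(x / bw[k]);
      c[k] = std::min(nb[k] - 1, std::max(0, ci));
    }
    int cc = (c[0] * nb[1] + c[1]) * nb[2] + c[2];
    cidx[i] = cc;
    nxt[i] = head[cc];
    head[cc] = i;
  }
  double c2 = cutoff * cutoff;
  for (int cx = 0; cx < nb[0]; ++cx)
    for (int cy = 0; cy < nb[1]; ++cy)
      for (int cz = 0; cz < nb[2]; ++cz) {
        int cc = (cx * nb[1] + cy) * nb[2] + cz;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              int ex = cx + dx, ey = cy + dy, ez = cz + dz;
              if (bx.per[0]) ex = (ex + nb[0]) % nb[0];
              if (bx.per[1]) ey = (ey + nb[1]) % nb[1];
              if (bx.per[2]) ez = (ez + nb[2]) % nb[2];
              if (ex < 0 || ey < 0 || ez < 0 || ex >= nb[0] || ey >= nb[1] ||
                  ez >= nb[2])
                continue;
              int dd = (ex * nb[1] + ey) * nb[2] + ez;
              if (dd < cc) continue; // visit each cell pair once
              for (int i = head[cc]; i >= 0; i = nxt[i])
                for (int j = head[dd]; j >= 0; j = nxt[j]) {
                  if (dd == cc && j <= i) continue;
                  double d[3] = {r[3 * i] - r[3 * j],
                                 r[3 * i + 1] - r[3 * j + 1],
                                 r[3 * i + 2] - r[3 * j + 2]};
                  bx.minimg(d);
                  if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] < c2)
                    pairs.emplace_back(std::min(i, j), std::max(i, j));
                }
            }
      }
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, NumericVector box,
                                 LogicalVector periodic, double cutoff) {
  Box bx = parse_box(box, periodic);
  int n = pos.nrow();
  std::vector<double> r(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) r[3 * i + k] = pos(i, k);
  std::vector<std::pair<int, int>> pairs;
  cell_pairs(r.data(), n, bx, cutoff, pairs);
  IntegerMatrix out(pairs.size(), 2);
  for (size_t q = 0; q < pairs.size(); ++q) {
    out(q, 0) = pairs[q].first + 1;
    out(q, 1) = pairs[q].second + 1;
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_brute_pairs(NumericMatrix pos, NumericVector box,
                              LogicalVector periodic, double cutoff) {
  Box bx = parse_box(box, periodic);
  int n = pos.nrow();
  std::vector<std::pair<int, int>> pairs;
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d[3] = {pos(i, 0) - pos(j, 0), pos(i, 1) - pos(j, 1),
                     pos(i, 2) - pos(j, 2)};
      bx.minimg(d);
      if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] < c2)
        pairs.emplace_back(i, j);
    }
  IntegerMatrix out(pairs.size(), 2);
  for (size_t q = 0; q < pairs.size(); ++q) {
    out(q, 0) = pairs[q].first + 1;
    out(q, 1) = pairs[q].second + 1;
  }
  return out;
}

// cross-set proximity pairs (binding queries during assembly)
// [[Rcpp::export]]
List cpp_pairs_between(NumericMatrix A, NumericMatrix B, double cutoff,
                       NumericVector box, LogicalVector periodic) {
  Box bx = parse_box(box, periodic);
  int na = A.nrow(), nbr = B.nrow();
  std::vector<int> ia, ib;
  std::vector<double> dd;
  double c2 = cutoff * cutoff;
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nbr; ++j) {
      double d[3] = {A(i, 0) - B(j, 0), A(i, 1) - B(j, 1), A(i, 2) - B(j, 2)};
      bx.minimg(d);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 < c2) {
        ia.push_back(i + 1);
        ib.push_back(j + 1);
        dd.push_back(std::sqrt(r2));
      }
    }
  return List::create(_["i"] = wrap(ia), _["j"] = wrap(ib),
                      _["dist"] = wrap(dd));
}

// --------------------------------------------------------------- DPD tables

struct PairTable {
  double a[NTYPE + 1][NTYPE + 1];
  double g[NTYPE + 1][NTYPE + 1];
  double rcrep[NTYPE + 1][NTYPE + 1];
  double rcth[NTYPE + 1][NTYPE + 1];
  double invrep[NTYPE + 1][NTYPE + 1];
  double invth[NTYPE + 1][NTYPE + 1];
  double rcmax2[NTYPE + 1][NTYPE + 1];
  double sexp;
  double maxcut;
  double sig[NTYPE + 1][NTYPE + 1]; // filled once kBT is known
};

static PairTable parse_table(const List& tb, double kBT) {
  PairTable T{};
  NumericMatrix a = tb["a"], g = tb["gamma"], r1 = tb["rc_rep"],
                r2 = tb["rc_th"];
  T.sexp = as<double>(tb["s"]);
  T.maxcut = 0;
  for (int i = 1; i <= NTYPE; ++i)
    for (int j = 1; j <= NTYPE; ++j) {
      T.a[i][j] = a(i - 1, j - 1);
      T.g[i][j] = g(i - 1, j - 1);
      T.rcrep[i][j] = r1(i - 1, j - 1);
      T.rcth[i][j] = r2(i - 1, j - 1);
      T.invrep[i][j] = T.rcrep[i][j] > 0 ? 1.0 / T.rcrep[i][j] : 0.0;
      T.invth[i][j] = T.rcth[i][j] > 0 ? 1.0 / T.rcth[i][j] : 0.0;
      double rc = std::max(T.rcrep[i][j], T.rcth[i][j]);
      T.rcmax2[i][j] = rc * rc;
      T.sig[i][j] = std::sqrt(2.0 * T.g[i][j] * kBT);
      if (!(i == NTYPE && j == NTYPE))
        T.maxcut = std::max(T.maxcut,
                            std::max(T.rcrep[i][j], T.rcth[i][j]));
    }
  return T;
}

// pairwise DPD forces over a pair list; one symmetric noise per pair per call
static void dpd_pair_kernel(const double* r, const double* v, const int* type,
                            const char* frozen, const PairTable& T,
                            const Box& bx, double kBT, double invsqrtdt,
                            const std::vector<std::pair<int, int>>& pairs,
                            RNG* rng, double* F) {
  for (const auto& pr : pairs) {
    int i = pr.first, j = pr.second;
    int ti = type[i], tj = type[j];
    if (frozen[i] && frozen[j]) continue; // wall-wall excluded
    double aij = T.a[ti][tj], gij = T.g[ti][tj];
    double rrep = T.rcrep[ti][tj], rth = T.rcth[ti][tj];
    if (aij == 0 && gij == 0) continue;
    double d[3] = {r[3 * i] - r[3 * j], r[3 * i + 1] - r[3 * j + 1],
                   r[3 * i + 2] - r[3 * j + 2]};
    bx.minimg(d);
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    if (r2 >= T.rcmax2[ti][tj]) continue;
    double rij = std::sqrt(r2);
    if (rij < 1e-12) stop("degenerate pair: particles %d and %d coincide",
                          i + 1, j + 1);
    double invr = 1.0 / rij;
    double e[3] = {d[0] * invr, d[1] * invr, d[2] * invr};
    double fmag = 0.0;
    if (aij != 0 && rij < rrep) fmag += aij * (1.0 - rij * T.invrep[ti][tj]);
    if (gij != 0 && rij < rth) {
      double w = weight_wR(1.0 - rij * T.invth[ti][tj], T.sexp);
      double vij[3] = {v[3 * i] - v[3 * j], v[3 * i + 1] - v[3 * j + 1],
                       v[3 * i + 2] - v[3 * j + 2]};
      double rv = e[0] * vij[0] + e[1] * vij[1] + e[2] * vij[2];
      fmag += -gij * (w * w) * rv;
      if (rng)
        fmag += T.sig[ti][tj] * w * rng->pair_noise() * invsqrtdt;
    }
    for (int k = 0; k < 3; ++k) {
      F[3 * i + k] += fmag * e[k];
      F[3 * j + k] -= fmag * e[k];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_pair_forces(NumericMatrix pos, NumericMatrix vel,
                              IntegerVector types, LogicalVector frozen,
                              List table, NumericVector box,
                              LogicalVector periodic, double kBT, double dt,
                              double seed, bool with_random) {
  Box bx = parse_box(box, periodic);
  PairTable T = parse_table(table, kBT);
  int n = pos.nrow();
  std::vector<double> r(3 * n), v(3 * n), F(3 * n, 0.0);
  std::vector<int> type(n);
  std::vector<char> froz(n);
  for (int i = 0; i < n; ++i) {
    type[i] = types[i];
    froz[i] = frozen[i] ? 1 : 0;
    for (int k = 0; k < 3; ++k) {
      r[3 * i + k] = pos(i, k);
      v[3 * i + k] = vel(i, k);
    }
  }
  std::vector<std::pair<int, int>> pairs;
  cell_pairs(r.data(), n, bx, T.maxcut, pairs);
  RNG rng((uint64_t)seed);
  dpd_pair_kernel(r.data(), v.data(), type.data(), froz.data(), T, bx, kBT,
                  1.0 / std::sqrt(dt), pairs, with_random ? &rng : nullptr,
                  F.data());
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = F[3 * i + k];
  return out;
}

// ------------------------------------------------------------- mesh kernels

// WLC tension dU/dl for x = l/lmax
static inline double wlc_dUdl(double x, double lmax, double p, double kBT) {
  double om = 1.0 - x;
  return kBT / (4.0 * p) * (6.0 * x - 9.0 * x * x + 4.0 * x * x * x) /
         (om * om);
}

static inline double wlc_energy(double l, double lmax, double p, double kBT) {
  double x = l / lmax;
  return kBT * lmax / (4.0 * p) * (3.0 * x * x - 2.0 * x * x * x) / (1.0 - x);
}

// gradient of triangle area w.r.t. its three vertices; returns area
static inline double tri_area_grad(const double* ra, const double* rb,
                                   const double* rc, double* ga, double* gb,
                                   double* gc) {
  double u[3] = {rb[0] - ra[0], rb[1] - ra[1], rb[2] - ra[2]};
  double w[3] = {rc[0] - ra[0], rc[1] - ra[1], rc[2] - ra[2]};
  double nvec[3] = {u[1] * w[2] - u[2] * w[1], u[2] * w[0] - u[0] * w[2],
                    u[0] * w[1] - u[1] * w[0]};
  double nn = std::sqrt(nvec[0] * nvec[0] + nvec[1] * nvec[1] +
                        nvec[2] * nvec[2]);
  if (nn < 1e-14) stop("degenerate (zero-area) triangle");
  double A = 0.5 * nn;
  double nh[3] = {nvec[0] / nn, nvec[1] / nn, nvec[2] / nn};
  // dA/dr_a = 0.5 * nh x (rc - rb), cyclic
  double ebc[3] = {rc[0] - rb[0], rc[1] - rb[1], rc[2] - rb[2]};
  double eca[3] = {ra[0] - rc[0], ra[1] - rc[1], ra[2] - rc[2]};
  double eab[3] = {rb[0] - ra[0], rb[1] - ra[1], rb[2] - ra[2]};
  ga[0] = 0.5 * (nh[1] * ebc[2] - nh[2] * ebc[1]);
  ga[1] = 0.5 * (nh[2] * ebc[0] - nh[0] * ebc[2]);
  ga[2] = 0.5 * (nh[0] * ebc[1] - nh[1] * ebc[0]);
  gb[0] = 0.5 * (nh[1] * eca[2] - nh[2] * eca[1]);
  gb[1] = 0.5 * (nh[2] * eca[0] - nh[0] * eca[2]);
  gb[2] = 0.5 * (nh[0] * eca[1] - nh[1] * eca[0]);
  gc[0] = 0.5 * (nh[1] * eab[2] - nh[2] * eab[1]);
  gc[1] = 0.5 * (nh[2] * eab[0] - nh[0] * eab[2]);
  gc[2] = 0.5 * (nh[0] * eab[1] - nh[1] * eab[0]);
  return A;
}

static void wlc_pow_kernel(const double* r, const int* ei, const int* ej,
                           const double* l0, const double* lmax, int ne,
                           const int* ta, const int* tb, const int* tc,
                           const double* C1, int nt, double p, double kBT,
                           const Box& bx, double* F, double* U) {
  for (int q = 0; q < ne; ++q) {
    int i = ei[q], j = ej[q];
    double d[3] = {r[3 * i] - r[3 * j], r[3 * i + 1] - r[3 * j + 1],
                   r[3 * i + 2] - r[3 * j + 2]};
    bx.minimg(d);
    double l = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    double x = l / lmax[q];
    if (x >= 1.0)
      stop("overstretched WLC edge %d (l = %.4f >= lmax = %.4f)", q + 1, l,
           lmax[q]);
    double f = wlc_dUdl(x, lmax[q], p, kBT); // tension, pulls ends together
    if (U) *U += wlc_energy(l, lmax[q], p, kBT);
    for (int k = 0; k < 3; ++k) {
      double fk = -f * d[k] / l;
      F[3 * i + k] += fk;
      F[3 * j + k] -= fk;
    }
  }
  for (int q = 0; q < nt; ++q) {
    int a = ta[q], b = tb[q], c = tc[q];
    // shift triangle to a common image of vertex a
    double rb_[3], rc_[3], ra_[3] = {r[3 * a], r[3 * a + 1], r[3 * a + 2]};
    for (int k = 0; k < 3; ++k) {
      double db = r[3 * b + k] - ra_[k];
      double dc = r[3 * c + k] - ra_[k];
      rb_[k] = db;
      rc_[k] = dc;
    }
    bx.minimg(rb_);
    bx.minimg(rc_);
    for (int k = 0; k < 3; ++k) { rb_[k] += ra_[k]; rc_[k] += ra_[k]; }
    double ga[3], gb[3], gc[3];
    double A = tri_area_grad(ra_, rb_, rc_, ga, gb, gc);
    if (U) *U += C1[q] / A;
    double dUdA = -C1[q] / (A * A); // repulsive: energy falls with area
    for (int k = 0; k < 3; ++k) {
      F[3 * a + k] -= dUdA * ga[k];
      F[3 * b + k] -= dUdA * gb[k];
      F[3 * c + k] -= dUdA * gc[k];
    }
  }
}

// dihedral angle phi for quadruple (i,j,k,l) about axis j-k, plus gradient
static inline double dihedral_grad(const double* ri, const double* rj,
                                   const double* rk, const double* rl,
                                   const Box& bx, double* di, double* dj,
                                   double* dk, double* dl) {
  double b1[3], b2[3], b3[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = rj[k] - ri[k];
    b2[k] = rk[k] - rj[k];
    b3[k] = rl[k] - rk[k];
  }
  bx.minimg(b1);
  bx.minimg(b2);
  bx.minimg(b3);
  double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1], b1[2] * b2[0] - b1[0] * b2[2],
                  b1[0] * b2[1] - b1[1] * b2[0]};
  double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1], b2[2] * b3[0] - b2[0] * b3[2],
                  b2[0] * b3[1] - b2[1] * b3[0]};
  double n1sq = n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2];
  double n2sq = n2[0] * n2[0] + n2[1] * n2[1] + n2[2] * n2[2];
  double b2n = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  if (n1sq < 1e-18 || n2sq < 1e-18 || b2n < 1e-12)
    stop("degenerate dihedral (collinear triple)");
  double cxy[3] = {n1[1] * n2[2] - n1[2] * n2[1], n1[2] * n2[0] - n1[0] * n2[2],
                   n1[0] * n2[1] - n1[1] * n2[0]};
  double sphi = (cxy[0] * b2[0] + cxy[1] * b2[1] + cxy[2] * b2[2]) / b2n;
  double cphi = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
  double phi = std::atan2(sphi, cphi);
  double pfac = (b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2]) / (b2n * b2n);
  double qfac = (b3[0] * b2[0] + b3[1] * b2[1] + b3[2] * b2[2]) / (b2n * b2n);
  for (int k = 0; k < 3; ++k) {
    di[k] = -b2n / n1sq * n1[k];
    dl[k] = b2n / n2sq * n2[k];
    dj[k] = -(1.0 + pfac) * di[k] + qfac * dl[k];
    dk[k] = pfac * di[k] - (1.0 + qfac) * dl[k];
  }
  return phi;
}

// cosine-well dihedral energy sum_q c[q] * (1 - cos(phi - phi0))
static void cosdih_kernel(const double* r, const int* qi, const int* qj,
                          const int* qk, const int* ql, const double* phi0,
                          const double* cst, int nq, const Box& bx, double* F,
                          double* U) {
  double di[3], dj[3], dk[3], dl[3];
  for (int q = 0; q < nq; ++q) {
    int i = qi[q], j = qj[q], k = qk[q], l = ql[q];
    double phi = dihedral_grad(r + 3 * i, r + 3 * j, r + 3 * k, r + 3 * l, bx,
                               di, dj, dk, dl);
    if (U) *U += cst[q] * (1.0 - std::cos(phi - phi0[q]));
    double dEdphi = cst[q] * std::sin(phi - phi0[q]);
    for (int m = 0; m < 3; ++m) {
      F[3 * i + m] -= dEdphi * di[m];
      F[3 * j + m] -= dEdphi * dj[m];
      F[3 * k + m] -= dEdphi * dk[m];
      F[3 * l + m] -= dEdphi * dl[m];
    }
  }
}

static void area_volume_kernel(const double* r, const int* ta, const int* tb,
                               const int* tc, int nt, double A0, double V0,
                               double ka, double kv, double kBT, double l0bar,
                               double* F, double* U, double* Aout,
                               double* Vout) {
  // global area and signed volume
  double A = 0.0, V = 0.0;
  for (int q = 0; q < nt; ++q) {
    const double *ra = r + 3 * ta[q], *rb = r + 3 * tb[q], *rc = r + 3 * tc[q];
    double u[3] = {rb[0] - ra[0], rb[1] - ra[1], rb[2] - ra[2]};
    double w[3] = {rc[0] - ra[0], rc[1] - ra[1], rc[2] - ra[2]};
    double nv[3] = {u[1] * w[2] - u[2] * w[1], u[2] * w[0] - u[0] * w[2],
                    u[0] * w[1] - u[1] * w[0]};
    A += 0.5 * std::sqrt(nv[0] * nv[0] + nv[1] * nv[1] + nv[2] * nv[2]);
    V += (ra[0] * (rb[1] * rc[2] - rb[2] * rc[1]) +
          ra[1] * (rb[2] * rc[0] - rb[0] * rc[2]) +
          ra[2] * (rb[0] * rc[1] - rb[1] * rc[0])) /
         6.0;
  }
  if (V < 0) stop("inconsistent mesh orientation: negative enclosed volume");
  if (Aout) *Aout = A;
  if (Vout) *Vout = V;
  double dUdA = ka * kBT * (A - A0) / (l0bar * l0bar * A0);
  double dUdV = kv * kBT * (V - V0) / (l0bar * l0bar * l0bar * V0);
  if (U)
    *U += ka * kBT * (A - A0) * (A - A0) / (2.0 * l0bar * l0bar * A0) +
          kv * kBT * (V - V0) * (V - V0) / (2.0 * l0bar * l0bar * l0bar * V0);
  for (int q = 0; q < nt; ++q) {
    int a = ta[q], b = tb[q], c = tc[q];
    const double *ra = r + 3 * a, *rb = r + 3 * b, *rc = r + 3 * c;
    double ga[3], gb[3], gc[3];
    tri_area_grad(ra, rb, rc, ga, gb, gc);
    // volume gradient: dV/dra = (rb x rc)/6 etc.
    double va[3] = {(rb[1] * rc[2] - rb[2] * rc[1]) / 6.0,
                    (rb[2] * rc[0] - rb[0] * rc[2]) / 6.0,
                    (rb[0] * rc[1] - rb[1] * rc[0]) / 6.0};
    double vb[3] = {(rc[1] * ra[2] - rc[2] * ra[1]) / 6.0,
                    (rc[2] * ra[0] - rc[0] * ra[2]) / 6.0,
                    (rc[0] * ra[1] - rc[1] * ra[0]) / 6.0};
    double vc[3] = {(ra[1] * rb[2] - ra[2] * rb[1]) / 6.0,
                    (ra[2] * rb[0] - ra[0] * rb[2]) / 6.0,
                    (ra[0] * rb[1] - ra[1] * rb[0]) / 6.0};
    for (int k = 0; k < 3; ++k) {
      F[3 * a + k] -= dUdA * ga[k] + dUdV * va[k];
      F[3 * b + k] -= dUdA * gb[k] + dUdV * vb[k];
      F[3 * c + k] -= dUdA * gc[k] + dUdV * vc[k];
    }
  }
}

// per-edge membrane viscosity (dissipative + matched random force)
static void mesh_visc_kernel(const double* r, const double* v, const int* ei,
                             const int* ej, int ne, double gT, double gC,
                             double kBT, double dt, const Box& bx, RNG* rng,
                             double* F) {
  double sqdt = std::sqrt(dt);
  double cS = std::sqrt(2.0 * kBT * 2.0 * gT);
  double tr3 = 3.0 * gC - gT; // zero when gT = 3 gC
  double cT = tr3 > 0 ? std::sqrt(2.0 * kBT * tr3) / 3.0 : 0.0;
  for (int q = 0; q < ne; ++q) {
    int i = ei[q], j = ej[q];
    double d[3] = {r[3 * i] - r[3 * j], r[3 * i + 1] - r[3 * j + 1],
                   r[3 * i + 2] - r[3 * j + 2]};
    bx.minimg(d);
    double rn = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    double e[3] = {d[0] / rn, d[1] / rn, d[2] / rn};
    double vij[3] = {v[3 * i] - v[3 * j], v[3 * i + 1] - v[3 * j + 1],
                     v[3 * i + 2] - v[3 * j + 2]};
    double rv = e[0] * vij[0] + e[1] * vij[1] + e[2] * vij[2];
    double f[3];
    for (int k = 0; k < 3; ++k) f[k] = -gT * vij[k] - gC * rv * e[k];
    if (rng) {
      // traceless symmetric Wiener increment dotted with edge direction
      double W[3][3], tr = 0.0;
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) W[a][b] = rng->normal() * sqdt;
      double S[3][3];
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) S[a][b] = 0.5 * (W[a][b] + W[b][a]);
      tr = S[0][0] + S[1][1] + S[2][2];
      for (int a = 0; a < 3; ++a) S[a][a] -= tr / 3.0;
      for (int a = 0; a < 3; ++a) {
        double s = 0.0;
        for (int b = 0; b < 3; ++b) s += S[a][b] * e[b];
        f[a] += (cS * s + cT * tr * e[a]) / dt;
      }
    }
    for (int k = 0; k < 3; ++k) {
      F[3 * i + k] += f[k];
      F[3 * j + k] -= f[k];
    }
  }
}

static void bond_kernel(const double* r, const int* bi, const int* bj,
                        const double* kap, const double* r0, int nb,
                        const Box& bx, double* F, double* U,
                        double* fmagout) {
  for (int q = 0; q < nb; ++q) {
    int i = bi[q], j = bj[q];
    double d[3] = {r[3 * i] - r[3 * j], r[3 * i + 1] - r[3 * j + 1],
                   r[3 * i + 2] - r[3 * j + 2]};
    bx.minimg(d);
    double l = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (l < 1e-12) stop("zero-length bond %d", q + 1);
    double f = 2.0 * kap[q] * (l - r0[q]); // dU/dl
    if (U) *U += kap[q] * (l - r0[q]) * (l - r0[q]);
    if (fmagout) fmagout[q] = std::fabs(f);
    for (int k = 0; k < 3; ++k) {
      double fk = -f * d[k] / l;
      F[3 * i + k] += fk;
      F[3 * j + k] -= fk;
    }
  }
}

static void angle_kernel(const double* r, const int* ai, const int* aj,
                         const int* ak, const double* kap, const double* th0,
                         int na, const Box& bx, double* F, double* U) {
  for (int q = 0; q < na; ++q) {
    int i = ai[q], j = aj[q], k = ak[q];
    double u[3] = {r[3 * i] - r[3 * j], r[3 * i + 1] - r[3 * j + 1],
                   r[3 * i + 2] - r[3 * j + 2]};
    double w[3] = {r[3 * k] - r[3 * j], r[3 * k + 1] - r[3 * j + 1],
                   r[3 * k + 2] - r[3 * j + 2]};
    bx.minimg(u);
    bx.minimg(w);
    double cu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    double cw = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
    if (cu < 1e-12 || cw < 1e-12) stop("zero-length bond in angle %d", q + 1);
    double c = (u[0] * w[0] + u[1] * w[1] + u[2] * w[2]) / (cu * cw);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double s = std::sqrt(std::max(1.0 - c * c, 1e-16));
    if (U) *U += kap[q] * (th - th0[q]) * (th - th0[q]);
    double dEdth = 2.0 * kap[q] * (th - th0[q]);
    for (int m = 0; m < 3; ++m) {
      double dthdi = (c * u[m] / cu - w[m] / cw) / (cu * s);
      double dthdk = (c * w[m] / cw - u[m] / cu) / (cw * s);
      F[3 * i + m] -= dEdth * dthdi;
      F[3 * k + m] -= dEdth * dthdk;
      F[3 * j + m] += dEdth * (dthdi + dthdk);
    }
  }
}

// ----------------------------------------------- exported bonded evaluators

// [[Rcpp::export]]
List cpp_bond_forces(NumericMatrix pos, IntegerVector bi, IntegerVector bj,
                     NumericVector kappa, NumericVector r0, NumericVector box,
                     LogicalVector periodic) {
  Box bx = parse_box(box, periodic);
  int n = pos.nrow(), nb = bi.size();
  std::vector<double> r(3 * n), F(3 * n, 0.0), fm(nb, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) r[3 * i + k] = pos(i, k);
  std::vector<int> I(nb), J(nb);
  for (int q = 0; q < nb; ++q) { I[q] = bi[q] - 1; J[q] = bj[q] - 1; }
  double U = 0.0;
  bond_kernel(r.data(), I.data(), J.data(), REAL(kappa), REAL(r0), nb, bx,
              F.data(), &U, fm.data());
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = F[3 * i + k];
  return List::create(_["forces"] = out, _["energy"] = U,
                      _["bond_force"] = wrap(fm));
}

// [[Rcpp::export]]
List cpp_angle_forces(NumericMatrix pos, IntegerVector ai, IntegerVector aj,
                      IntegerVector ak, NumericVector kappa,
                      NumericVector theta0, NumericVector box,
                      LogicalVector periodic) {
  Box bx = parse_box(box, periodic);
  int n = pos.nrow(), na = ai.size();
  std::vector<double> r(3 * n), F(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) r[3 * i + k] = pos(i, k);
  std::vector<int> I(na), J(na), K(na);
  for (int q = 0; q < na; ++q) {
    I[q] = ai[q] - 1; J[q] = aj[q] - 1; K[q] = ak[q] - 1;
  }
  double U = 0.0;
  angle_kernel(r.data(), I.data(), J.data(), K.data(), REAL(kappa),
               REAL(theta0), na, bx, F.data(), &U);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = F[3 * i + k];
  return List::create(_["forces"] = out, _["energy"] = U);
}

// [[Rcpp::export]]
List cpp_torsion_forces(NumericMatrix pos, IntegerMatrix quads,
                        NumericVector ktor, NumericVector phi0,
                        NumericVector box, LogicalVector periodic) {
  Box bx = parse_box(box, periodic);
  int n = pos.nrow(), nq = quads.nrow();
  std::vector<double> r(3 * n), F(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) r[3 * i + k] = pos(i, k);
  std::vector<int> I(nq), J(nq), K(nq), L(nq);
  for (int q = 0; q < nq; ++q) {
    I[q] = quads(q, 0) - 1; J[q] = quads(q, 1) - 1;
    K[q] = quads(q, 2) - 1; L[q] = quads(q, 3) - 1;
  }
  double U = 0.0;
  cosdih_kernel(r.data(), I.data(), J.data(), K.data(), L.data(), REAL(phi0),
                REAL(ktor), nq, bx, F.data(), &U);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = F[3 * i + k];
  return List::create(_["forces"] = out, _["energy"] = U);
}

// [[Rcpp::export]]
NumericVector cpp_dihedral_angles(NumericMatrix pos, IntegerMatrix quads,
                                  NumericVector box, LogicalVector periodic) {
  Box bx = parse_box(box, periodic);
  int n = pos.nrow(), nq = quads.nrow();
  std::vector<double> r(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) r[3 * i + k] = pos(i, k);
  NumericVector out(nq);
  double di[3], dj[3], dk[3], dl[3];
  for (int q = 0; q < nq; ++q)
    out[q] = dihedral_grad(r.data() + 3 * (quads(q, 0) - 1),
                           r.data() + 3 * (quads(q, 1) - 1),
                           r.data() + 3 * (quads(q, 2) - 1),
                           r.data() + 3 * (quads(q, 3) - 1), bx, di, dj, dk,
                           dl);
  return out;
}

// [[Rcpp::export]]
List cpp_wlc_pow_forces(NumericMatrix pos, IntegerMatrix edges,
                        NumericVector l0, NumericVector lmax,
                        IntegerMatrix tris, NumericVector C1, double p,
                        double kBT, NumericVector box,
                        LogicalVector periodic) {
  Box bx = parse_box(box, periodic);
  int n = pos.nrow(), ne = edges.nrow(), nt = tris.nrow();
  std::vector<double> r(3 * n), F(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) r[3 * i + k] = pos(i, k);
  std::vector<int> ei(ne), ej(ne), ta(nt), tb(nt), tc(nt);
  for (int q = 0; q < ne; ++q) { ei[q] = edges(q, 0) - 1; ej[q] = edges(q, 1) - 1; }
  for (int q = 0; q < nt; ++q) {
    ta[q] = tris(q, 0) - 1; tb[q] = tris(q, 1) - 1; tc[q] = tris(q, 2) - 1;
  }
  double U = 0.0;
  wlc_pow_kernel(r.data(), ei.data(), ej.data(), REAL(l0), REAL(lmax), ne,
                 ta.data(), tb.data(), tc.data(), REAL(C1), nt, p, kBT, bx,
                 F.data(), &U);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = F[3 * i + k];
  return List::create(_["forces"] = out, _["energy"] = U);
}

// [[Rcpp::export]]
List cpp_bending_forces(NumericMatrix pos, IntegerMatrix dihedrals,
                        NumericVector phi0, double kb, NumericVector box,
                        LogicalVector periodic) {
  NumericVector cst(dihedrals.nrow(), kb);
  return cpp_torsion_forces(pos, dihedrals, cst, phi0, box, periodic);
}

// [[Rcpp::export]]
List cpp_area_volume_forces(NumericMatrix pos, IntegerMatrix tris, double A0,
                            double V0, double ka, double kv, double kBT,
                            double l0bar) {
  int n = pos.nrow(), nt = tris.nrow();
  std::vector<double> r(3 * n), F(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) r[3 * i + k] = pos(i, k);
  std::vector<int> ta(nt), tb(nt), tc(nt);
  for (int q = 0; q < nt; ++q) {
    ta[q] = tris(q, 0) - 1; tb[q] = tris(q, 1) - 1; tc[q] = tris(q, 2) - 1;
  }
  double U = 0.0, A = 0.0, V = 0.0;
  area_volume_kernel(r.data(), ta.data(), tb.data(), tc.data(), nt, A0, V0, ka,
                     kv, kBT, l0bar, F.data(), &U, &A, &V);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = F[3 * i + k];
  return List::create(_["forces"] = out, _["energy"] = U, _["area"] = A,
                      _["volume"] = V);
}

// [[Rcpp::export]]
NumericMatrix cpp_mesh_viscous_forces(NumericMatrix pos, NumericMatrix vel,
                                      IntegerMatrix edges, double gammaT,
                                      double gammaC, double kBT, double dt,
                                      double seed, bool with_random,
                                      NumericVector box,
                                      LogicalVector periodic) {
  Box bx = parse_box(box, periodic);
  int n = pos.nrow(), ne = edges.nrow();
  std::vector<double> r(3 * n), v(3 * n), F(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      r[3 * i + k] = pos(i, k);
      v[3 * i + k] = vel(i, k);
    }
  std::vector<int> ei(ne), ej(ne);
  for (int q = 0; q < ne; ++q) { ei[q] = edges(q, 0) - 1; ej[q] = edges(q, 1) - 1; }
  RNG rng((uint64_t)seed);
  mesh_visc_kernel(r.data(), v.data(), ei.data(), ej.data(), ne, gammaT,
                   gammaC, kBT, dt, bx, with_random ? &rng : nullptr,
                   F.data());
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = F[3 * i + k];
  return out;
}

// [[Rcpp::export]]
List cpp_mesh_area_volume(NumericMatrix pos, IntegerMatrix tris) {
  int n = pos.nrow(), nt = tris.nrow();
  double A = 0.0, V = 0.0;
  for (int q = 0; q < nt; ++q) {
    int a = tris(q, 0) - 1, b = tris(q, 1) - 1, c = tris(q, 2) - 1;
    double u[3] = {pos(b, 0) - pos(a, 0), pos(b, 1) - pos(a, 1),
                   pos(b, 2) - pos(a, 2)};
    double w[3] = {pos(c, 0) - pos(a, 0), pos(c, 1) - pos(a, 1),
                   pos(c, 2) - pos(a, 2)};
    double nv[3] = {u[1] * w[2] - u[2] * w[1], u[2] * w[0] - u[0] * w[2],
                    u[0] * w[1] - u[1] * w[0]};
    A += 0.5 * std::sqrt(nv[0] * nv[0] + nv[1] * nv[1] + nv[2] * nv[2]);
    V += (pos(a, 0) * (pos(b, 1) * pos(c, 2) - pos(b, 2) * pos(c, 1)) +
          pos(a, 1) * (pos(b, 2) * pos(c, 0) - pos(b, 0) * pos(c, 2)) +
          pos(a, 2) * (pos(b, 0) * pos(c, 1) - pos(b, 1) * pos(c, 0))) / 6.0;
  }
  (void)n;
  return List::create(_["area"] = A, _["volume"] = V);
}

// winding number (summed solid angle) point-in-closed-mesh test
// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix query, NumericMatrix pos,
                                 IntegerMatrix tris) {
  int nq = query.nrow(), nt = tris.nrow();
  LogicalVector out(nq);
  for (int s = 0; s < nq; ++s) {
    double px = query(s, 0), py = query(s, 1), pz = query(s, 2);
    double wsum = 0.0;
    for (int q = 0; q < nt; ++q) {
      int a = tris(q, 0) - 1, b = tris(q, 1) - 1, c = tris(q, 2) - 1;
      double A[3] = {pos(a, 0) - px, pos(a, 1) - py, pos(a, 2) - pz};
      double B[3] = {pos(b, 0) - px, pos(b, 1) - py, pos(b, 2) - pz};
      double C[3] = {pos(c, 0) - px, pos(c, 1) - py, pos(c, 2) - pz};
      double la = std::sqrt(A[0] * A[0] + A[1] * A[1] + A[2] * A[2]);
      double lb = std::sqrt(B[0] * B[0] + B[1] * B[1] + B[2] * B[2]);
      double lc = std::sqrt(C[0] * C[0] + C[1] * C[1] + C[2] * C[2]);
      double num = A[0] * (B[1] * C[2] - B[2] * C[1]) +
                   A[1] * (B[2] * C[0] - B[0] * C[2]) +
                   A[2] * (B[0] * C[1] - B[1] * C[0]);
      double den = la * lb * lc +
                   (A[0] * B[0] + A[1] * B[1] + A[2] * B[2]) * lc +
                   (A[0] * C[0] + A[1] * C[1] + A[2] * C[2]) * lb +
                   (B[0] * C[0] + B[1] * C[1] + B[2] * C[2]) * la;
      wsum += 2.0 * std::atan2(num, den);
    }
    out[s] = std::fabs(wsum) > 2.0 * M_PI; // |Omega| > 2pi => inside
  }
  return out;
}

// ------------------------------------------------------------------- engine

struct MeshBlock {
  std::vector<int> ei, ej;
  std::vector<double> l0, lmax;
  std::vector<int> ta, tb, tc;
  std::vector<double> C1;
  std::vector<int> di, dj, dk, dl;
  std::vector<double> phi0, kbvec;
  double kb, p, ka, kv, A0, V0, l0bar, gT, gC;
};

struct Model {
  int n;
  std::vector<int> type;
  std::vector<char> frozen;
  Box bx;
  double kBT, dt, mass;
  PairTable T;
  // plain bonded terms
  std::vector<int> bi, bj;
  std::vector<double> bk, br0;
  std::vector<int> ai, aj, ak;
  std::vector<double> akap, ath0;
  std::vector<int> qi, qj, qk, ql;
  std::vector<double> qkt, qphi0;
  std::vector<MeshBlock> meshes;
  // body force
  double g[3] = {0, 0, 0};
  bool gtype[NTYPE + 1] = {false, false, false, false, false, false};
  int region_kind = 0; // 0 none, 1 cylinder along +x
  double region[4] = {0, 0, 0, 0};
  SDF sdf;
};

static Model parse_model(const List& m, int n) {
  Model M;
  M.n = n;
  IntegerVector types = m["types"];
  if (types.size() != n) stop("types length mismatch");
  M.type.assign(types.begin(), types.end());
  M.frozen.resize(n);
  for (int i = 0; i < n; ++i) M.frozen[i] = (M.type[i] == 5);
  if (m.containsElementNamed("frozen") && !Rf_isNull(m["frozen"])) {
    LogicalVector fr = m["frozen"];
    for (int i = 0; i < n; ++i) M.frozen[i] = fr[i] ? 1 : 0;
  }
  M.bx = parse_box(m["box"], m["periodic"]);
  M.kBT = as<double>(m["kBT"]);
  M.dt = as<double>(m["dt"]);
  M.mass = m.containsElementNamed("mass") ? as<double>(m["mass"]) : 1.0;
  M.T = parse_table(m["table"], M.kBT);
  if (m.containsElementNamed("bonds") && !Rf_isNull(m["bonds"])) {
    List b = m["bonds"];
    IntegerVector i = b["i"], j = b["j"];
    NumericVector k = b["kappa"], r0 = b["r0"];
    for (int q = 0; q < i.size(); ++q) {
      M.bi.push_back(i[q] - 1);
      M.bj.push_back(j[q] - 1);
      M.bk.push_back(k[q]);
      M.br0.push_back(r0[q]);
    }
  }
  if (m.containsElementNamed("angles") && !Rf_isNull(m["angles"])) {
    List a = m["angles"];
    IntegerVector i = a["i"], j = a["j"], k = a["k"];
    NumericVector kap = a["kappa"], t0 = a["theta0"];
    for (int q = 0; q < i.size(); ++q) {
      M.ai.push_back(i[q] - 1);
      M.aj.push_back(j[q] - 1);
      M.ak.push_back(k[q] - 1);
      M.akap.push_back(kap[q]);
      M.ath0.push_back(t0[q]);
    }
  }
  if (m.containsElementNamed("torsions") && !Rf_isNull(m["torsions"])) {
    List t = m["torsions"];
    IntegerVector i = t["i"], j = t["j"], k = t["k"], l = t["l"];
    NumericVector kt = t["ktor"], p0 = t["phi0"];
    for (int q = 0; q < i.size(); ++q) {
      M.qi.push_back(i[q] - 1);
      M.qj.push_back(j[q] - 1);
      M.qk.push_back(k[q] - 1);
      M.ql.push_back(l[q] - 1);
      M.qkt.push_back(kt[q]);
      M.qphi0.push_back(p0[q]);
    }
  }
  if (m.containsElementNamed("meshes") && !Rf_isNull(m["meshes"])) {
    List ms = m["meshes"];
    for (int mi = 0; mi < ms.size(); ++mi) {
      List mm = ms[mi];
      MeshBlock B;
      IntegerMatrix ed = mm["edges"], tr = mm["tris"], dh = mm["dihedrals"];
      NumericVector l0 = mm["l0"], lmax = mm["lmax"], C1 = mm["C1"],
                    ph = mm["phi0"];
      for (int q = 0; q < ed.nrow(); ++q) {
        B.ei.push_back(ed(q, 0) - 1);
        B.ej.push_back(ed(q, 1) - 1);
        B.l0.push_back(l0[q]);
        B.lmax.push_back(lmax[q]);
      }
      for (int q = 0; q < tr.nrow(); ++q) {
        B.ta.push_back(tr(q, 0) - 1);
        B.tb.push_back(tr(q, 1) - 1);
        B.tc.push_back(tr(q, 2) - 1);
        B.C1.push_back(C1[q]);
      }
      for (int q = 0; q < dh.nrow(); ++q) {
        B.di.push_back(dh(q, 0) - 1);
        B.dj.push_back(dh(q, 1) - 1);
        B.dk.push_back(dh(q, 2) - 1);
        B.dl.push_back(dh(q, 3) - 1);
        B.phi0.push_back(ph[q]);
      }
      B.kb = as<double>(mm["kb"]);
      B.kbvec.assign(dh.nrow(), B.kb);
      B.p = as<double>(mm["p"]);
      B.ka = as<double>(mm["ka"]);
      B.kv = as<double>(mm["kv"]);
      B.A0 = as<double>(mm["A0"]);
      B.V0 = as<double>(mm["V0"]);
      B.l0bar = as<double>(mm["l0bar"]);
      B.gT = as<double>(mm["gammaT"]);
      B.gC = as<double>(mm["gammaC"]);
      M.meshes.push_back(std::move(B));
    }
  }
  if (m.containsElementNamed("body_force") && !Rf_isNull(m["body_force"])) {
    List bf = m["body_force"];
    NumericVector g = bf["g"];
    for (int k = 0; k < 3; ++k) M.g[k] = g[k];
    IntegerVector tt = bf["types"];
    for (int q = 0; q < tt.size(); ++q)
      if (tt[q] >= 1 && tt[q] <= NTYPE) M.gtype[tt[q]] = true;
    if (bf.containsElementNamed("region") && !Rf_isNull(bf["region"])) {
      List rg = bf["region"];
      M.region_kind = 1;
      M.region[0] = as<double>(rg["x0"]);
      M.region[1] = as<double>(rg["radius"]);
      M.region[2] = as<double>(rg["cy"]);
      M.region[3] = as<double>(rg["cz"]);
    }
  }
  if (m.containsElementNamed("sdf") && !Rf_isNull(m["sdf"]))
    M.sdf = parse_sdf(m["sdf"]);
  return M;
}

static void compute_all_forces(const Model& M, const double* r,
                               const double* v,
                               const std::vector<std::pair<int, int>>& pairs,
                               RNG& rng, std::vector<double>& F) {
  std::fill(F.begin(), F.end(), 0.0);
  dpd_pair_kernel(r, v, M.type.data(), M.frozen.data(), M.T, M.bx, M.kBT,
                  1.0 / std::sqrt(M.dt), pairs, &rng, F.data());
  if (!M.bi.empty())
    bond_kernel(r, M.bi.data(), M.bj.data(), M.bk.data(), M.br0.data(),
                (int)M.bi.size(), M.bx, F.data(), nullptr, nullptr);
  if (!M.ai.empty())
    angle_kernel(r, M.ai.data(), M.aj.data(), M.ak.data(), M.akap.data(),
                 M.ath0.data(), (int)M.ai.size(), M.bx, F.data(), nullptr);
  if (!M.qi.empty())
    cosdih_kernel(r, M.qi.data(), M.qj.data(), M.qk.data(), M.ql.data(),
                  M.qphi0.data(), M.qkt.data(), (int)M.qi.size(), M.bx,
                  F.data(), nullptr);
  for (const auto& B : M.meshes) {
    wlc_pow_kernel(r, B.ei.data(), B.ej.data(), B.l0.data(), B.lmax.data(),
                   (int)B.ei.size(), B.ta.data(), B.tb.data(), B.tc.data(),
                   B.C1.data(), (int)B.ta.size(), B.p, M.kBT, M.bx, F.data(),
                   nullptr);
    if (!B.di.empty())
      cosdih_kernel(r, B.di.data(), B.dj.data(), B.dk.data(), B.dl.data(),
                    B.phi0.data(), B.kbvec.data(), (int)B.di.size(), M.bx,
                    F.data(), nullptr);
    area_volume_kernel(r, B.ta.data(), B.tb.data(), B.tc.data(),
                       (int)B.ta.size(), B.A0, B.V0, B.ka, B.kv, M.kBT,
                       B.l0bar, F.data(), nullptr, nullptr, nullptr);
    mesh_visc_kernel(r, v, B.ei.data(), B.ej.data(), (int)B.ei.size(), B.gT,
                     B.gC, M.kBT, M.dt, M.bx, &rng, F.data());
  }
  if (M.g[0] != 0 || M.g[1] != 0 || M.g[2] != 0) {
    for (int i = 0; i < M.n; ++i) {
      if (M.frozen[i] || !M.gtype[M.type[i]]) continue;
      if (M.region_kind == 1) {
        double x = M.bx.wrap(r[3 * i], 0);
        double dy = r[3 * i + 1] - M.region[2], dz = r[3 * i + 2] - M.region[3];
        if (x < M.region[0] ||
            dy * dy + dz * dz > M.region[1] * M.region[1])
          continue;
      }
      for (int k = 0; k < 3; ++k) F[3 * i + k] += M.g[k];
    }
  }
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, List model, int nsteps,
             double seed, int sample_every, IntegerVector track,
             int track_axis, double skin) {
  int n = pos.nrow();
  Model M = parse_model(model, n);
  std::vector<double> r(3 * n), v(3 * n), rref(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      r[3 * i + k] = pos(i, k);
      v[3 * i + k] = vel(i, k);
    }
  RNG rng((uint64_t)seed);
  std::vector<std::pair<int, int>> pairs;
  double listcut = M.T.maxcut + skin;
  cell_pairs(r.data(), n, M.bx, listcut, pairs);
  rref = r;
  int nbuild = 1;
  std::vector<double> F(3 * n, 0.0);
  compute_all_forces(M, r.data(), v.data(), pairs, rng, F);

  int nmob = 0;
  for (int i = 0; i < n; ++i)
    if (!M.frozen[i]) ++nmob;
  int nsamp = sample_every > 0 ? nsteps / sample_every : 0;
  int ncol = 14;
  NumericMatrix diag(nsamp, ncol);
  int srow = 0;
  std::vector<int> trk(track.begin(), track.end());
  for (auto& t : trk) t -= 1;
  bool has_mesh = !M.meshes.empty();
  const double halfdt = 0.5 * M.dt;
  const double maxdisp = M.T.maxcut;

  for (int step = 1; step <= nsteps; ++step) {
    // half kick + drift
    double maxv2 = 0.0;
    int badi = -1;
    for (int i = 0; i < n; ++i) {
      if (M.frozen[i]) continue;
      for (int k = 0; k < 3; ++k) {
        v[3 * i + k] += halfdt * F[3 * i + k] / M.mass;
      }
      double v2 = v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                  v[3 * i + 2] * v[3 * i + 2];
      if (v2 > maxv2) { maxv2 = v2; badi = i; }
      for (int k = 0; k < 3; ++k) r[3 * i + k] += M.dt * v[3 * i + k];
    }
    if (std::sqrt(maxv2) * M.dt > maxdisp)
      stop("instability: particle %d moved %.3g (> cutoff %.3g) in one step",
           badi + 1, std::sqrt(maxv2) * M.dt, maxdisp);
    // bounce-back at walls
    if (!M.sdf.prims.empty()) {
      for (int i = 0; i < n; ++i) {
        if (M.frozen[i]) continue;
        double x = M.bx.wrap(r[3 * i], 0), y = M.bx.wrap(r[3 * i + 1], 1),
               z = M.bx.wrap(r[3 * i + 2], 2);
        double s = M.sdf.eval(x, y, z, M.bx);
        if (s <= 0) continue;
        // walk back along the trajectory to the crossing, then mirror
        double old_[3], dvec[3];
        for (int k = 0; k < 3; ++k) {
          dvec[k] = M.dt * v[3 * i + k];
          old_[k] = r[3 * i + k] - dvec[k];
        }
        double s0 = M.sdf.eval(M.bx.wrap(old_[0], 0), M.bx.wrap(old_[1], 1),
                               M.bx.wrap(old_[2], 2), M.bx);
        if (s0 > 0) {
          // started inside solid (deep overlap): push to previous position
          for (int k = 0; k < 3; ++k) r[3 * i + k] = old_[k];
          for (int k = 0; k < 3; ++k) v[3 * i + k] = -v[3 * i + k];
          if (s0 > M.T.maxcut)
            stop("particle %d is %.3g deep inside a wall", i + 1, s0);
          continue;
        }
        double a = 0.0, b = 1.0;
        for (int it = 0; it < 25; ++it) {
          double mid = 0.5 * (a + b);
          double px = old_[0] + mid * dvec[0], py = old_[1] + mid * dvec[1],
                 pz = old_[2] + mid * dvec[2];
          double sm = M.sdf.eval(M.bx.wrap(px, 0), M.bx.wrap(py, 1),
                                 M.bx.wrap(pz, 2), M.bx);
          if (sm > 0) b = mid; else a = mid;
        }
        for (int k = 0; k < 3; ++k) {
          double cross = old_[k] + a * dvec[k];
          r[3 * i + k] = cross - (1.0 - a) * dvec[k]; // retrace remaining path
          v[3 * i + k] = -v[3 * i + k];
        }
      }
    }
    // neighbour list refresh
    double dmax2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double d[3] = {r[3 * i] - rref[3 * i], r[3 * i + 1] - rref[3 * i + 1],
                     r[3 * i + 2] - rref[3 * i + 2]};
      double d2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (d2 > dmax2) dmax2 = d2;
    }
    if (dmax2 > 0.25 * skin * skin) {
      cell_pairs(r.data(), n, M.bx, listcut, pairs);
      rref = r;
      ++nbuild;
    }
    // force at new positions, half-step velocities (lambda = 1/2)
    compute_all_forces(M, r.data(), v.data(), pairs, rng, F);
    for (int i = 0; i < n; ++i) {
      if (M.frozen[i]) continue;
      for (int k = 0; k < 3; ++k) v[3 * i + k] += halfdt * F[3 * i + k] / M.mass;
    }
    if (sample_every > 0 && step % sample_every == 0 && srow < nsamp) {
      double ke = 0.0, px = 0.0, py = 0.0, pz = 0.0;
      for (int i = 0; i < n; ++i) {
        if (M.frozen[i]) continue;
        ke += M.mass * (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                        v[3 * i + 2] * v[3 * i + 2]);
        px += M.mass * v[3 * i];
        py += M.mass * v[3 * i + 1];
        pz += M.mass * v[3 * i + 2];
      }
      diag(srow, 0) = step;
      diag(srow, 1) = step * M.dt;
      diag(srow, 2) = ke / (3.0 * nmob);
      diag(srow, 3) = px;
      diag(srow, 4) = py;
      diag(srow, 5) = pz;
      if (has_mesh) {
        const MeshBlock& B = M.meshes[0];
        double A = 0.0, V = 0.0;
        for (size_t q = 0; q < B.ta.size(); ++q) {
          const double *ra = r.data() + 3 * B.ta[q],
                       *rb = r.data() + 3 * B.tb[q],
                       *rc = r.data() + 3 * B.tc[q];
          double u[3] = {rb[0] - ra[0], rb[1] - ra[1], rb[2] - ra[2]};
          double w[3] = {rc[0] - ra[0], rc[1] - ra[1], rc[2] - ra[2]};
          double nv[3] = {u[1] * w[2] - u[2] * w[1],
                          u[2] * w[0] - u[0] * w[2],
                          u[0] * w[1] - u[1] * w[0]};
          A += 0.5 * std::sqrt(nv[0] * nv[0] + nv[1] * nv[1] + nv[2] * nv[2]);
          V += (ra[0] * (rb[1] * rc[2] - rb[2] * rc[1]) +
                ra[1] * (rb[2] * rc[0] - rb[0] * rc[2]) +
                ra[2] * (rb[0] * rc[1] - rb[1] * rc[0])) / 6.0;
        }
        diag(srow, 6) = A;
        diag(srow, 7) = V;
      } else {
        diag(srow, 6) = NA_REAL;
        diag(srow, 7) = NA_REAL;
      }
      if (!trk.empty()) {
        double cx = 0, cy = 0, cz = 0, mx = -1e30;
        for (int t : trk) {
          cx += r[3 * t];
          cy += r[3 * t + 1];
          cz += r[3 * t + 2];
          double c = r[3 * t + (track_axis - 1)];
          if (c > mx) mx = c;
        }
        diag(srow, 8) = cx / trk.size();
        diag(srow, 9) = cy / trk.size();
        diag(srow, 10) = cz / trk.size();
        diag(srow, 11) = mx;
      } else {
        diag(srow, 8) = diag(srow, 9) = diag(srow, 10) = diag(srow, 11) =
            NA_REAL;
      }
      diag(srow, 12) = NA_REAL;
      diag(srow, 13) = NA_REAL;
      ++srow;
    }
  }
  NumericMatrix rout(n, 3), vout(n, 3), fout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      rout(i, k) = r[3 * i + k];
      vout(i, k) = v[3 * i + k];
      fout(i, k) = F[3 * i + k];
    }
  colnames(diag) = CharacterVector::create(
      "step", "time", "temperature", "px", "py", "pz", "area", "volume",
      "cx", "cy", "cz", "track_max", "aux1", "aux2");
  return List::create(_["positions"] = rout, _["velocities"] = vout,
                      _["forces"] = fout, _["diagnostics"] = diag,
                      _["nbuild"] = nbuild);
}
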