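// Incremental 3D convex hull, used to triangulate point sets relaxed onto a
// sphere (all points in convex position).  Returns outward-oriented faces.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Face {
  int a, b, c;
  double nx, ny, nz, off; // outward normal and plane offset n.x = off
  bool alive;
};

inline void face_plane(Face& f, const NumericMatrix& P) {
  double ax = P(f.a, 0), ay = P(f.a, 1), az = P(f.a, 2);
  double ux = P(f.b, 0) - ax, uy = P(f.b, 1) - ay, uz = P(f.b, 2) - az;
  double vx = P(f.c, 0) - ax, vy = P(f.c, 1) - ay, vz = P(f.c, 2) - az;
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * ax + f.ny * ay + f.nz * az;
}

inline double face_dist(const Face& f, const NumericMatrix& P, int i) {
  return f.nx * P(i, 0) + f.ny * P(i, 1) + f.nz * P(i, 2) - f.off;
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_convex_hull(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");

  // scale-aware tolerance
  double scale = 0.0;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) scale = std::max(scale, std::fabs(pts(i, k)));
  const double eps = 1e-10 * scale * scale; // face_dist has units length^2

  // initial tetrahedron: spread points
  int i0 = 0, i1 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double d = 0;
    for (int k = 0; k < 3; ++k) {
      double t = pts(i, k) - pts(i0, k);
      d += t * t;
    }
    if (d > best) { best = d; i1 = i; }
  }
  // farthest from line i0-i1
  int i2 = -1; best = -1.0;
  double lx = pts(i1, 0) - pts(i0, 0), ly = pts(i1, 1) - pts(i0, 1),
         lz = pts(i1, 2) - pts(i0, 2);
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double wx = pts(i, 0) - pts(i0, 0), wy = pts(i, 1) - pts(i0, 1),
           wz = pts(i, 2) - pts(i0, 2);
    double cx = ly * wz - lz * wy, cy = lz * wx - lx * wz, cz = lx * wy - ly * wx;
    double d = cx * cx + cy * cy + cz * cz;
    if (d > best) { best = d; i2 = i; }
  }
  // farthest from plane i0-i1-i2
  Face base{i0, i1, i2, 0, 0, 0, 0, true};
  face_plane(base, pts);
  int i3 = -1; best = 0.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double d = std::fabs(face_dist(base, pts, i));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0 || best <= eps) stop("degenerate point set: all points coplanar");

  // interior reference point
  double cx = 0, cy = 0, cz = 0;
  int ids[4] = {i0, i1, i2, i3};
  for (int k = 0; k < 4; ++k) {
    cx += pts(ids[k], 0); cy += pts(ids[k], 1); cz += pts(ids[k], 2);
  }
  cx /= 4; cy /= 4; cz /= 4;

  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c) {
    Face f{a, b, c, 0, 0, 0, 0, true};
    face_plane(f, pts);
    // orient outward w.r.t. interior centroid
    if (f.nx * cx + f.ny * cy + f.nz * cz - f.off > 0) {
      std::swap(f.b, f.c);
      face_plane(f, pts);
    }
    faces.push_back(f);
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  std::vector<bool> used(n, false);
  used[i0] = used[i1] = used[i2] = used[i3] = true;

  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    used[p] = true;
    // visible faces
    std::vector<int> vis;
    for (size_t fi = 0; fi < faces.size(); ++fi) {
      if (!faces[fi].alive) continue;
      if (face_dist(faces[fi], pts, p) > eps) vis.push_back((int)fi);
    }
    if (vis.empty()) continue; // interior point (cannot happen on a sphere)
    // horizon: directed edges of visible faces whose reverse is not visible
    std::vector<std::pair<int, int>> edges;
    for (int fi : vis) {
      const Face& f = faces[fi];
      edges.emplace_back(f.a, f.b);
      edges.emplace_back(f.b, f.c);
      edges.emplace_back(f.c, f.a);
    }
    std::vector<std::pair<int, int>> horizon;
    for (auto& e : edges) {
      bool paired = false;
      for (auto& g : edges)
        if (g.first == e.second && g.second == e.first) { paired = true; break; }
      if (!paired) horizon.push_back(e);
    }
    for (int fi : vis) faces[fi].alive = false;
    for (auto& e : horizon) add_face(e.first, e.second, p);
  }

  int nf = 0;
  for (auto& f : faces) if (f.alive) ++nf;
  IntegerMatrix out(nf, 3);
  int r = 0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    out(r, 0) = f.a + 1; out(r, 1) = f.b + 1; out(r, 2) = f.c + 1;
    ++r;
  }
  return out;
}

// Lloyd-style repulsion relaxation of points constrained to the unit sphere.
// Each iteration pushes close pairs apart along the tangent plane and
// reprojects; produces a near-uniform distribution for any point count.
// [[Rcpp::export]]
NumericMatrix cpp_sphere_relax(NumericMatrix pts, int iters, double step_frac) {
  const int n = pts.nrow();
  NumericMatrix P = clone(pts);
  for (int i = 0; i < n; ++i) { // project to unit sphere
    double r = std::sqrt(P(i,0)*P(i,0) + P(i,1)*P(i,1) + P(i,2)*P(i,2));
    for (int k = 0; k < 3; ++k) P(i, k) /= r;
  }
  const double h = std::sqrt(4.0 * M_PI / n); // ~ mean point spacing
  const double cutoff = 2.0 * h;
  const double step = step_frac * h;

  // simple uniform grid over the cube [-1,1]^3 for neighbour search
  const int nb = std::max(1, (int)std::floor(2.0 / cutoff));
  const double bw = 2.0 / nb;
  std::vector<std::vector<int>> cells;
  std::vector<double> disp(3 * n);
  for (int it = 0; it < iters; ++it) {
    cells.assign((size_t)nb * nb * nb, {});
    for (int i = 0; i < n; ++i) {
      int bx = std::min(nb - 1, std::max(0, (int)((P(i,0) + 1.0) / bw)));
      int by = std::min(nb - 1, std::max(0, (int)((P(i,1) + 1.0) / bw)));
      int bz = std::min(nb - 1, std::max(0, (int)((P(i,2) + 1.0) / bw)));
      cells[(bx * nb + by) * (size_t)nb + bz].push_back(i);
    }
    std::fill(disp.begin(), disp.end(), 0.0);
    for (int bx = 0; bx < nb; ++bx)
      for (int by = 0; by < nb; ++by)
        for (int bz = 0; bz < nb; ++bz) {
          auto& ci = cells[(bx * nb + by) * (size_t)nb + bz];
          if (ci.empty()) continue;
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dz = -1; dz <= 1; ++dz) {
                int ex = bx + dx, ey = by + dy, ez = bz + dz;
                if (ex < 0 || ey < 0 || ez < 0 || ex >= nb || ey >= nb || ez >= nb)
                  continue;
                auto& cj = cells[(ex * nb + ey) * (size_t)nb + ez];
                for (int i : ci)
                  for (int j : cj) {
                    if (j <= i) continue;
                    double rx = P(i,0) - P(j,0), ry = P(i,1) - P(j,1),
                           rz = P(i,2) - P(j,2);
                    double r2 = rx*rx + ry*ry + rz*rz;
                    if (r2 >= cutoff * cutoff || r2 < 1e-24) continue;
                    double r = std::sqrt(r2);
                    double f = (cutoff - r) / r; // soft linear repulsion
                    disp[3*i]   += f * rx; disp[3*i+1] += f * ry; disp[3*i+2] += f * rz;
                    disp[3*j]   -= f * rx; disp[3*j+1] -= f * ry; disp[3*j+2] -= f * rz;
                  }
              }
        }
    for (int i = 0; i < n; ++i) {
      double m = std::sqrt(disp[3*i]*disp[3*i] + disp[3*i+1]*disp[3*i+1] +
                           disp[3*i+2]*disp[3*i+2]);
      if (m < 1e-30) continue;
      double s = step * std::min(1.0, m) / m;
      double x = P(i,0) + s * disp[3*i], y = P(i,1) + s * disp[3*i+1],
             z = P(i,2) + s * disp[3*i+2];
      double r = std::sqrt(x*x + y*y + z*z);
      P(i,0) = x / r; P(i,1) = y / r; P(i,2) = z / r;
    }
  }
  return P;
}

// Laplacian smoothing on the unit sphere with fixed edge topology:
// each vertex moves toward the mean of its neighbours and is reprojected.
// [[Rcpp::export]]
NumericMatrix cpp_sphere_smooth(NumericMatrix pts, IntegerMatrix edges,
                                int iters, double alpha) {
  const int n = pts.nrow(), ne = edges.nrow();
  NumericMatrix P = clone(pts);
  std::vector<double> acc(3 * n);
  std::vector<int> deg(n);
  for (int it = 0; it < iters; ++it) {
    std::fill(acc.begin(), acc.end(), 0.0);
    std::fill(deg.begin(), deg.end(), 0);
    for (int q = 0; q < ne; ++q) {
      int i = edges(q, 0) - 1, j = edges(q, 1) - 1;
      for (int k = 0; k < 3; ++k) {
        acc[3 * i + k] += P(j, k);
        acc[3 * j + k] += P(i, k);
      }
      ++deg[i]; ++deg[j];
    }
    for (int i = 0; i < n; ++i) {
      if (!deg[i]) continue;
      double x = P(i, 0) + alpha * (acc[3 * i] / deg[i] - P(i, 0));
      double y = P(i, 1) + alpha * (acc[3 * i + 1] / deg[i] - P(i, 1));
      double z = P(i, 2) + alpha * (acc[3 * i + 2] / deg[i] - P(i, 2));
      double r = std::sqrt(x * x + y * y + z * z);
      P(i, 0) = x / r; P(i, 1) = y / r; P(i, 2) = z / r;
    }
  }
  return P;
}
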