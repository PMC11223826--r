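// Power-diagram (Laguerre) contact surface areas for sets of atomic balls.
//
// Every atom i is represented by its solvent-expanded ball B_i with radius
// R_i = r_i + probe.  The power cell of B_i is the set of points x with
// pow_i(x) = |x - c_i|^2 - R_i^2 minimal over all balls.  The contact face
// between atoms i and j is the part of their radical plane that belongs to
// both cells and lies inside the union of expanded balls; on the radical
// plane the union constraint reduces to |x - c_i| <= R_i, a disk.  Faces are
// therefore planar convex regions: a disk cut by the half-planes induced by
// the other balls' power constraints.  Their areas are computed exactly
// (polygon clipping + closed-form polygon/circle intersection).
//
// The per-atom solvent area is the part of the expanded sphere surface not
// inside any other expanded ball (on the sphere of B_i, pow_i = 0, so this
// is exactly the boundary of the union claimed by cell i).  It is evaluated
// on a deterministic Fibonacci lattice.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

// Signed area contribution of triangle (O, A, B) clipped to the disk of
// radius R centred at the origin.  Summed over the edges of a CCW polygon
// this yields area(polygon ∩ disk).
static double triCircArea(double ax, double ay, double bx, double by,
                          double R) {
  const double R2 = R * R;
  const bool ain = (ax * ax + ay * ay) <= R2;
  const bool bin = (bx * bx + by * by) <= R2;
  if (ain && bin)
    return 0.5 * cross2(ax, ay, bx, by);

  const double dx = bx - ax, dy = by - ay;
  const double a = dx * dx + dy * dy;
  const double b = 2.0 * (ax * dx + ay * dy);
  const double c = ax * ax + ay * ay - R2;
  const double disc = b * b - 4.0 * a * c;

  auto sector = [&](double ux, double uy, double vx, double vy) {
    double ang = std::atan2(cross2(ux, uy, vx, vy), ux * vx + uy * vy);
    return 0.5 * R2 * ang;
  };

  if (a < 1e-300)  // degenerate zero-length edge
    return 0.0;

  if (ain && !bin) {
    double t = (-b + std::sqrt(std::max(disc, 0.0))) / (2.0 * a);
    double px = ax + t * dx, py = ay + t * dy;
    return 0.5 * cross2(ax, ay, px, py) + sector(px, py, bx, by);
  }
  if (!ain && bin) {
    double t = (-b - std::sqrt(std::max(disc, 0.0))) / (2.0 * a);
    double px = ax + t * dx, py = ay + t * dy;
    return sector(ax, ay, px, py) + 0.5 * cross2(px, py, bx, by);
  }
  // both endpoints outside: the segment may still cross the disk
  if (disc > 0.0) {
    double sq = std::sqrt(disc);
    double t1 = (-b - sq) / (2.0 * a);
    double t2 = (-b + sq) / (2.0 * a);
    if (t1 > 0.0 && t2 < 1.0 && t1 < t2) {
      double p1x = ax + t1 * dx, p1y = ay + t1 * dy;
      double p2x = ax + t2 * dx, p2y = ay + t2 * dy;
      return sector(ax, ay, p1x, p1y) + 0.5 * cross2(p1x, p1y, p2x, p2y) +
             sector(p2x, p2y, bx, by);
    }
  }
  return sector(ax, ay, bx, by);
}

static double circPolyArea(const std::vector<double>& xs,
                           const std::vector<double>& ys, double R) {
  const size_t n = xs.size();
  if (n < 3) return 0.0;
  double area = 0.0;
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    area += triCircArea(xs[i], ys[i], xs[j], ys[j], R);
  }
  return std::max(area, 0.0);
}

// Sutherland-Hodgman clip of a convex CCW polygon by alpha*x + beta*y <= gamma
static void clipHalfplane(std::vector<double>& xs, std::vector<double>& ys,
                          double alpha, double beta, double gamma) {
  const size_t n = xs.size();
  if (n == 0) return;
  std::vector<double> ox, oy;
  ox.reserve(n + 4);
  oy.reserve(n + 4);
  for (size_t i = 0; i < n; ++i) {
    size_t j = (i + 1) % n;
    double fi = alpha * xs[i] + beta * ys[i] - gamma;
    double fj = alpha * xs[j] + beta * ys[j] - gamma;
    bool iin = fi <= 0.0, jin = fj <= 0.0;
    if (iin) {
      ox.push_back(xs[i]);
      oy.push_back(ys[i]);
    }
    if (iin != jin) {
      double t = fi / (fi - fj);
      ox.push_back(xs[i] + t * (xs[j] - xs[i]));
      oy.push_back(ys[i] + t * (ys[j] - ys[i]));
    }
  }
  xs.swap(ox);
  ys.swap(oy);
}

struct CellGrid {
  double h, x0, y0, z0;
  int nx, ny, nz;
  std::unordered_map<long long, std::vector<int>> cells;

  long long key(int ix, int iy, int iz) const {
    return (static_cast<long long>(ix) * 1048576 + iy) * 1048576 + iz;
  }
  void build(const NumericMatrix& c, double cell) {
    h = cell;
    x0 = y0 = z0 = R_PosInf;
    for (int i = 0; i < c.nrow(); ++i) {
      x0 = std::min(x0, c(i, 0));
      y0 = std::min(y0, c(i, 1));
      z0 = std::min(z0, c(i, 2));
    }
    for (int i = 0; i < c.nrow(); ++i) {
      int ix = static_cast<int>(std::floor((c(i, 0) - x0) / h));
      int iy = static_cast<int>(std::floor((c(i, 1) - y0) / h));
      int iz = static_cast<int>(std::floor((c(i, 2) - z0) / h));
      cells[key(ix, iy, iz)].push_back(i);
    }
  }
  // all atoms in cells intersecting the ball (p, rad)
  void gather(double px, double py, double pz, double rad,
              std::vector<int>& out) const {
    out.clear();
    int ix0 = static_cast<int>(std::floor((px - rad - x0) / h));
    int ix1 = static_cast<int>(std::floor((px + rad - x0) / h));
    int iy0 = static_cast<int>(std::floor((py - rad - y0) / h));
    int iy1 = static_cast<int>(std::floor((py + rad - y0) / h));
    int iz0 = static_cast<int>(std::floor((pz - rad - z0) / h));
    int iz1 = static_cast<int>(std::floor((pz + rad - z0) / h));
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy)
        for (int iz = iz0; iz <= iz1; ++iz) {
          auto it = cells.find(key(ix, iy, iz));
          if (it != cells.end())
            out.insert(out.end(), it->second.begin(), it->second.end());
        }
  }
};

// [[Rcpp::export]]
List vt_contacts(NumericMatrix coords, NumericVector radii, double probe,
                 int nSphere, bool solvent) {
  const int n = coords.nrow();
  if (n < 1) stop("at least one ball is required");
  std::vector<double> R(n);
  double maxR = 0.0;
  for (int i = 0; i < n; ++i) {
    if (radii[i] <= 0.0) stop("all radii must be positive");
    R[i] = radii[i] + probe;
    maxR = std::max(maxR, R[i]);
  }

  CellGrid grid;
  grid.build(coords, std::max(2.0 * maxR, 1.0));

  std::vector<int> outI, outJ;
  std::vector<double> outA;
  std::vector<int> nb, clip;

  for (int i = 0; i < n; ++i) {
    const double cix = coords(i, 0), ciy = coords(i, 1), ciz = coords(i, 2);
    grid.gather(cix, ciy, ciz, R[i] + maxR, nb);
    for (int j : nb) {
      if (j <= i) continue;
      double dx = coords(j, 0) - cix, dy = coords(j, 1) - ciy,
             dz = coords(j, 2) - ciz;
      double d2 = dx * dx + dy * dy + dz * dz;
      double sumR = R[i] + R[j];
      if (d2 >= sumR * sumR) continue;
      if (d2 < 1e-12)
        stop("degenerate input: atoms %d and %d have coincident centers",
             i + 1, j + 1);
      double d = std::sqrt(d2);
      // radical plane at signed distance t from c_i along u = (c_j - c_i)/d
      double t = (d2 + R[i] * R[i] - R[j] * R[j]) / (2.0 * d);
      double rho2 = R[i] * R[i] - t * t;
      if (rho2 <= 0.0) continue;
      double rho = std::sqrt(rho2);
      double ux = dx / d, uy = dy / d, uz = dz / d;
      double p0x = cix + t * ux, p0y = ciy + t * uy, p0z = ciz + t * uz;
      // orthonormal basis of the plane
      double e1x, e1y, e1z;
      if (std::fabs(ux) < 0.9) {
        e1x = 0.0; e1y = -uz; e1z = uy;
      } else {
        e1x = -uz; e1y = 0.0; e1z = ux;
      }
      double norm = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
      e1x /= norm; e1y /= norm; e1z /= norm;
      double e2x = uy * e1z - uz * e1y;
      double e2y = uz * e1x - ux * e1z;
      double e2z = ux * e1y - uy * e1x;

      // start from a square slightly circumscribing the disk (CCW)
      double s = rho * 1.0001;
      std::vector<double> xs = {s, s, -s, -s};
      std::vector<double> ys = {-s, s, s, -s};

      grid.gather(p0x, p0y, p0z, rho + maxR, clip);
      bool empty = false;
      for (int k : clip) {
        if (k == i || k == j) continue;
        double kx = coords(k, 0) - p0x, ky = coords(k, 1) - p0y,
               kz = coords(k, 2) - p0z;
        double dd = std::sqrt(kx * kx + ky * ky + kz * kz);
        if (dd >= R[k] + rho) continue;  // cannot cut the disk
        // pow_i(x) <= pow_k(x) as a half-plane in (a, b) plane coordinates
        double gx = coords(k, 0) - cix, gy = coords(k, 1) - ciy,
               gz = coords(k, 2) - ciz;
        double alpha = 2.0 * (gx * e1x + gy * e1y + gz * e1z);
        double beta = 2.0 * (gx * e2x + gy * e2y + gz * e2z);
        double Ck = gx * gx + gy * gy + gz * gz - R[k] * R[k] + R[i] * R[i];
        double p0g = (p0x - cix) * gx + (p0y - ciy) * gy + (p0z - ciz) * gz;
        double gamma = Ck - 2.0 * p0g;
        clipHalfplane(xs, ys, alpha, beta, gamma);
        if (xs.size() < 3) {
          empty = true;
          break;
        }
      }
      if (empty) continue;
      double area = circPolyArea(xs, ys, rho);
      if (area > 1e-6) {
        outI.push_back(i + 1);
        outJ.push_back(j + 1);
        outA.push_back(area);
      }
    }
  }

  NumericVector solv(n, NA_REAL);
  if (solvent) {
    const double ga = M_PI * (3.0 - std::sqrt(5.0));  // golden angle
    for (int i = 0; i < n; ++i) {
      const double cix = coords(i, 0), ciy = coords(i, 1), ciz = coords(i, 2);
      grid.gather(cix, ciy, ciz, R[i] + maxR, nb);
      std::vector<int> close;
      for (int k : nb) {
        if (k == i) continue;
        double dx = coords(k, 0) - cix, dy = coords(k, 1) - ciy,
               dz = coords(k, 2) - ciz;
        double d2 = dx * dx + dy * dy + dz * dz;
        double sumR = R[i] + R[k];
        if (d2 < sumR * sumR) close.push_back(k);
      }
      int exposed = 0;
      for (int m = 0; m < nSphere; ++m) {
        double z = 1.0 - 2.0 * (m + 0.5) / nSphere;
        double r = std::sqrt(std::max(1.0 - z * z, 0.0));
        double phi = ga * m;
        double px = cix + R[i] * r * std::cos(phi);
        double py = ciy + R[i] * r * std::sin(phi);
        double pz = ciz + R[i] * z;
        bool buried = false;
        for (int k : close) {
          double dx = px - coords(k, 0), dy = py - coords(k, 1),
                 dz = pz - coords(k, 2);
          if (dx * dx + dy * dy + dz * dz < R[k] * R[k]) {
            buried = true;
            break;
          }
        }
        if (!buried) ++exposed;
      }
      solv[i] = 4.0 * M_PI * R[i] * R[i] * exposed / nSphere;
    }
  }

  return List::create(_["i"] = wrap(outI), _["j"] = wrap(outJ),
                      _["area"] = wrap(outA), _["solvent"] = solv);
}
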