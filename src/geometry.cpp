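#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double det3(double ax, double ay, double az,
                          double bx, double by, double bz,
                          double cx, double cy, double cz) {
  return ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
         az * (bx * cy - by * cx);
}

// Locate query directions in a spherical triangulation by exhaustive scan.
// pos: V x 3 unit vectors, faces: F x 3 one-based, q: Q x 3.
// Containment by sign-consistent gnomonic barycentric coordinates; the best
// face (largest normalized minimum coordinate) is returned even when no face
// contains the query exactly, so vertices/edges resolve robustly.
// [[Rcpp::export]]
List cpp_locate(NumericMatrix pos, IntegerMatrix faces, NumericMatrix q) {
  const int F = faces.nrow(), Q = q.nrow();
  std::vector<double> fx(3 * F), fy(3 * F), fz(3 * F), fdet(F);
  for (int f = 0; f < F; ++f) {
    for (int k = 0; k < 3; ++k) {
      int v = faces(f, k) - 1;
      fx[3 * f + k] = pos(v, 0);
      fy[3 * f + k] = pos(v, 1);
      fz[3 * f + k] = pos(v, 2);
    }
    fdet[f] = det3(fx[3 * f], fy[3 * f], fz[3 * f],
                   fx[3 * f + 1], fy[3 * f + 1], fz[3 * f + 1],
                   fx[3 * f + 2], fy[3 * f + 2], fz[3 * f + 2]);
  }
  IntegerVector out_face(Q);
  NumericMatrix out_bary(Q, 3);
  for (int i = 0; i < Q; ++i) {
    const double qx = q(i, 0), qy = q(i, 1), qz = q(i, 2);
    double best = -1e300;
    int bestf = -1;
    double bb0 = 0, bb1 = 0, bb2 = 0;
    for (int f = 0; f < F; ++f) {
      const double D = fdet[f];
      const double aD = std::fabs(D);
      if (aD < 1e-300) continue;
      const double s = (D > 0) ? 1.0 : -1.0;
      const double d0 = s * det3(qx, qy, qz,
                                 fx[3 * f + 1], fy[3 * f + 1], fz[3 * f + 1],
                                 fx[3 * f + 2], fy[3 * f + 2], fz[3 * f + 2]);
      if (d0 < -0.5 * aD) continue;  // early reject far faces
      const double d1 = s * det3(fx[3 * f], fy[3 * f], fz[3 * f],
                                 qx, qy, qz,
                                 fx[3 * f + 2], fy[3 * f + 2], fz[3 * f + 2]);
      const double d2 = s * det3(fx[3 * f], fy[3 * f], fz[3 * f],
                                 fx[3 * f + 1], fy[3 * f + 1], fz[3 * f + 1],
                                 qx, qy, qz);
      double m = d0;
      if (d1 < m) m = d1;
      if (d2 < m) m = d2;
      const double score = m / aD;
      if (score > best) {
        best = score;
        bestf = f;
        const double tot = d0 + d1 + d2;
        if (std::fabs(tot) > 1e-300) {
          bb0 = d0 / tot; bb1 = d1 / tot; bb2 = d2 / tot;
        } else {
          bb0 = bb1 = bb2 = 1.0 / 3.0;
        }
        if (score > 1e-9 && score > 0.3) break;  // safely interior: stop early
      }
    }
    if (bestf < 0) stop("cpp_locate: mesh has no non-degenerate faces");
    // clamp tiny negatives (query on an edge/vertex) and renormalize
    if (bb0 < 0) bb0 = 0;
    if (bb1 < 0) bb1 = 0;
    if (bb2 < 0) bb2 = 0;
    double tot = bb0 + bb1 + bb2;
    if (tot <= 0) { bb0 = bb1 = bb2 = 1.0 / 3.0; tot = 1.0; }
    out_face[i] = bestf + 1;
    out_bary(i, 0) = bb0 / tot;
    out_bary(i, 1) = bb1 / tot;
    out_bary(i, 2) = bb2 / tot;
  }
  return List::create(_["face"] = out_face, _["bary"] = out_bary,
                      _["containment"] = R_NilValue);
}

static inline double ang(double ax, double ay, double az,
                         double bx, double by, double bz) {
  // robust angle between unit vectors via atan2(|a x b|, a.b)
  double cx = ay * bz - az * by, cy = az * bx - ax * bz, cz = ax * by - ay * bx;
  double s = std::sqrt(cx * cx + cy * cy + cz * cz);
  double c = ax * bx + ay * by + az * bz;
  return std::atan2(s, c);
}

static double sph_tri_area(double ax, double ay, double az,
                           double bx, double by, double bz,
                           double cx, double cy, double cz) {
  // l'Huilier's theorem for spherical excess on the unit sphere
  double A = ang(bx, by, bz, cx, cy, cz);
  double B = ang(ax, ay, az, cx, cy, cz);
  double C = ang(ax, ay, az, bx, by, bz);
  double s = 0.5 * (A + B + C);
  double t = std::tan(0.5 * s) * std::tan(0.5 * (s - A)) *
             std::tan(0.5 * (s - B)) * std::tan(0.5 * (s - C));
  if (t < 0) t = 0;
  return 4.0 * std::atan(std::sqrt(t));
}

// [[Rcpp::export]]
NumericVector cpp_sph_areas(NumericMatrix pos, IntegerMatrix faces) {
  const int F = faces.nrow();
  NumericVector out(F);
  for (int f = 0; f < F; ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    out[f] = sph_tri_area(pos(a, 0), pos(a, 1), pos(a, 2),
                          pos(b, 0), pos(b, 1), pos(b, 2),
                          pos(c, 0), pos(c, 1), pos(c, 2));
  }
  return out;
}

// Objective E = sum_f ((A_f / (4 pi * tfrac_f)) - 1)^2 and its per-vertex
// tangential gradient by central differences (step h radians). Only faces
// incident to the probed vertex are recomputed.
// [[Rcpp::export]]
List cpp_area_grad(NumericMatrix pos, IntegerMatrix faces,
                   NumericVector tfrac, double h) {
  const int V = pos.nrow(), F = faces.nrow();
  const double FOURPI = 4.0 * M_PI;
  std::vector<std::vector<int>> inc(V);
  for (int f = 0; f < F; ++f)
    for (int k = 0; k < 3; ++k) inc[faces(f, k) - 1].push_back(f);
  std::vector<double> area(F);
  double E = 0;
  for (int f = 0; f < F; ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    area[f] = sph_tri_area(pos(a, 0), pos(a, 1), pos(a, 2),
                           pos(b, 0), pos(b, 1), pos(b, 2),
                           pos(c, 0), pos(c, 1), pos(c, 2));
    double r = area[f] / (FOURPI * tfrac[f]) - 1.0;
    E += r * r;
  }
  NumericMatrix grad(V, 3);
  std::vector<double> P(9);
  for (int v = 0; v < V; ++v) {
    double px = pos(v, 0), py = pos(v, 1), pz = pos(v, 2);
    // tangent basis
    double t1x, t1y, t1z;
    if (std::fabs(pz) < 0.9) { t1x = -py; t1y = px; t1z = 0; }
    else { t1x = 0; t1y = -pz; t1z = py; }
    double n1 = std::sqrt(t1x * t1x + t1y * t1y + t1z * t1z);
    t1x /= n1; t1y /= n1; t1z /= n1;
    double t2x = py * t1z - pz * t1y;
    double t2y = pz * t1x - px * t1z;
    double t2z = px * t1y - py * t1x;
    double g[2];
    for (int d = 0; d < 2; ++d) {
      double tx = d ? t2x : t1x, ty = d ? t2y : t1y, tz = d ? t2z : t1z;
      double Ed[2];
      for (int sgn = 0; sgn < 2; ++sgn) {
        double sg = sgn ? -h : h;
        double nx = px + sg * tx, ny = py + sg * ty, nz = pz + sg * tz;
        double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
        nx /= nn; ny /= nn; nz /= nn;
        double Eloc = 0;
        for (size_t kk = 0; kk < inc[v].size(); ++kk) {
          int f = inc[v][kk];
          for (int k = 0; k < 3; ++k) {
            int w = faces(f, k) - 1;
            if (w == v) { P[3 * k] = nx; P[3 * k + 1] = ny; P[3 * k + 2] = nz; }
            else { P[3 * k] = pos(w, 0); P[3 * k + 1] = pos(w, 1); P[3 * k + 2] = pos(w, 2); }
          }
          double Af = sph_tri_area(P[0], P[1], P[2], P[3], P[4], P[5],
                                   P[6], P[7], P[8]);
          double r = Af / (FOURPI * tfrac[f]) - 1.0;
          // subtract the unperturbed contribution, add perturbed
          double r0 = area[f] / (FOURPI * tfrac[f]) - 1.0;
          Eloc += r * r - r0 * r0;
        }
        Ed[sgn] = Eloc;
      }
      g[d] = (Ed[0] - Ed[1]) / (2 * h);
    }
    grad(v, 0) = g[0] * t1x + g[1] * t2x;
    grad(v, 1) = g[0] * t1y + g[1] * t2y;
    grad(v, 2) = g[0] * t1z + g[1] * t2z;
  }
  return List::create(_["objective"] = E, _["grad"] = grad);
}
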