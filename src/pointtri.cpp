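#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact minimum distance from each query point to a triangle mesh
// (closest-point-on-triangle via barycentric region clamping).
static inline double tri_dist2(const double *p, const double *a,
                               const double *b, const double *c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k];
  }
  const double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  const double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double u, v; // barycentric of closest point: a + u*ab + v*ac
  if (d1 <= 0.0 && d2 <= 0.0) { u = 0.0; v = 0.0; }
  else {
    double bp[3], cp[3];
    for (int k = 0; k < 3; ++k) { bp[k] = p[k] - b[k]; cp[k] = p[k] - c[k]; }
    const double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    const double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    const double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    const double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d3 >= 0.0 && d4 <= d3) { u = 1.0; v = 0.0; }
    else if (d6 >= 0.0 && d5 <= d6) { u = 0.0; v = 1.0; }
    else {
      const double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        u = d1 / (d1 - d3); v = 0.0;
      } else {
        const double vb = d5 * d2 - d1 * d6;
        if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
          u = 0.0; v = d2 / (d2 - d6);
        } else {
          const double va = d3 * d6 - d5 * d4;
          if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
            const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
            u = 1.0 - w; v = w;
          } else {
            const double denom = 1.0 / (va + vb + vc);
            u = vb * denom; v = vc * denom;
          }
        }
      }
    }
  }
  double dx = ap[0] - u * ab[0] - v * ac[0];
  double dy = ap[1] - u * ab[1] - v * ac[1];
  double dz = ap[2] - u * ab[2] - v * ac[2];
  return dx * dx + dy * dy + dz * dz;
}

static inline void tri_closest(const double *p, const double *a,
                               const double *b, const double *c,
                               double *q) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k];
  }
  const double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  const double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double u = 0.0, v = 0.0;
  if (!(d1 <= 0.0 && d2 <= 0.0)) {
    double bp[3], cp[3];
    for (int k = 0; k < 3; ++k) { bp[k] = p[k] - b[k]; cp[k] = p[k] - c[k]; }
    const double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    const double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    const double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    const double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d3 >= 0.0 && d4 <= d3) { u = 1.0; v = 0.0; }
    else if (d6 >= 0.0 && d5 <= d6) { u = 0.0; v = 1.0; }
    else {
      const double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) { u = d1 / (d1 - d3); v = 0.0; }
      else {
        const double vb = d5 * d2 - d1 * d6;
        if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) { u = 0.0; v = d2 / (d2 - d6); }
        else {
          const double va = d3 * d6 - d5 * d4;
          if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
            const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
            u = 1.0 - w; v = w;
          } else {
            const double denom = 1.0 / (va + vb + vc);
            u = vb * denom; v = vc * denom;
          }
        }
      }
    }
  }
  for (int k = 0; k < 3; ++k) q[k] = a[k] + u * ab[k] + v * ac[k];
}

// Closest surface points (and distances) from each query to the mesh.
// [[Rcpp::export]]
List point_mesh_closest_cpp(NumericMatrix P, NumericMatrix V,
                            IntegerMatrix F) {
  const int n = P.nrow(), m = F.nrow();
  NumericVector dist(n);
  NumericMatrix Q(n, 3);
  for (int i = 0; i < n; ++i) {
    const double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = R_PosInf;
    double bq[3] = {0, 0, 0};
    for (int t = 0; t < m; ++t) {
      const int i0 = F(t, 0), i1 = F(t, 1), i2 = F(t, 2);
      const double a[3] = {V(i0, 0), V(i0, 1), V(i0, 2)};
      const double b[3] = {V(i1, 0), V(i1, 1), V(i1, 2)};
      const double c[3] = {V(i2, 0), V(i2, 1), V(i2, 2)};
      double q[3];
      tri_closest(p, a, b, c, q);
      const double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bq[0] = q[0]; bq[1] = q[1]; bq[2] = q[2]; }
    }
    dist[i] = std::sqrt(best);
    Q(i, 0) = bq[0]; Q(i, 1) = bq[1]; Q(i, 2) = bq[2];
  }
  return List::create(_["dist"] = dist, _["closest"] = Q);
}

// [[Rcpp::export]]
NumericVector point_mesh_distance_cpp(NumericMatrix P, NumericMatrix V,
                                      IntegerMatrix F) {
  const int n = P.nrow(), m = F.nrow();
  NumericVector out(n);
  std::vector<double> vx(V.nrow()), vy(V.nrow()), vz(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) {
    vx[i] = V(i, 0); vy[i] = V(i, 1); vz[i] = V(i, 2);
  }
  // triangle bounding spheres for cheap pruning
  std::vector<double> cx(m), cy(m), cz(m), cr(m);
  for (int t = 0; t < m; ++t) {
    const int i0 = F(t, 0), i1 = F(t, 1), i2 = F(t, 2);
    cx[t] = (vx[i0] + vx[i1] + vx[i2]) / 3.0;
    cy[t] = (vy[i0] + vy[i1] + vy[i2]) / 3.0;
    cz[t] = (vz[i0] + vz[i1] + vz[i2]) / 3.0;
    double r2 = 0.0;
    const int ids[3] = {i0, i1, i2};
    for (int k = 0; k < 3; ++k) {
      const double dx = vx[ids[k]] - cx[t], dy = vy[ids[k]] - cy[t],
                   dz = vz[ids[k]] - cz[t];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    cr[t] = std::sqrt(r2);
  }
  for (int i = 0; i < n; ++i) {
    const double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = R_PosInf, bestd = R_PosInf;
    for (int t = 0; t < m; ++t) {
      const double dx = p[0] - cx[t], dy = p[1] - cy[t], dz = p[2] - cz[t];
      const double dc = std::sqrt(dx * dx + dy * dy + dz * dz) - cr[t];
      if (dc > bestd) continue;
      const int i0 = F(t, 0), i1 = F(t, 1), i2 = F(t, 2);
      const double a[3] = {vx[i0], vy[i0], vz[i0]};
      const double b[3] = {vx[i1], vy[i1], vz[i1]};
      const double c[3] = {vx[i2], vy[i2], vz[i2]};
      const double d2 = tri_dist2(p, a, b, c);
      if (d2 < best) { best = d2; bestd = std::sqrt(best); }
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
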