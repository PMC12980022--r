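#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Voxelize a closed, outward-oriented triangle mesh (or a union of such
// components) on a regular grid by counting signed ray crossings along +z.
// Travelling upward, crossing a triangle with outward normal n_z < 0 enters
// solid material (+1) and n_z > 0 leaves it (-1); a voxel centre is inside
// when the running count is positive, which handles overlapping closed
// components as their union.
//
// V: n x 3 vertices (mm); F: m x 3 zero-based faces; origin: grid corner of
// voxel (0,0,0) centre; dims: (nx, ny, nz). Returns logical occupancy of
// length nx*ny*nz in x-fastest order.
// [[Rcpp::export]]
LogicalVector voxelize_cpp(NumericMatrix V, IntegerMatrix F,
                           NumericVector origin, double spacing,
                           IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int m = F.nrow();
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  // per-(x,y)-column list of signed crossings
  std::vector< std::vector< std::pair<double, int> > > cols((size_t)nx * ny);

  for (int t = 0; t < m; ++t) {
    const int i0 = F(t, 0), i1 = F(t, 1), i2 = F(t, 2);
    const double x0 = V(i0, 0), y0 = V(i0, 1), z0 = V(i0, 2);
    const double x1 = V(i1, 0), y1 = V(i1, 1), z1 = V(i1, 2);
    const double x2 = V(i2, 0), y2 = V(i2, 1), z2 = V(i2, 2);
    // outward normal z-component from CCW winding
    const double nzc = (x1 - x0) * (y2 - y0) - (y1 - y0) * (x2 - x0);
    if (std::fabs(nzc) < 1e-14) continue; // vertical face: no z-crossing
    const int sign = nzc > 0 ? -1 : +1;   // n_z<0 enters (+1) going up
    const double xmin = std::min(x0, std::min(x1, x2));
    const double xmax = std::max(x0, std::max(x1, x2));
    const double ymin = std::min(y0, std::min(y1, y2));
    const double ymax = std::max(y0, std::max(y1, y2));
    int ix0 = (int)std::ceil((xmin - ox) / spacing);
    int ix1 = (int)std::floor((xmax - ox) / spacing);
    int iy0 = (int)std::ceil((ymin - oy) / spacing);
    int iy1 = (int)std::floor((ymax - oy) / spacing);
    if (ix0 < 0) ix0 = 0; if (iy0 < 0) iy0 = 0;
    if (ix1 > nx - 1) ix1 = nx - 1; if (iy1 > ny - 1) iy1 = ny - 1;
    const double inv = 1.0 / nzc;
    for (int iy = iy0; iy <= iy1; ++iy) {
      const double py = oy + iy * spacing;
      for (int ix = ix0; ix <= ix1; ++ix) {
        const double px = ox + ix * spacing;
        // barycentric inside test in the xy-plane
        const double w0 = ((x1 - px) * (y2 - py) - (y1 - py) * (x2 - px)) * inv;
        const double w1 = ((x2 - px) * (y0 - py) - (y2 - py) * (x0 - px)) * inv;
        const double w2 = 1.0 - w0 - w1;
        if (w0 < 0.0 || w1 < 0.0 || w2 < 0.0) continue;
        const double z = w0 * z0 + w1 * z1 + w2 * z2;
        cols[(size_t)iy * nx + ix].push_back(std::make_pair(z, sign));
      }
    }
  }

  LogicalVector occ((R_xlen_t)nx * ny * nz);
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      std::vector< std::pair<double, int> > &cr = cols[(size_t)iy * nx + ix];
      if (cr.empty()) continue;
      std::sort(cr.begin(), cr.end());
      size_t k = 0;
      int depth = 0;
      for (int iz = 0; iz < nz; ++iz) {
        const double pz = oz + iz * spacing;
        while (k < cr.size() && cr[k].first <= pz) { depth += cr[k].second; ++k; }
        if (depth > 0)
          occ[(R_xlen_t)iz * nx * ny + (R_xlen_t)iy * nx + ix] = true;
      }
    }
  }
  return occ;
}
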