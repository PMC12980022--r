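#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Truncated Gaussian splat kernel with a C1 roll-off at the cutoff.
// In terms of s = r^2 / (2 sigma^2) and s_c = cut^2 / 2:
//   phi(s)  = exp(-s) - exp(-s_c) + exp(-s_c) * (s - s_c)   for s < s_c
//   phi'(s) = -exp(-s) + exp(-s_c)
// phi(s_c) = phi'(s_c) = 0, so both the rendered image and its gradient
// are continuous as splat footprints slide across pixel-window boundaries.

// [[Rcpp::export]]
NumericMatrix splat_forward_cpp(NumericVector u, NumericVector v,
                                NumericVector sigma, NumericVector amp,
                                int H, int W, double cut) {
  const int n = u.size();
  NumericMatrix img(H, W);
  const double sc = 0.5 * cut * cut;
  const double esc = std::exp(-sc);
  for (int p = 0; p < n; ++p) {
    const double up = u[p], vp = v[p], sg = sigma[p], A = amp[p];
    if (!R_finite(up) || !R_finite(vp) || sg <= 0.0) continue;
    const double rad = cut * sg;
    int c0 = (int)std::ceil(up - rad), c1 = (int)std::floor(up + rad);
    int r0 = (int)std::ceil(vp - rad), r1 = (int)std::floor(vp + rad);
    if (c0 < 0) c0 = 0; if (r0 < 0) r0 = 0;
    if (c1 > W - 1) c1 = W - 1; if (r1 > H - 1) r1 = H - 1;
    const double inv2s2 = 1.0 / (2.0 * sg * sg);
    for (int r = r0; r <= r1; ++r) {
      const double dv = (double)r - vp;
      for (int c = c0; c <= c1; ++c) {
        const double du = (double)c - up;
        const double s = (du * du + dv * dv) * inv2s2;
        if (s >= sc) continue;
        img(r, c) += A * (std::exp(-s) - esc + esc * (s - sc));
      }
    }
  }
  return img;
}

// Backward pass: given dL/dI, accumulate dL/du, dL/dv, dL/dsigma per splat.
//   dg/du_p    = A * phi'(s) * ds/du_p,  ds/du_p = -(u_px - u_p)/sigma^2
//   dg/dsigma  = A * phi'(s) * (-2 s / sigma)
// [[Rcpp::export]]
NumericMatrix splat_backward_cpp(NumericVector u, NumericVector v,
                                 NumericVector sigma, NumericVector amp,
                                 int H, int W, double cut,
                                 NumericMatrix dLdI) {
  const int n = u.size();
  NumericMatrix grad(n, 3); // columns: d/du, d/dv, d/dsigma
  const double sc = 0.5 * cut * cut;
  const double esc = std::exp(-sc);
  for (int p = 0; p < n; ++p) {
    const double up = u[p], vp = v[p], sg = sigma[p], A = amp[p];
    if (!R_finite(up) || !R_finite(vp) || sg <= 0.0) continue;
    const double rad = cut * sg;
    int c0 = (int)std::ceil(up - rad), c1 = (int)std::floor(up + rad);
    int r0 = (int)std::ceil(vp - rad), r1 = (int)std::floor(vp + rad);
    if (c0 < 0) c0 = 0; if (r0 < 0) r0 = 0;
    if (c1 > W - 1) c1 = W - 1; if (r1 > H - 1) r1 = H - 1;
    const double inv2s2 = 1.0 / (2.0 * sg * sg);
    const double invs2 = 1.0 / (sg * sg);
    double gu = 0.0, gv = 0.0, gs = 0.0;
    for (int r = r0; r <= r1; ++r) {
      const double dv = (double)r - vp;
      for (int c = c0; c <= c1; ++c) {
        const double du = (double)c - up;
        const double s = (du * du + dv * dv) * inv2s2;
        if (s >= sc) continue;
        const double w = dLdI(r, c);
        if (w == 0.0) continue;
        const double dphi = -std::exp(-s) + esc; // phi'(s)
        const double common = w * A * dphi;
        gu += common * (-du * invs2);
        gv += common * (-dv * invs2);
        gs += common * (-2.0 * s / sg);
      }
    }
    grad(p, 0) = gu; grad(p, 1) = gv; grad(p, 2) = gs;
  }
  return grad;
}
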