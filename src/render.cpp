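#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Radiological path of one ray through an axis-aligned voxel volume of linear
// attenuation coefficients (mm^-1). Incremental Siddon / Amanatides-Woo
// traversal: the ray is clipped to the volume bounding box, axis-crossing
// parameters are visited in sorted order and each voxel contributes
// mu * segment length (direction is unit-norm, so t is in mm). Voxels are
// half-open boxes [t_i, t_{i+1}) so exact plane crossings are unambiguous.
static double siddon_path(const double* mu,
                          int nx, int ny, int nz,
                          const double* origin, const double* spacing,
                          const double* src, const double* dir) {
  const double eps = 1e-12;
  double lo[3], hi[3];
  int n[3] = {nx, ny, nz};
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a] - 0.5 * spacing[a];
    hi[a] = origin[a] + (n[a] - 0.5) * spacing[a];
  }
  // slab clipping
  double t0 = 0.0, t1 = std::numeric_limits<double>::infinity();
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dir[a]) < eps) {
      if (src[a] < lo[a] || src[a] >= hi[a]) return 0.0;
    } else {
      double ta = (lo[a] - src[a]) / dir[a];
      double tb = (hi[a] - src[a]) / dir[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t1 <= t0) return 0.0;

  // entry voxel
  double t = t0;
  int idx[3];
  for (int a = 0; a < 3; ++a) {
    double p = src[a] + (t + eps) * dir[a];
    int i = (int)std::floor((p - lo[a]) / spacing[a]);
    if (i < 0) i = 0;
    if (i >= n[a]) i = n[a] - 1;
    idx[a] = i;
  }
  // per-axis step and next-crossing parameter
  double tMax[3], tDelta[3];
  int step[3];
  for (int a = 0; a < 3; ++a) {
    if (dir[a] > eps) {
      step[a] = 1;
      tMax[a] = ((lo[a] + (idx[a] + 1) * spacing[a]) - src[a]) / dir[a];
      tDelta[a] = spacing[a] / dir[a];
    } else if (dir[a] < -eps) {
      step[a] = -1;
      tMax[a] = ((lo[a] + idx[a] * spacing[a]) - src[a]) / dir[a];
      tDelta[a] = -spacing[a] / dir[a];
    } else {
      step[a] = 0;
      tMax[a] = std::numeric_limits<double>::infinity();
      tDelta[a] = std::numeric_limits<double>::infinity();
    }
  }

  double total = 0.0;
  while (t < t1 - eps) {
    int a = 0;
    if (tMax[1] < tMax[a]) a = 1;
    if (tMax[2] < tMax[a]) a = 2;
    double tNext = std::min(tMax[a], t1);
    double m = mu[idx[0] + (size_t)nx * (idx[1] + (size_t)ny * idx[2])];
    if (m > 0) total += m * (tNext - t);
    t = tNext;
    if (tMax[a] <= t1) {
      idx[a] += step[a];
      if (idx[a] < 0 || idx[a] >= n[a]) break;
      tMax[a] += tDelta[a];
    } else {
      break;
    }
  }
  return total;
}

// [[Rcpp::export(name = ".siddon_path_cpp")]]
double siddon_path_cpp(NumericVector mu, IntegerVector dims,
                       NumericVector origin, NumericVector spacing,
                       NumericVector src, NumericVector dir) {
  return siddon_path(mu.begin(), dims[0], dims[1], dims[2],
                     origin.begin(), spacing.begin(), src.begin(), dir.begin());
}

// Render a full projection: one ray per pixel center of an (nu x nv) grid on
// the panel. det00 is the physical position of pixel (0,0); du/dv are the
// panel axis steps (pitch * axis), already including any downsampling.
// Returns an nu x nv matrix of radiological paths.
// [[Rcpp::export(name = ".render_drr_cpp")]]
NumericMatrix render_drr_cpp(NumericVector mu, IntegerVector dims,
                             NumericVector origin, NumericVector spacing,
                             NumericVector src,
                             NumericVector det00,
                             NumericVector du, NumericVector dv,
                             int nu, int nv) {
  NumericMatrix out(nu, nv);
  double dir[3], p[3];
  for (int v = 0; v < nv; ++v) {
    for (int u = 0; u < nu; ++u) {
      double nrm = 0.0;
      for (int a = 0; a < 3; ++a) {
        p[a] = det00[a] + u * du[a] + v * dv[a];
        dir[a] = p[a] - src[a];
        nrm += dir[a] * dir[a];
      }
      nrm = std::sqrt(nrm);
      for (int a = 0; a < 3; ++a) dir[a] /= nrm;
      out(u, v) = siddon_path(mu.begin(), dims[0], dims[1], dims[2],
                              origin.begin(), spacing.begin(), src.begin(), dir);
    }
  }
  return out;
}

// Zero-normalized cross-correlation of a template patch against an image over
// integer offsets in [u0, u1] x [v0, v1] (0-based position of the patch's
// top-left pixel). Returns the best offset and correlation.
// [[Rcpp::export(name = ".zncc_search_cpp")]]
List zncc_search_cpp(NumericMatrix image, NumericMatrix patch,
                     int u0, int u1, int v0, int v1) {
  int pu = patch.nrow(), pv = patch.ncol();
  int nu = image.nrow(), nv = image.ncol();
  double pmean = 0.0;
  for (int j = 0; j < pv; ++j)
    for (int i = 0; i < pu; ++i) pmean += patch(i, j);
  pmean /= (double)(pu * pv);
  double pss = 0.0;
  for (int j = 0; j < pv; ++j)
    for (int i = 0; i < pu; ++i) {
      double d = patch(i, j) - pmean;
      pss += d * d;
    }
  double best = -2.0;
  int bu = NA_INTEGER, bv = NA_INTEGER;
  if (pss <= 0) return List::create(_["u"] = bu, _["v"] = bv, _["zncc"] = NA_REAL);
  for (int ov = std::max(v0, 0); ov <= std::min(v1, nv - pv); ++ov) {
    for (int ou = std::max(u0, 0); ou <= std::min(u1, nu - pu); ++ou) {
      double s = 0, ss = 0, sp = 0;
      for (int j = 0; j < pv; ++j)
        for (int i = 0; i < pu; ++i) {
          double x = image(ou + i, ov + j);
          s += x; ss += x * x;
          sp += x * (patch(i, j) - pmean);
        }
      double npx = (double)(pu * pv);
      double iss = ss - s * s / npx;
      if (iss <= 0) continue;
      double c = sp / std::sqrt(iss * pss);
      if (c > best) { best = c; bu = ou; bv = ov; }
    }
  }
  if (bu == NA_INTEGER)
    return List::create(_["u"] = bu, _["v"] = bv, _["zncc"] = NA_REAL);
  return List::create(_["u"] = bu, _["v"] = bv, _["zncc"] = best);
}
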