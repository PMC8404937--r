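// Ray-driven forward projection (Joseph's method: linear interpolation along
// the ray's minor axis, stepping one pixel along the major axis) and pixel-
// driven back-projection, for parallel and fan (flat, virtual detector at the
// rotation axis) geometries.
//
// Conventions:
//   - pixel size 1, image centred on the rotation axis: pixel (r, c) of an
//     H x W matrix sits at x = c - (W-1)/2, y = r - (H-1)/2
//   - view angle theta (radians): parallel ray direction d = (-sin t, cos t),
//     detector axis e_s = (cos t, sin t), offset s measured along e_s
//   - fan source at S = SAD * (sin b, -cos b); detector coordinate u measured
//     on the virtual detector line through the origin along e_u = (cos b, sin b)
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static double joseph_ray(const mat& img, double p0x, double p0y,
                         double dx, double dy) {
  const int H = img.n_rows, W = img.n_cols;
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  double acc = 0.0;
  if (std::fabs(dx) >= std::fabs(dy)) {
    const double w = 1.0 / std::fabs(dx);
    for (int c = 0; c < W; ++c) {
      double x = c - cx;
      double t = (x - p0x) / dx;
      double r = p0y + t * dy + cy;
      int r0 = (int)std::floor(r);
      double f = r - r0;
      if (r0 >= 0 && r0 < H) acc += (1.0 - f) * img(r0, c) * w;
      if (r0 + 1 >= 0 && r0 + 1 < H) acc += f * img(r0 + 1, c) * w;
    }
  } else {
    const double w = 1.0 / std::fabs(dy);
    for (int r = 0; r < H; ++r) {
      double y = r - cy;
      double t = (y - p0y) / dy;
      double cc = p0x + t * dx + cx;
      int c0 = (int)std::floor(cc);
      double f = cc - c0;
      if (c0 >= 0 && c0 < W) acc += (1.0 - f) * img(r, c0) * w;
      if (c0 + 1 >= 0 && c0 + 1 < W) acc += f * img(r, c0 + 1) * w;
    }
  }
  return acc;
}

// [[Rcpp::export]]
arma::mat cpp_forward_parallel(const arma::mat& img,
                               const arma::vec& angles,
                               const arma::vec& offsets) {
  mat sino(angles.n_elem, offsets.n_elem);
  for (uword v = 0; v < angles.n_elem; ++v) {
    double ct = std::cos(angles[v]), st = std::sin(angles[v]);
    for (uword d = 0; d < offsets.n_elem; ++d) {
      double s = offsets[d];
      sino(v, d) = joseph_ray(img, s * ct, s * st, -st, ct);
    }
  }
  return sino;
}

// [[Rcpp::export]]
arma::mat cpp_forward_fan(const arma::mat& img,
                          const arma::vec& betas,
                          const arma::vec& offsets,
                          double sad) {
  mat sino(betas.n_elem, offsets.n_elem);
  for (uword v = 0; v < betas.n_elem; ++v) {
    double cb = std::cos(betas[v]), sb = std::sin(betas[v]);
    double sx = sad * sb, sy = -sad * cb;       // source
    for (uword d = 0; d < offsets.n_elem; ++d) {
      double u = offsets[d];
      double qx = u * cb, qy = u * sb;          // point on virtual detector
      double dx = qx - sx, dy = qy - sy;
      double nrm = std::sqrt(dx * dx + dy * dy);
      sino(v, d) = joseph_ray(img, sx, sy, dx / nrm, dy / nrm);
    }
  }
  return sino;
}

// Pixel-driven back-projection of filtered rows; caller applies the angular
// step scaling.  Linear interpolation in the detector coordinate.
// [[Rcpp::export]]
arma::mat cpp_backproject_parallel(const arma::mat& fsino,
                                   const arma::vec& angles,
                                   const arma::vec& offsets,
                                   int out_size) {
  const int N = out_size;
  const double c0 = (N - 1) / 2.0;
  const int nd = fsino.n_cols;
  const double o0 = offsets[0];
  const double ds = (nd > 1) ? (offsets[1] - offsets[0]) : 1.0;
  mat rec(N, N, fill::zeros);
  for (uword v = 0; v < angles.n_elem; ++v) {
    double ct = std::cos(angles[v]), st = std::sin(angles[v]);
    const double* row = fsino.memptr();  // column-major: element (v, d)
    for (int c = 0; c < N; ++c) {
      double x = c - c0;
      for (int r = 0; r < N; ++r) {
        double y = r - c0;
        double s = x * ct + y * st;
        double di = (s - o0) / ds;
        int d0 = (int)std::floor(di);
        if (d0 < 0 || d0 + 1 >= nd) continue;
        double f = di - d0;
        double val = (1.0 - f) * fsino(v, d0) + f * fsino(v, d0 + 1);
        rec(r, c) += val;
      }
    }
    (void)row;
  }
  return rec;
}

// [[Rcpp::export]]
arma::mat cpp_backproject_fan(const arma::mat& fsino,
                              const arma::vec& betas,
                              const arma::vec& offsets,
                              int out_size, double sad) {
  const int N = out_size;
  const double c0 = (N - 1) / 2.0;
  const int nd = fsino.n_cols;
  const double o0 = offsets[0];
  const double ds = (nd > 1) ? (offsets[1] - offsets[0]) : 1.0;
  mat rec(N, N, fill::zeros);
  for (uword v = 0; v < betas.n_elem; ++v) {
    double cb = std::cos(betas[v]), sb = std::sin(betas[v]);
    double sx = sad * sb, sy = -sad * cb;
    for (int c = 0; c < N; ++c) {
      double x = c - c0;
      for (int r = 0; r < N; ++r) {
        double y = r - c0;
        double vx = x - sx, vy = y - sy;
        double t = vx * -sb + vy * cb;          // distance along central ray
        if (t <= 0) continue;
        double u = sad * (vx * cb + vy * sb) / t;
        double di = (u - o0) / ds;
        int d0 = (int)std::floor(di);
        if (d0 < 0 || d0 + 1 >= nd) continue;
        double f = di - d0;
        double val = (1.0 - f) * fsino(v, d0) + f * fsino(v, d0 + 1);
        double w = sad / t;
        rec(r, c) += w * w * val;
      }
    }
  }
  return rec;
}
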