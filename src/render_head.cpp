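#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Procedural head-proxy renderer.
//
// The head is a textured ellipsoid with Gaussian surface features (eye
// sockets, nose ridge, mouth) shaded by a fixed directional light plus an
// ambient term. The texture is a sum of 3-D sinusoids evaluated in the
// head-local frame, so it moves rigidly with the head and carries smooth
// intensity gradients that encode sub-pixel pose changes. Rays are cast
// per (super-sampled) pixel through a pinhole camera.
//
// Arguments:
//   Rh, th      : head pose, p_world = Rh * p_local + th   (3x3, 3)
//   Rc, tc      : camera extrinsic, p_cam = Rc * p_world + tc
//   fx,fy,cx,cy : intrinsics (px); Wpx,Hpx output size; ss supersampling
//   axes        : ellipsoid half axes (mm)
//   tex         : K x 5 matrix (kx, ky, kz, phase, amplitude)
//   spots       : M x 5 matrix (x, y, z, radius, depth)  depth>0 darkens
//   light       : 3-vector directional light (world frame, unit)
//   ambient, diffuse, base : shading parameters (base in grey levels)
//   background  : background grey level
// [[Rcpp::export(name = ".render_head_cpp")]]
NumericMatrix render_head_cpp(const NumericMatrix& Rh, const NumericVector& th,
                              const NumericMatrix& Rc, const NumericVector& tc,
                              double fx, double fy, double cx, double cy,
                              int Wpx, int Hpx, int ss,
                              const NumericVector& axes,
                              const NumericMatrix& tex,
                              const NumericMatrix& spots,
                              const NumericVector& light,
                              double ambient, double diffuse, double base,
                              double background) {
  NumericMatrix out(Hpx, Wpx);
  const double a2 = axes[0] * axes[0], b2 = axes[1] * axes[1],
               c2 = axes[2] * axes[2];
  // camera centre in world frame: -Rc^T tc ; then to head-local frame
  double Cw[3];
  for (int i = 0; i < 3; ++i)
    Cw[i] = -(Rc(0, i) * tc[0] + Rc(1, i) * tc[1] + Rc(2, i) * tc[2]);
  double Ol[3];
  for (int i = 0; i < 3; ++i)
    Ol[i] = Rh(0, i) * (Cw[0] - th[0]) + Rh(1, i) * (Cw[1] - th[1]) +
            Rh(2, i) * (Cw[2] - th[2]);
  // combined rotation taking camera-frame directions to head-local frame:
  // d_local = Rh^T * Rc^T * d_cam
  // A = Rc^T (world<-cam), B = Rh^T (local<-world), M = B*A
  double M[3][3], A[3][3], B[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) { A[i][j] = Rc(j, i); B[i][j] = Rh(j, i); }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += B[i][k] * A[k][j];
      M[i][j] = s;
    }
  const int K = tex.nrow(), Msp = spots.nrow();
  const double inv_ss = 1.0 / (ss * ss);
  // copy small parameter matrices into flat arrays (fast inner loops)
  std::vector<double> tx_(5 * K), sp_(5 * Msp), Rh_(9), li_(3);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < 5; ++j) tx_[5 * k + j] = tex(k, j);
  for (int m = 0; m < Msp; ++m)
    for (int j = 0; j < 5; ++j) sp_[5 * m + j] = spots(m, j);
  for (int i = 0; i < 3; ++i) {
    li_[i] = light[i];
    for (int j = 0; j < 3; ++j) Rh_[3 * i + j] = Rh(i, j);
  }
  for (int px = 0; px < Wpx; ++px) {
    for (int py = 0; py < Hpx; ++py) {
      double acc = 0;
      for (int sx = 0; sx < ss; ++sx) {
        for (int sy = 0; sy < ss; ++sy) {
          double u = px + (sx + 0.5) / ss;
          double v = py + (sy + 0.5) / ss;
          double dc[3] = { (u - cx) / fx, (v - cy) / fy, 1.0 };
          double d[3];
          for (int i = 0; i < 3; ++i)
            d[i] = M[i][0] * dc[0] + M[i][1] * dc[1] + M[i][2] * dc[2];
          // ray-ellipsoid intersection in scaled coordinates
          double qa = d[0] * d[0] / a2 + d[1] * d[1] / b2 + d[2] * d[2] / c2;
          double qb = 2 * (Ol[0] * d[0] / a2 + Ol[1] * d[1] / b2 +
                           Ol[2] * d[2] / c2);
          double qc = Ol[0] * Ol[0] / a2 + Ol[1] * Ol[1] / b2 +
                      Ol[2] * Ol[2] / c2 - 1.0;
          double disc = qb * qb - 4 * qa * qc;
          if (disc <= 0) { acc += background; continue; }
          double t = (-qb - std::sqrt(disc)) / (2 * qa);
          if (t <= 0) { acc += background; continue; }
          double p[3] = { Ol[0] + t * d[0], Ol[1] + t * d[1],
                          Ol[2] + t * d[2] };
          // outward normal in local frame
          double nl[3] = { p[0] / a2, p[1] / b2, p[2] / c2 };
          double nn = std::sqrt(nl[0] * nl[0] + nl[1] * nl[1] + nl[2] * nl[2]);
          nl[0] /= nn; nl[1] /= nn; nl[2] /= nn;
          // to world frame for shading: n_w = Rh * n_l
          double nw[3];
          for (int i = 0; i < 3; ++i)
            nw[i] = Rh_[3 * i] * nl[0] + Rh_[3 * i + 1] * nl[1] +
                    Rh_[3 * i + 2] * nl[2];
          double lam = nw[0] * li_[0] + nw[1] * li_[1] + nw[2] * li_[2];
          if (lam < 0) lam = 0;
          double shade = ambient + diffuse * lam;
          double texv = 1.0;
          for (int k = 0; k < K; ++k) {
            const double* tk = &tx_[5 * k];
            texv += tk[4] * std::sin(tk[0] * p[0] + tk[1] * p[1] +
                                     tk[2] * p[2] + tk[3]);
          }
          double spotv = 1.0;
          for (int m = 0; m < Msp; ++m) {
            const double* sm = &sp_[5 * m];
            double dx = p[0] - sm[0], dy = p[1] - sm[1], dz = p[2] - sm[2];
            double r2 = sm[3] * sm[3];
            spotv -= sm[4] * std::exp(-(dx * dx + dy * dy + dz * dz) /
                                      (2 * r2));
          }
          double val = base * shade * texv * spotv;
          acc += val;
        }
      }
      double val = acc * inv_ss;
      if (val < 0) val = 0;
      if (val > 255) val = 255;
      out(py, px) = val;
    }
  }
  return out;
}
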