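#include <Rcpp.h>
using namespace Rcpp;

// Catmull-Rom cubic kernel (Keys, a = -0.5), the classic "cubic
// interpolation" of image resamplers.
static inline double cubic_w(double t) {
  const double a = -0.5;
  t = std::fabs(t);
  if (t < 1.0)  return ((a + 2.0) * t - (a + 3.0)) * t * t + 1.0;
  if (t < 2.0)  return (((t - 5.0) * t + 8.0) * t - 4.0) * a;
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Resample a stack of frames onto a new grid under an affine point map.
//
// frames:  numeric array rows x cols x n (column-major, R layout)
// minv:    2x3 matrix mapping output pixel (x=col, y=row) to input
//          coordinates, 0-based pixel-centre convention
// out_dim: c(rows, cols) of the output grid
// interp:  0 = nearest, 1 = bilinear, 2 = bicubic
// Samples whose continuous source location falls outside the input
// pixel-centre hull are zero-filled.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector frames, IntegerVector in_dim,
                                  IntegerVector out_dim, NumericMatrix minv,
                                  int interp) {
  const int nr = in_dim[0], nc = in_dim[1], nf = in_dim[2];
  const int onr = out_dim[0], onc = out_dim[1];
  const double m00 = minv(0, 0), m01 = minv(0, 1), m02 = minv(0, 2);
  const double m10 = minv(1, 0), m11 = minv(1, 1), m12 = minv(1, 2);
  NumericVector out(static_cast<R_xlen_t>(onr) * onc * nf);
  const double *in = frames.begin();
  double *o = out.begin();

  for (int c = 0; c < onc; ++c) {
    for (int r = 0; r < onr; ++r) {
      const double xo = static_cast<double>(c), yo = static_cast<double>(r);
      const double xs = m00 * xo + m01 * yo + m02;
      const double ys = m10 * xo + m11 * yo + m12;
      const R_xlen_t oidx = static_cast<R_xlen_t>(r) + static_cast<R_xlen_t>(c) * onr;
      if (xs < 0.0 || xs > nc - 1.0 || ys < 0.0 || ys > nr - 1.0) {
        for (int f = 0; f < nf; ++f)
          o[oidx + static_cast<R_xlen_t>(f) * onr * onc] = 0.0;
        continue;
      }
      if (interp == 0) {
        const int xi = clampi(static_cast<int>(std::floor(xs + 0.5)), 0, nc - 1);
        const int yi = clampi(static_cast<int>(std::floor(ys + 0.5)), 0, nr - 1);
        const R_xlen_t iidx = static_cast<R_xlen_t>(yi) + static_cast<R_xlen_t>(xi) * nr;
        for (int f = 0; f < nf; ++f)
          o[oidx + static_cast<R_xlen_t>(f) * onr * onc] =
              in[iidx + static_cast<R_xlen_t>(f) * nr * nc];
      } else if (interp == 1) {
        const int x0 = clampi(static_cast<int>(std::floor(xs)), 0, nc - 1);
        const int y0 = clampi(static_cast<int>(std::floor(ys)), 0, nr - 1);
        const int x1 = clampi(x0 + 1, 0, nc - 1), y1 = clampi(y0 + 1, 0, nr - 1);
        const double fx = xs - x0, fy = ys - y0;
        for (int f = 0; f < nf; ++f) {
          const R_xlen_t base = static_cast<R_xlen_t>(f) * nr * nc;
          const double v00 = in[base + y0 + static_cast<R_xlen_t>(x0) * nr];
          const double v01 = in[base + y0 + static_cast<R_xlen_t>(x1) * nr];
          const double v10 = in[base + y1 + static_cast<R_xlen_t>(x0) * nr];
          const double v11 = in[base + y1 + static_cast<R_xlen_t>(x1) * nr];
          o[oidx + static_cast<R_xlen_t>(f) * onr * onc] =
              (1 - fy) * ((1 - fx) * v00 + fx * v01) +
              fy * ((1 - fx) * v10 + fx * v11);
        }
      } else {
        const int x0 = static_cast<int>(std::floor(xs));
        const int y0 = static_cast<int>(std::floor(ys));
        const double fx = xs - x0, fy = ys - y0;
        double wx[4], wy[4];
        int ix[4], iy[4];
        for (int k = 0; k < 4; ++k) {
          wx[k] = cubic_w(fx - (k - 1));
          wy[k] = cubic_w(fy - (k - 1));
          ix[k] = clampi(x0 + k - 1, 0, nc - 1);
          iy[k] = clampi(y0 + k - 1, 0, nr - 1);
        }
        for (int f = 0; f < nf; ++f) {
          const R_xlen_t base = static_cast<R_xlen_t>(f) * nr * nc;
          double acc = 0.0;
          for (int ky = 0; ky < 4; ++ky) {
            if (wy[ky] == 0.0) continue;
            double row = 0.0;
            const R_xlen_t rbase = base + iy[ky];
            for (int kx = 0; kx < 4; ++kx)
              row += wx[kx] * in[rbase + static_cast<R_xlen_t>(ix[kx]) * nr];
            acc += wy[ky] * row;
          }
          o[oidx + static_cast<R_xlen_t>(f) * onr * onc] = acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(onr, onc, nf);
  return out;
}
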