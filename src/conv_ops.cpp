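#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are (B*H*W) x C matrices: image i of a batch occupies rows
// [i*H*W, (i+1)*H*W), each block being the column-major vectorisation of an
// H x W plane (spatial index y + x*H). Kernel patch columns are ordered
// channel-major: j = c*k*k + kx*k + ky.

static void im2col_into(const double* xp, double* op, int H, int W, int C,
                        int k, int stride, int pad, int Ho, int Wo,
                        R_xlen_t in_rows, R_xlen_t out_rows) {
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + c * in_rows;
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        double* oc = op + ((R_xlen_t)c * k * k + kx * k + ky) * out_rows;
        for (int xo = 0; xo < Wo; ++xo) {
          const int x = xo * stride + kx - pad;
          if (x < 0 || x >= W) continue;
          const double* src = xc + (R_xlen_t)x * H;
          double* dst = oc + (R_xlen_t)xo * Ho;
          if (stride == 1) {
            int y0 = ky - pad;
            int lo = y0 < 0 ? -y0 : 0;
            int hi = Ho - 1;
            if (y0 + hi >= H) hi = H - 1 - y0;
            if (hi >= lo)
              std::copy(src + y0 + lo, src + y0 + hi + 1, dst + lo);
          } else {
            for (int yo = 0; yo < Ho; ++yo) {
              const int y = yo * stride + ky - pad;
              if (y < 0 || y >= H) continue;
              dst[yo] = src[y];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix im2col_chw(const NumericMatrix& X, int B, int H, int W, int k,
                         int stride, int pad) {
  const int C = X.ncol();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t HoWo = (R_xlen_t)Ho * Wo;
  NumericMatrix out(HoWo * B, C * k * k);
  for (int i = 0; i < B; ++i)
    im2col_into(X.begin() + i * HW, out.begin() + i * HoWo, H, W, C, k,
                stride, pad, Ho, Wo, (R_xlen_t)B * HW, (R_xlen_t)B * HoWo);
  return out;
}

// Adjoint of im2col_chw: scatter-accumulate patch gradients back.
// [[Rcpp::export]]
NumericMatrix col2im_chw(const NumericMatrix& cols, int B, int H, int W,
                         int C, int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t HoWo = (R_xlen_t)Ho * Wo;
  const R_xlen_t in_rows = HW * B;
  const R_xlen_t col_rows = HoWo * B;
  NumericMatrix out(in_rows, C);
  for (int i = 0; i < B; ++i) {
    const double* cp = cols.begin() + i * HoWo;
    double* op = out.begin() + i * HW;
    for (int c = 0; c < C; ++c) {
      double* oc = op + c * in_rows;
      for (int kx = 0; kx < k; ++kx) {
        for (int ky = 0; ky < k; ++ky) {
          const double* cc = cp + ((R_xlen_t)c * k * k + kx * k + ky) * col_rows;
          for (int xo = 0; xo < Wo; ++xo) {
            const int x = xo * stride + kx - pad;
            if (x < 0 || x >= W) continue;
            double* dst = oc + (R_xlen_t)x * H;
            const double* src = cc + (R_xlen_t)xo * Ho;
            if (stride == 1) {
              int y0 = ky - pad;
              int lo = y0 < 0 ? -y0 : 0;
              int hi = Ho - 1;
              if (y0 + hi >= H) hi = H - 1 - y0;
              for (int yo = lo; yo <= hi; ++yo) dst[y0 + yo] += src[yo];
            } else {
              for (int yo = 0; yo < Ho; ++yo) {
                const int y = yo * stride + ky - pad;
                if (y < 0 || y >= H) continue;
                dst[y] += src[yo];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling, stride 2; H and W must be even. idx holds the 1-based
// row index of the argmax in X for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd(const NumericMatrix& X, int B, int H, int W) {
  const int C = X.ncol();
  const int Ho = H / 2, Wo = W / 2;
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t HoWo = (R_xlen_t)Ho * Wo;
  NumericMatrix out(HoWo * B, C);
  IntegerMatrix idx(HoWo * B, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.begin() + c * HW * B;
    double* oc = out.begin() + c * HoWo * B;
    int* ic = idx.begin() + c * HoWo * B;
    for (int i = 0; i < B; ++i) {
      const R_xlen_t xoff = i * HW;
      const R_xlen_t ooff = i * HoWo;
      for (int xo = 0; xo < Wo; ++xo) {
        for (int yo = 0; yo < Ho; ++yo) {
          double best = R_NegInf;
          R_xlen_t besti = -1;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy) {
              const R_xlen_t p = xoff + (2 * yo + dy) + (R_xlen_t)(2 * xo + dx) * H;
              if (xc[p] > best) { best = xc[p]; besti = p; }
            }
          oc[ooff + yo + (R_xlen_t)xo * Ho] = best;
          ic[ooff + yo + (R_xlen_t)xo * Ho] = (int)(besti + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxpool2_bwd(const NumericMatrix& dY, const IntegerMatrix& idx,
                           R_xlen_t in_rows) {
  const int C = dY.ncol();
  NumericMatrix dX(in_rows, C);
  for (int c = 0; c < C; ++c) {
    const double* dy = dY.begin() + (R_xlen_t)c * dY.nrow();
    const int* ic = idx.begin() + (R_xlen_t)c * idx.nrow();
    double* dx = dX.begin() + (R_xlen_t)c * in_rows;
    for (R_xlen_t i = 0; i < dY.nrow(); ++i) dx[ic[i] - 1] += dy[i];
  }
  return dX;
}

// [[Rcpp::export]]
NumericMatrix avgpool2_fwd(const NumericMatrix& X, int B, int H, int W) {
  const int C = X.ncol();
  const int Ho = H / 2, Wo = W / 2;
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t HoWo = (R_xlen_t)Ho * Wo;
  NumericMatrix out(HoWo * B, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.begin() + c * HW * B;
    double* oc = out.begin() + c * HoWo * B;
    for (int i = 0; i < B; ++i)
      for (int xo = 0; xo < Wo; ++xo)
        for (int yo = 0; yo < Ho; ++yo) {
          double s = 0;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy)
              s += xc[i * HW + (2 * yo + dy) + (R_xlen_t)(2 * xo + dx) * H];
          oc[i * HoWo + yo + (R_xlen_t)xo * Ho] = s / 4.0;
        }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix avgpool2_bwd(const NumericMatrix& dY, int B, int H, int W) {
  // H, W are the input (fine) dims
  const int C = dY.ncol();
  const int Ho = H / 2;
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t HoWo = HW / 4;
  NumericMatrix dX(HW * B, C);
  for (int c = 0; c < C; ++c) {
    const double* dy = dY.begin() + c * HoWo * B;
    double* dx = dX.begin() + c * HW * B;
    for (int i = 0; i < B; ++i)
      for (int x = 0; x < W; ++x)
        for (int y = 0; y < H; ++y)
          dx[i * HW + y + (R_xlen_t)x * H] =
            dy[i * HoWo + (y / 2) + (R_xlen_t)(x / 2) * Ho] / 4.0;
  }
  return dX;
}

// Nearest-neighbour x2 upsampling; backward is the 2x2 sum.
// [[Rcpp::export]]
NumericMatrix upsample2_fwd(const NumericMatrix& X, int B, int H, int W) {
  const int C = X.ncol();
  const int Ho = 2 * H, Wo = 2 * W;
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t HoWo = (R_xlen_t)Ho * Wo;
  NumericMatrix out(HoWo * B, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.begin() + c * HW * B;
    double* oc = out.begin() + c * HoWo * B;
    for (int i = 0; i < B; ++i)
      for (int x = 0; x < Wo; ++x)
        for (int y = 0; y < Ho; ++y)
          oc[i * HoWo + y + (R_xlen_t)x * Ho] =
            xc[i * HW + (y / 2) + (R_xlen_t)(x / 2) * H];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix upsample2_bwd(const NumericMatrix& dY, int B, int H, int W) {
  // H, W are the input (coarse) dims
  const int C = dY.ncol();
  const int Ho = 2 * H;
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t HoWo = HW * 4;
  NumericMatrix dX(HW * B, C);
  for (int c = 0; c < C; ++c) {
    const double* dy = dY.begin() + c * HoWo * B;
    double* dx = dX.begin() + c * HW * B;
    for (int i = 0; i < B; ++i)
      for (int x = 0; x < 2 * W; ++x)
        for (int y = 0; y < Ho; ++y)
          dx[i * HW + (y / 2) + (R_xlen_t)(x / 2) * H] +=
            dy[i * HoWo + y + (R_xlen_t)x * Ho];
  }
  return dX;
}
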