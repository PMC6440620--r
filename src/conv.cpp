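#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Activations are H x W x C x N arrays, kernels kH x kW x Cin x Cout, both in
// R's column-major order. "Same" zero padding of floor(k/2) on each side, so
// out = floor((H + 2*floor(k/2) - k)/stride) + 1, i.e. ceil(H/stride) for odd
// kernels. Convolution here is cross-correlation, the CNN convention.

static inline arma::uword outdim(int in, int k, int stride) {
  int pad = k / 2;
  return (arma::uword)((in + 2 * pad - k) / stride + 1);
}

// Gather one sample into patch-matrix form: rows are output pixels
// (oy + outH*ox), cols are kernel positions (ky + kH*(kx + kW*ci)).
static void im2col(const double *x, int H, int W, int C,
                   int kH, int kW, int stride, arma::mat &M) {
  const int pH = kH / 2, pW = kW / 2;
  const int oH = (H + 2 * pH - kH) / stride + 1;
  const int oW = (W + 2 * pW - kW) / stride + 1;
  M.zeros(oH * (arma::uword)oW, (arma::uword)kH * kW * C);
  for (int ci = 0; ci < C; ++ci) {
    const double *xc = x + (size_t)ci * H * W;
    for (int kx = 0; kx < kW; ++kx) {
      for (int ky = 0; ky < kH; ++ky) {
        const arma::uword col = ky + (arma::uword)kH * (kx + (arma::uword)kW * ci);
        double *mc = M.colptr(col);
        for (int ox = 0; ox < oW; ++ox) {
          const int ix = ox * stride - pW + kx;
          if (ix < 0 || ix >= W) continue;
          const double *xcol = xc + (size_t)ix * H;
          double *mcol = mc + (size_t)ox * oH;
          for (int oy = 0; oy < oH; ++oy) {
            const int iy = oy * stride - pH + ky;
            if (iy >= 0 && iy < H) mcol[oy] = xcol[iy];
          }
        }
      }
    }
  }
}

// Scatter-add the patch-matrix gradient back onto the input image.
static void col2im(const arma::mat &G, int H, int W, int C,
                   int kH, int kW, int stride, double *dx) {
  const int pH = kH / 2, pW = kW / 2;
  const int oH = (H + 2 * pH - kH) / stride + 1;
  const int oW = (W + 2 * pW - kW) / stride + 1;
  for (int ci = 0; ci < C; ++ci) {
    double *xc = dx + (size_t)ci * H * W;
    for (int kx = 0; kx < kW; ++kx) {
      for (int ky = 0; ky < kH; ++ky) {
        const arma::uword col = ky + (arma::uword)kH * (kx + (arma::uword)kW * ci);
        const double *gc = G.colptr(col);
        for (int ox = 0; ox < oW; ++ox) {
          const int ix = ox * stride - pW + kx;
          if (ix < 0 || ix >= W) continue;
          double *xcol = xc + (size_t)ix * H;
          const double *gcol = gc + (size_t)ox * oH;
          for (int oy = 0; oy < oH; ++oy) {
            const int iy = oy * stride - pH + ky;
            if (iy >= 0 && iy < H) xcol[iy] += gcol[oy];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward_cpp")]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w, int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  if (xd.size() != 4 || wd.size() != 4)
    stop("conv2d expects 4-d input and kernel arrays");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kH = wd[0], kW = wd[1], Cin = wd[2], K = wd[3];
  if (Cin != C) stop("kernel in_channels (%d) != input channels (%d)", Cin, C);
  const arma::uword oH = outdim(H, kH, stride), oW = outdim(W, kW, stride);

  arma::mat Wm(const_cast<double *>(w.begin()), (arma::uword)kH * kW * C, K, false, true);
  NumericVector y((R_xlen_t)oH * oW * K * N);
  y.attr("dim") = IntegerVector::create((int)oH, (int)oW, K, N);

  arma::mat M;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kH, kW, stride, M);
    arma::mat Yn(y.begin() + (size_t)n * oH * oW * K, oH * oW, K, false, true);
    Yn = M * Wm;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward_cpp")]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kH = wd[0], kW = wd[1], K = wd[3];
  const arma::uword oH = yd[0], oW = yd[1];

  arma::mat Wm(const_cast<double *>(w.begin()), (arma::uword)kH * kW * C, K, false, true);
  NumericVector dx((R_xlen_t)H * W * C * N), dw(w.size());
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), (arma::uword)kH * kW * C, K, false, true);

  arma::mat M, G;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kH, kW, stride, M);
    arma::mat dYn(const_cast<double *>(dy.begin()) + (size_t)n * oH * oW * K,
                  oH * oW, K, false, true);
    dWm += M.t() * dYn;
    G = dYn * Wm.t();
    col2im(G, H, W, C, kH, kW, stride, dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}
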