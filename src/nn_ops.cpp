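// Convolution kernels for the in-package neural networks.
//
// Tensor layout follows R's column-major arrays:
//   activations: dim (H, W, C, N)   -- H fastest
//   conv weights: dim (k, k, Cin, Cout)
//   transposed-conv weights: dim (k, k, Cout, Cin)
// im2col column p = io + Ho*jo holds the receptive field of output pixel
// (io, jo) with rows ordered (kh, kw, ci), so a flattened weight array
// multiplies it directly.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col_one(const double* x, int H, int W, int C,
                       int k, int stride, int pad,
                       int Ho, int Wo, arma::mat& cols) {
  // cols: (k*k*C) x (Ho*Wo), pre-allocated
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      int p = io + Ho * jo;
      double* col = cols.colptr(p);
      int h0 = io * stride - pad;
      int w0 = jo * stride - pad;
      int r = 0;
      for (int ci = 0; ci < C; ++ci) {
        const double* plane = x + (size_t)ci * H * W;
        for (int kw = 0; kw < k; ++kw) {
          int w = w0 + kw;
          bool wok = (w >= 0 && w < W);
          for (int kh = 0; kh < k; ++kh, ++r) {
            int h = h0 + kh;
            col[r] = (wok && h >= 0 && h < H) ? plane[h + (size_t)w * H] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& cols, int H, int W, int C,
                       int k, int stride, int pad,
                       int Ho, int Wo, double* x) {
  // scatter-add columns back into the (H, W, C) image
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      int p = io + Ho * jo;
      const double* col = cols.colptr(p);
      int h0 = io * stride - pad;
      int w0 = jo * stride - pad;
      int r = 0;
      for (int ci = 0; ci < C; ++ci) {
        double* plane = x + (size_t)ci * H * W;
        for (int kw = 0; kw < k; ++kw) {
          int w = w0 + kw;
          bool wok = (w >= 0 && w < W);
          for (int kh = 0; kh < k; ++kh, ++r) {
            int h = h0 + kh;
            if (wok && h >= 0 && h < H) plane[h + (size_t)w * H] += col[r];
          }
        }
      }
    }
  }
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector dim4(const NumericVector& a) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  return d;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad) {
  IntegerVector dx = dim4(x), dw = dim4(w);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int k = dw[0], Cin = dw[2], Cout = dw[3];
  if (dw[1] != k) stop("non-square kernel");
  if (Cin != C) stop("channel mismatch in conv2d");
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("input smaller than kernel support");

  arma::mat Wm(const_cast<double*>(&w[0]), (size_t)k * k * Cin, Cout, false, true);
  NumericVector y = alloc4(Ho, Wo, Cout, N);
  arma::mat cols((size_t)k * k * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col_one(&x[0] + (size_t)n * H * W * C, H, W, C, k, stride, pad, Ho, Wo, cols);
    arma::mat Y = cols.t() * Wm; // (Ho*Wo) x Cout
    double* yp = &y[0] + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      double bc = b[co];
      const double* src = Y.colptr(co);
      double* dst = yp + (size_t)co * Ho * Wo;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) dst[i] = src[i] + bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
               int stride, int pad) {
  IntegerVector dx = dim4(x), dw = dim4(w), dgy = dim4(gy);
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int k = dw[0], Cin = dw[2], Cout = dw[3];
  int Ho = dgy[0], Wo = dgy[1];

  arma::mat Wm(const_cast<double*>(&w[0]), (size_t)k * k * Cin, Cout, false, true);
  NumericVector gx = alloc4(H, W, C, N);
  arma::mat gW((size_t)k * k * Cin, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::mat cols((size_t)k * k * Cin, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    im2col_one(&x[0] + (size_t)n * H * W * C, H, W, C, k, stride, pad, Ho, Wo, cols);
    arma::mat gY((size_t)Ho * Wo, Cout);
    const double* gp = &gy[0] + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      std::copy(gp + (size_t)co * Ho * Wo, gp + (size_t)(co + 1) * Ho * Wo,
                gY.colptr(co));
      gb(co) += arma::accu(gY.col(co));
    }
    gW += cols * gY;
    arma::mat gcols = Wm * gY.t(); // (k*k*Cin) x (Ho*Wo)
    col2im_one(gcols, H, W, C, k, stride, pad, Ho, Wo,
               &gx[0] + (size_t)n * H * W * C);
  }
  NumericVector gWr = alloc4(k, k, Cin, Cout);
  std::copy(gW.memptr(), gW.memptr() + gW.n_elem, gWr.begin());
  return List::create(_["gx"] = gx, _["gw"] = gWr,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Transposed convolution: out side = (H - 1)*stride - 2*pad + k
// [[Rcpp::export(name = ".convt2d_fw")]]
NumericVector convt2d_fw(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector dx = dim4(x), dw = dim4(w);
  int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  int k = dw[0], Cout = dw[2];
  if (dw[3] != Cin) stop("channel mismatch in convt2d");
  int Ho = (H - 1) * stride - 2 * pad + k;
  int Wo = (W - 1) * stride - 2 * pad + k;
  if (Ho < 1 || Wo < 1) stop("degenerate transposed-conv output");

  arma::mat Wt(const_cast<double*>(&w[0]), (size_t)k * k * Cout, Cin, false, true);
  NumericVector y = alloc4(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(&x[0]) + (size_t)n * H * W * Cin,
                (size_t)H * W, Cin, false, true);
    arma::mat colsY = Wt * X.t(); // (k*k*Cout) x (H*W)
    double* yp = &y[0] + (size_t)n * Ho * Wo * Cout;
    col2im_one(colsY, Ho, Wo, Cout, k, stride, pad, H, W, yp);
    for (int co = 0; co < Cout; ++co) {
      double bc = b[co];
      double* dst = yp + (size_t)co * Ho * Wo;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) dst[i] += bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".convt2d_bw")]]
List convt2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad) {
  IntegerVector dx = dim4(x), dw = dim4(w), dgy = dim4(gy);
  int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  int k = dw[0], Cout = dw[2];
  int Ho = dgy[0], Wo = dgy[1];

  arma::mat Wt(const_cast<double*>(&w[0]), (size_t)k * k * Cout, Cin, false, true);
  NumericVector gx = alloc4(H, W, Cin, N);
  arma::mat gW((size_t)k * k * Cout, Cin, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::mat cols((size_t)k * k * Cout, (size_t)H * W);

  for (int n = 0; n < N; ++n) {
    const double* gp = &gy[0] + (size_t)n * Ho * Wo * Cout;
    im2col_one(gp, Ho, Wo, Cout, k, stride, pad, H, W, cols);
    arma::mat X(const_cast<double*>(&x[0]) + (size_t)n * H * W * Cin,
                (size_t)H * W, Cin, false, true);
    arma::mat gX = cols.t() * Wt; // (H*W) x Cin
    std::copy(gX.memptr(), gX.memptr() + gX.n_elem,
              &gx[0] + (size_t)n * H * W * Cin);
    gW += cols * X;
    for (int co = 0; co < Cout; ++co) {
      const double* g = gp + (size_t)co * Ho * Wo;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) gb(co) += g[i];
    }
  }
  NumericVector gWr = alloc4(k, k, Cout, Cin);
  std::copy(gW.memptr(), gW.memptr() + gW.n_elem, gWr.begin());
  return List::create(_["gx"] = gx, _["gw"] = gWr,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}
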