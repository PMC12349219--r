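// Dense primitives for the CNN engine: stride-1 zero-padded 2-D convolution
// (forward and backward) and 2x2 average pooling, batched over the last
// array dimension. Layout follows R column-major arrays:
//   activations (H, W, C, N), kernels (kh, kw, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int pad, arma::mat& cols) {
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        double* dst = cols.memptr() + r; // row r, stride = n_rows
        const int nr = cols.n_rows;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + j - pad;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho + i - pad;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = xc[hi + (size_t)H * wi];
            dst[(size_t)nr * (ho + (size_t)Ho * wo)] = v;
          }
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& cols, int H, int W, int C,
                       int kh, int kw, int pad, double* dx) {
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        const double* src = cols.memptr() + r;
        const int nr = cols.n_rows;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + j - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho + i - pad;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wi] +=
              src[(size_t)nr * (ho + (size_t)Ho * wo)];
          }
        }
      }
    }
  }
}

static arma::mat weight_matrix(const NumericVector& w, int kh, int kw,
                               int Cin, int Cout) {
  arma::mat Wm(Cout, (size_t)kh * kw * Cin);
  const double* wp = w.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          Wm(o, i + kh * (j + kw * c)) =
            wp[i + (size_t)kh * (j + (size_t)kw * (c + (size_t)Cin * o))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("input has %d channels but kernel expects %d", C, Cin);
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  const size_t L = (size_t)Ho * Wo;

  arma::mat Wm = weight_matrix(w, kh, kw, Cin, Cout);
  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat cols((size_t)kh * kw * Cin, L);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, pad, cols);
    arma::mat res = Wm * cols; // Cout x L
    double* op = out.begin() + (size_t)Ho * Wo * Cout * n;
    for (int o = 0; o < Cout; ++o) {
      const double bo = b[o];
      for (size_t l = 0; l < L; ++l)
        op[l + (size_t)Ho * Wo * o] = res(o, l) + bo;
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dout,
                    int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = W + 2 * pad - kw + 1;
  const size_t L = (size_t)Ho * Wo;
  const size_t K = (size_t)kh * kw * Cin;

  arma::mat Wm = weight_matrix(w, kh, kw, Cin, Cout);
  arma::mat dWm(Cout, K, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);

  arma::mat cols(K, L);
  arma::mat dom(Cout, L);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, pad, cols);
    const double* dp = dout.begin() + (size_t)Ho * Wo * Cout * n;
    for (int o = 0; o < Cout; ++o)
      for (size_t l = 0; l < L; ++l)
        dom(o, l) = dp[l + (size_t)Ho * Wo * o];
    dWm += dom * cols.t();
    db += arma::sum(dom, 1);
    arma::mat dcols = Wm.t() * dom; // K x L
    col2im_acc(dcols, H, W, C, kh, kw, pad,
               dx.begin() + (size_t)H * W * C * n);
  }

  NumericVector dwv((size_t)kh * kw * Cin * Cout);
  dwv.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  double* dwp = dwv.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          dwp[i + (size_t)kh * (j + (size_t)kw * (c + (size_t)Cin * o))] =
            dWm(o, i + kh * (j + kw * c));

  return List::create(_["dw"] = dwv, _["db"] = NumericVector(db.begin(), db.end()),
                      _["dx"] = dx);
}

// [[Rcpp::export]]
NumericVector avgpool2_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("avgpool2 requires even spatial dims, got %dx%d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* op = out.begin();
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* xi = xp + (size_t)H * W * p;
    double* oi = op + (size_t)Ho * Wo * p;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        oi[ho + (size_t)Ho * wo] = 0.25 *
          (xi[2 * ho + (size_t)H * (2 * wo)] +
           xi[2 * ho + 1 + (size_t)H * (2 * wo)] +
           xi[2 * ho + (size_t)H * (2 * wo + 1)] +
           xi[2 * ho + 1 + (size_t)H * (2 * wo + 1)]);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool2_bwd_cpp(NumericVector dout) {
  IntegerVector od = dout.attr("dim");
  const int Ho = od[0], Wo = od[1], C = od[2], N = od[3];
  const int H = 2 * Ho, W = 2 * Wo;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dp = dout.begin();
  double* xp = dx.begin();
  const size_t planes = (size_t)C * N;
  for (size_t p = 0; p < planes; ++p) {
    const double* di = dp + (size_t)Ho * Wo * p;
    double* xi = xp + (size_t)H * W * p;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = 0.25 * di[ho + (size_t)Ho * wo];
        xi[2 * ho + (size_t)H * (2 * wo)] = g;
        xi[2 * ho + 1 + (size_t)H * (2 * wo)] = g;
        xi[2 * ho + (size_t)H * (2 * wo + 1)] = g;
        xi[2 * ho + 1 + (size_t)H * (2 * wo + 1)] = g;
      }
  }
  return dx;
}
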