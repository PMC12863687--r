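// Fused training step for the 4-layer convolutional attention probe:
// forward, masked binary cross-entropy gradient, and full backward in one
// call. Mirrors the R path built from .conv3_fwd/.conv3_bwd (the two are
// asserted to agree in the test suite through the shared finite-difference
// checks of the R primitives).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// im2col on "cols-form" activations: x is (B*L*L) x C with row index
// b*L*L + j*L + i; output (B*L*L) x (9*C), offset blocks (di, dj) row-major
static arma::mat im2col_m(const arma::mat& x, int B, int L) {
  int C = x.n_cols;
  arma::mat out(x.n_rows, 9 * C, arma::fill::zeros);
  for (int di = 0; di < 3; ++di) {
    for (int dj = 0; dj < 3; ++dj) {
      int k = di * 3 + dj;
      for (int c = 0; c < C; ++c) {
        int col = k * C + c;
        for (int b = 0; b < B; ++b) {
          for (int j = 0; j < L; ++j) {
            int js = j + dj - 1;
            if (js < 0 || js >= L) continue;
            for (int i = 0; i < L; ++i) {
              int is = i + di - 1;
              if (is < 0 || is >= L) continue;
              out(b * L * L + j * L + i, col) = x(b * L * L + js * L + is, c);
            }
          }
        }
      }
    }
  }
  return out;
}

// inverse scatter-add
static arma::mat col2im_m(const arma::mat& dcols, int B, int L, int C) {
  arma::mat dx(dcols.n_rows, C, arma::fill::zeros);
  for (int di = 0; di < 3; ++di) {
    for (int dj = 0; dj < 3; ++dj) {
      int k = di * 3 + dj;
      for (int c = 0; c < C; ++c) {
        int col = k * C + c;
        for (int b = 0; b < B; ++b) {
          for (int j = 0; j < L; ++j) {
            int js = j + dj - 1;
            if (js < 0 || js >= L) continue;
            for (int i = 0; i < L; ++i) {
              int is = i + di - 1;
              if (is < 0 || is >= L) continue;
              dx(b * L * L + js * L + is, c) += dcols(b * L * L + j * L + i, col);
            }
          }
        }
      }
    }
  }
  return dx;
}

// One probe training step. x: (B, C, L, L) array; labels: B x L matrix with
// NA at positions excluded from the loss. Returns the gradient list (names
// matching the R optimizer's flat layout) plus the mean loss.
// [[Rcpp::export]]
List cpp_conv_probe_step(const NumericVector& x, int B, int C, int L,
                         const arma::mat& w1, const arma::rowvec& b1,
                         const arma::mat& w2, const arma::rowvec& b2,
                         const arma::mat& w3, const arma::rowvec& b3,
                         const arma::mat& w4, const arma::rowvec& b4,
                         const NumericMatrix& labels) {
  // array -> cols-form
  arma::mat x0(B * L * L, C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < L; ++j)
        for (int i = 0; i < L; ++i)
          x0(b * L * L + j * L + i, c) = x[b + B * (c + C * (i + L * j))];

  arma::mat cols1 = im2col_m(x0, B, L);
  arma::mat y1 = cols1 * w1; y1.each_row() += b1;
  arma::mat a1 = arma::clamp(y1, 0.0, arma::datum::inf);
  arma::mat cols2 = im2col_m(a1, B, L);
  arma::mat y2 = cols2 * w2; y2.each_row() += b2;
  arma::mat a2 = arma::clamp(y2, 0.0, arma::datum::inf);
  arma::mat cols3 = im2col_m(a2, B, L);
  arma::mat y3 = cols3 * w3; y3.each_row() += b3;
  arma::mat a3 = arma::clamp(y3, 0.0, arma::datum::inf);
  arma::mat cols4 = im2col_m(a3, B, L);
  arma::mat y4 = cols4 * w4; y4.each_row() += b4;   // (B*L*L) x 1

  // logits: mean over j of y4[b, i, j]; BCE gradient on labeled positions
  arma::mat dy4(B * L * L, 1, arma::fill::zeros);
  double loss = 0.0; int n_lab = 0;
  for (int b = 0; b < B; ++b) {
    int keep_b = 0;
    for (int i = 0; i < L; ++i) if (!NumericMatrix::is_na(labels(b, i))) ++keep_b;
    if (keep_b == 0) continue;
    for (int i = 0; i < L; ++i) {
      if (NumericMatrix::is_na(labels(b, i))) continue;
      double logit = 0.0;
      for (int j = 0; j < L; ++j) logit += y4(b * L * L + j * L + i, 0);
      logit /= L;
      double p = 1.0 / (1.0 + std::exp(-logit));
      double yy = labels(b, i);
      loss += -(yy * std::log(std::max(p, 1e-12)) +
                (1 - yy) * std::log(std::max(1 - p, 1e-12)));
      ++n_lab;
      double d = (p - yy) / (keep_b * B) / L;
      for (int j = 0; j < L; ++j) dy4(b * L * L + j * L + i, 0) = d;
    }
  }

  arma::mat g_w4 = cols4.t() * dy4;
  arma::rowvec g_b4 = arma::sum(dy4, 0);
  arma::mat dy3 = col2im_m(dy4 * w4.t(), B, L, w3.n_cols) % (y3 > 0);
  arma::mat g_w3 = cols3.t() * dy3;
  arma::rowvec g_b3 = arma::sum(dy3, 0);
  arma::mat dy2 = col2im_m(dy3 * w3.t(), B, L, w2.n_cols) % (y2 > 0);
  arma::mat g_w2 = cols2.t() * dy2;
  arma::rowvec g_b2 = arma::sum(dy2, 0);
  arma::mat dy1 = col2im_m(dy2 * w2.t(), B, L, w1.n_cols) % (y1 > 0);
  arma::mat g_w1 = cols1.t() * dy1;
  arma::rowvec g_b1 = arma::sum(dy1, 0);

  return List::create(
    _["c1.w"] = g_w1, _["c1.b"] = NumericVector(g_b1.begin(), g_b1.end()),
    _["c2.w"] = g_w2, _["c2.b"] = NumericVector(g_b2.begin(), g_b2.end()),
    _["c3.w"] = g_w3, _["c3.b"] = NumericVector(g_b3.begin(), g_b3.end()),
    _["c4.w"] = g_w4, _["c4.b"] = NumericVector(g_b4.begin(), g_b4.end()),
    _["loss"] = n_lab > 0 ? loss / n_lab : 0.0);
}
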