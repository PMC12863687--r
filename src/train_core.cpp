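// Training-loop primitives: a fused AdamW update over a named parameter
// list, and the batched 3x3 im2col/col2im pair used by the convolutional
// heads and probes. Semantics mirror the R reference implementations.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// One AdamW step over all parameters, updating params and the moment
// estimates IN PLACE (the R-side optimizer owns fresh copies of all three
// lists for exactly this reason). params/grads/m/v are parallel named
// lists; lrs a named numeric vector; weight decay applies only where
// decay_mask is true (matrices).
// [[Rcpp::export]]
void cpp_adam_step_inplace(List params, const List& grads, List m, List v,
                           int t, const NumericVector& lrs, double scale,
                           double b1, double b2, double eps, double wd,
                           const LogicalVector& decay_mask) {
  CharacterVector nms = grads.names();
  double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  for (int k = 0; k < nms.size(); ++k) {
    std::string nm = as<std::string>(nms[k]);
    NumericVector g = grads[nm];
    NumericVector mm = m[nm];
    NumericVector vv = v[nm];
    NumericVector pp = params[nm];
    double lr = lrs[nm] * scale;
    bool decay = decay_mask[nm];
    double* gp = g.begin();
    double* mp = mm.begin();
    double* vp = vv.begin();
    double* ppp = pp.begin();
    int n = g.size();
    for (int i = 0; i < n; ++i) {
      mp[i] = b1 * mp[i] + (1.0 - b1) * gp[i];
      vp[i] = b2 * vp[i] + (1.0 - b2) * gp[i] * gp[i];
      double upd = (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
      if (decay) upd += wd * ppp[i];
      ppp[i] -= lr * upd;
    }
  }
}

// Batched 3x3 same-padded im2col: x is an R array (B, C, L, L); output is
// (B*L*L) x (9*C), rows grouped by sample, column-major over the grid,
// column block k (offsets (di, dj) row-major in -1..1) holding the shifted
// channel maps.
// [[Rcpp::export]]
NumericMatrix cpp_im2col3b(const NumericVector& x, int B, int C, int L) {
  NumericMatrix out(B * L * L, 9 * C);
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
              // x index (b, c, is, js), column-major
              out(b * L * L + j * L + i, col) =
                x[b + B * (c + C * (is + L * js))];
            }
          }
        }
      }
    }
  }
  return out;
}

// inverse scatter-add of cpp_im2col3b for gradients
// [[Rcpp::export]]
NumericVector cpp_col2im3b(const NumericMatrix& dcols, int B, int C, int L) {
  NumericVector dx(B * C * L * L);
  dx.attr("dim") = IntegerVector::create(B, C, L, L);
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
              dx[b + B * (c + C * (is + L * js))] +=
                dcols(b * L * L + j * L + i, col);
            }
          }
        }
      }
    }
  }
  return dx;
}
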