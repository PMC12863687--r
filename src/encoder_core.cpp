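// Transformer encoder forward/backward core. Mirrors the reference R
// implementation (kept as .encoder_forward_r / .encoder_backward_r, against
// which equivalence is tested) with identical numerics: pre-RMSNorm blocks,
// rotary position encoding on queries/keys, 1/head_dim attention scaling,
// SwiGLU feed-forward, additive -1e30 key masking for padded positions.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double RMS_EPS = 1e-8;

// row-wise RMS of x; y = x * (g / r) rowwise
static arma::vec rmsnorm_fwd(const arma::mat& x, const arma::rowvec& g,
                             arma::mat& y) {
  arma::vec r = arma::sqrt(arma::mean(arma::square(x), 1) + RMS_EPS);
  y = x.each_col() / r;
  y.each_row() %= g;
  return r;
}

// backward of rmsnorm; returns dx, accumulates dg
static arma::mat rmsnorm_bwd(const arma::mat& dy, const arma::mat& x,
                             const arma::rowvec& g, const arma::vec& r,
                             arma::rowvec& dg) {
  arma::mat dyg = dy.each_row() % g;
  dg = arma::sum(dy % (x.each_col() / r), 0);
  arma::vec s = arma::sum(dyg % x, 1) / (x.n_cols * arma::pow(r, 3));
  arma::mat dx = dyg.each_col() / r;
  dx -= x.each_col() % s;
  return dx;
}

// rotary tables: cosines/sines per position (L) and column pair (d/2)
static void rope_tables(int L, int d, int dh, int H, double base,
                        arma::mat& CO, arma::mat& SI) {
  int half = dh / 2;
  CO.set_size(L, d / 2);
  SI.set_size(L, d / 2);
  for (int h = 0; h < H; ++h) {
    for (int t = 0; t < half; ++t) {
      double theta = std::pow(base, -2.0 * t / dh);
      for (int l = 0; l < L; ++l) {
        CO(l, h * half + t) = std::cos(l * theta);
        SI(l, h * half + t) = std::sin(l * theta);
      }
    }
  }
}

// apply rotation in place to m ((B*L) x d, rows (b*L + l)); sign = -1 inverts
static void rope_apply(arma::mat& m, const arma::mat& CO, const arma::mat& SI,
                       int B, int L, double sign) {
  int half_cols = m.n_cols / 2;
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < L; ++l) {
      int row = b * L + l;
      for (int p = 0; p < half_cols; ++p) {
        double c = CO(l, p), s = sign * SI(l, p);
        double mo = m(row, 2 * p), me = m(row, 2 * p + 1);
        m(row, 2 * p) = mo * c - me * s;
        m(row, 2 * p + 1) = mo * s + me * c;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_encoder_forward(const List& params, const List& config,
                         const IntegerMatrix& ids_r,
                         const LogicalMatrix& mask_r,
                         bool want_cache, bool want_attn) {
  const int B = ids_r.nrow(), L = ids_r.ncol();
  const int d = as<int>(config["width"]);
  const int H = as<int>(config["n_heads"]);
  const int dh = as<int>(config["head_dim"]);
  const int nl = as<int>(config["n_layers"]);
  const double scale = as<double>(config["attention_scale"]);
  const double rope_base = as<double>(config["rope_base"]);

  arma::mat emb = as<arma::mat>(params["emb"]);
  arma::mat x(B * L, d);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L; ++l)
      x.row(b * L + l) = emb.row(ids_r(b, l));

  arma::mat CO, SI;
  rope_tables(L, d, dh, H, rope_base, CO, SI);

  arma::mat keymask(L, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L; ++l)
      if (!mask_r(b, l)) keymask(l, b) = -1e30;

  List cache, layer_caches(nl), attns(nl);

  for (int layer = 0; layer < nl; ++layer) {
    std::string pre = "L" + std::to_string(layer + 1) + ".";
    arma::rowvec g1 = as<arma::rowvec>(params[pre + "g1"]);
    arma::mat wq = as<arma::mat>(params[pre + "wq"]);
    arma::mat wk = as<arma::mat>(params[pre + "wk"]);
    arma::mat wv = as<arma::mat>(params[pre + "wv"]);
    arma::mat wo = as<arma::mat>(params[pre + "wo"]);
    arma::rowvec g2 = as<arma::rowvec>(params[pre + "g2"]);
    arma::mat w1 = as<arma::mat>(params[pre + "w1"]);
    arma::mat w3 = as<arma::mat>(params[pre + "w3"]);
    arma::mat w2 = as<arma::mat>(params[pre + "w2"]);

    arma::mat x_in = x, a;
    arma::vec r1 = rmsnorm_fwd(x, g1, a);
    arma::mat Q = a * wq, K = a * wk, V = a * wv;
    rope_apply(Q, CO, SI, B, L, 1.0);
    rope_apply(K, CO, SI, B, L, 1.0);

    arma::mat O(B * L, d, arma::fill::zeros);
    arma::cube P_l(L, L, B * H);         // slice b*H + h
    for (int b = 0; b < B; ++b) {
      arma::span rows(b * L, (b + 1) * L - 1);
      for (int h = 0; h < H; ++h) {
        arma::span cols(h * dh, (h + 1) * dh - 1);
        arma::mat S = Q(rows, cols) * K(rows, cols).t() * scale;
        S.each_row() += keymask.col(b).t();
        arma::vec mx = arma::max(S, 1);
        S.each_col() -= mx;
        arma::mat E = arma::exp(S);
        arma::vec rs = arma::sum(E, 1);
        arma::mat P = E.each_col() / rs;
        P_l.slice(b * H + h) = P;
        O(rows, cols) = P * V(rows, cols);
      }
    }
    arma::mat x_mid = x_in + O * wo;
    arma::mat b2;
    arma::vec r2 = rmsnorm_fwd(x_mid, g2, b2);
    arma::mat U = b2 * w1, G = b2 * w3;
    arma::mat Ssw = (U / (1.0 + arma::exp(-U))) % G;
    x = x_mid + Ssw * w2;

    if (want_attn) {
      // export as R array (B, H, L, L)
      NumericVector A(B * H * L * L);
      A.attr("dim") = IntegerVector::create(B, H, L, L);
      for (int b = 0; b < B; ++b)
        for (int h = 0; h < H; ++h) {
          const arma::mat& P = P_l.slice(b * H + h);
          for (int i = 0; i < L; ++i)
            for (int j = 0; j < L; ++j)
              A[b + B * (h + H * (i + L * j))] = P(i, j);
        }
      attns[layer] = A;
    }
    if (want_cache) {
      layer_caches[layer] = List::create(
        _["x_in"] = x_in, _["a"] = a, _["r1"] = r1, _["Q"] = Q, _["K"] = K,
        _["V"] = V, _["P"] = P_l, _["O"] = O, _["x_mid"] = x_mid,
        _["b2"] = b2, _["r2"] = r2, _["U"] = U, _["G"] = G, _["Ssw"] = Ssw);
    }
  }

  arma::rowvec gf = as<arma::rowvec>(params["gf"]);
  arma::mat hidden;
  arma::vec rf = rmsnorm_fwd(x, gf, hidden);

  List out = List::create(_["hidden"] = hidden,
                          _["attentions"] = R_NilValue,
                          _["B"] = B, _["L"] = L);
  if (want_attn) out["attentions"] = attns;
  if (want_cache) {
    out["cache"] = List::create(_["layers"] = layer_caches,
                                _["x_final"] = x, _["rf"] = rf,
                                _["B"] = B, _["L"] = L);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_encoder_backward(const arma::mat& dhidden, const List& params,
                          const List& config, const List& cache,
                          const IntegerMatrix& ids_r) {
  const int B = as<int>(cache["B"]), L = as<int>(cache["L"]);
  const int d = as<int>(config["width"]);
  const int H = as<int>(config["n_heads"]);
  const int dh = as<int>(config["head_dim"]);
  const int nl = as<int>(config["n_layers"]);
  const int V = as<int>(config["vocab_size"]);
  const double scale = as<double>(config["attention_scale"]);
  const double rope_base = as<double>(config["rope_base"]);

  arma::mat CO, SI;
  rope_tables(L, d, dh, H, rope_base, CO, SI);

  List grads;
  arma::rowvec gf = as<arma::rowvec>(params["gf"]);
  arma::mat x_final = as<arma::mat>(cache["x_final"]);
  arma::vec rf = as<arma::vec>(cache["rf"]);
  arma::rowvec dgf;
  arma::mat dx = rmsnorm_bwd(dhidden, x_final, gf, rf, dgf);
  grads["gf"] = dgf;

  List layer_caches = cache["layers"];
  for (int layer = nl - 1; layer >= 0; --layer) {
    std::string pre = "L" + std::to_string(layer + 1) + ".";
    List cc = layer_caches[layer];
    arma::rowvec g1 = as<arma::rowvec>(params[pre + "g1"]);
    arma::rowvec g2 = as<arma::rowvec>(params[pre + "g2"]);
    arma::mat wq = as<arma::mat>(params[pre + "wq"]);
    arma::mat wk = as<arma::mat>(params[pre + "wk"]);
    arma::mat wv = as<arma::mat>(params[pre + "wv"]);
    arma::mat wo = as<arma::mat>(params[pre + "wo"]);
    arma::mat w1 = as<arma::mat>(params[pre + "w1"]);
    arma::mat w3 = as<arma::mat>(params[pre + "w3"]);
    arma::mat w2 = as<arma::mat>(params[pre + "w2"]);

    arma::mat Ssw = as<arma::mat>(cc["Ssw"]);
    arma::mat U = as<arma::mat>(cc["U"]);
    arma::mat G = as<arma::mat>(cc["G"]);
    arma::mat b2 = as<arma::mat>(cc["b2"]);
    arma::mat x_mid = as<arma::mat>(cc["x_mid"]);
    arma::vec r2 = as<arma::vec>(cc["r2"]);

    // ffn block
    arma::mat dSsw = dx * w2.t();
    grads[pre + "w2"] = Ssw.t() * dx;
    arma::mat sig = 1.0 / (1.0 + arma::exp(-U));
    arma::mat silu = U % sig;
    arma::mat dU = dSsw % G % (sig % (1.0 + U % (1.0 - sig)));
    arma::mat dG_ = dSsw % silu;
    grads[pre + "w1"] = b2.t() * dU;
    grads[pre + "w3"] = b2.t() * dG_;
    arma::mat db2 = dU * w1.t() + dG_ * w3.t();
    arma::rowvec dg2;
    dx += rmsnorm_bwd(db2, x_mid, g2, r2, dg2);
    grads[pre + "g2"] = dg2;

    // attention block
    arma::mat O = as<arma::mat>(cc["O"]);
    arma::mat Q = as<arma::mat>(cc["Q"]);
    arma::mat K = as<arma::mat>(cc["K"]);
    arma::mat Vv = as<arma::mat>(cc["V"]);
    arma::cube P_l = as<arma::cube>(cc["P"]);
    arma::mat dO = dx * wo.t();
    grads[pre + "wo"] = O.t() * dx;
    arma::mat dQ(B * L, d, arma::fill::zeros);
    arma::mat dK(B * L, d, arma::fill::zeros);
    arma::mat dV(B * L, d, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      arma::span rows(b * L, (b + 1) * L - 1);
      for (int h = 0; h < H; ++h) {
        arma::span cols(h * dh, (h + 1) * dh - 1);
        const arma::mat& P = P_l.slice(b * H + h);
        arma::mat dOb = dO(rows, cols);
        arma::mat dP = dOb * Vv(rows, cols).t();
        dV(rows, cols) = P.t() * dOb;
        arma::vec rw = arma::sum(dP % P, 1);
        arma::mat dS = (P % (dP.each_col() - rw)) * scale;
        dQ(rows, cols) = dS * K(rows, cols);
        dK(rows, cols) = dS.t() * Q(rows, cols);
      }
    }
    rope_apply(dQ, CO, SI, B, L, -1.0);
    rope_apply(dK, CO, SI, B, L, -1.0);
    arma::mat a = as<arma::mat>(cc["a"]);
    grads[pre + "wq"] = a.t() * dQ;
    grads[pre + "wk"] = a.t() * dK;
    grads[pre + "wv"] = a.t() * dV;
    arma::mat da = dQ * wq.t() + dK * wk.t() + dV * wv.t();
    arma::mat x_in = as<arma::mat>(cc["x_in"]);
    arma::vec r1 = as<arma::vec>(cc["r1"]);
    arma::rowvec dg1;
    dx += rmsnorm_bwd(da, x_in, g1, r1, dg1);
    grads[pre + "g1"] = dg1;
  }

  arma::mat demb(V, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L; ++l)
      demb.row(ids_r(b, l)) += dx.row(b * L + l);
  grads["emb"] = demb;
  return grads;
}
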