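// Batched multi-head attention forward/backward.
//
// Mirrors the reference R implementation in R/nn.R (mha_fwd / mha_bwd):
// rows of Xq / Xkv are grouped per sequence (b-major), kmask marks real key
// positions, causal restricts each query to keys at or before its position.
// The attention probability tensor is returned so the backward pass can
// reuse it; both paths are finite-difference-checked in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List mha_fwd_cpp(const arma::mat& Xq, const arma::mat& Xkv,
                 const arma::mat& Wq, const arma::mat& Wk,
                 const arma::mat& Wv, const arma::mat& Wo,
                 int n_heads, int B, int Lq, int Lk,
                 const arma::umat& kmask, bool causal) {
  const int d = Wq.n_cols;
  const int dk = d / n_heads;
  const double scale = 1.0 / std::sqrt((double)dk);
  arma::mat Q = Xq * Wq;
  arma::mat K = Xkv * Wk;
  arma::mat V = Xkv * Wv;
  arma::mat O(Xq.n_rows, d, arma::fill::zeros);
  arma::cube P(Lq, Lk, (size_t)B * n_heads);
  for (int b = 0; b < B; ++b) {
    const arma::span qr(b * Lq, (b + 1) * Lq - 1);
    const arma::span kr(b * Lk, (b + 1) * Lk - 1);
    for (int h = 0; h < n_heads; ++h) {
      const arma::span cols(h * dk, (h + 1) * dk - 1);
      arma::mat S = Q(qr, cols) * K(kr, cols).t() * scale;
      for (int j = 0; j < Lk; ++j) {
        if (!kmask(b, j)) S.col(j).fill(-arma::datum::inf);
      }
      if (causal) {
        for (int i = 0; i < Lq; ++i) {
          for (int j = i + 1; j < Lk; ++j) S(i, j) = -arma::datum::inf;
        }
      }
      arma::mat Pm(Lq, Lk);
      for (int i = 0; i < Lq; ++i) {
        double m = S.row(i).max();
        arma::rowvec e = arma::exp(S.row(i) - m);
        e.replace(arma::datum::nan, 0.0);
        double s = arma::accu(e);
        Pm.row(i) = e / (s > 0 ? s : 1.0);
      }
      P.slice((size_t)b * n_heads + h) = Pm;
      O(qr, cols) = Pm * V(kr, cols);
    }
  }
  arma::mat out = O * Wo;
  return List::create(_["out"] = out, _["Q"] = Q, _["K"] = K, _["V"] = V,
                      _["O"] = O, _["P"] = P);
}

// [[Rcpp::export]]
List mha_bwd_cpp(const arma::mat& dout, const arma::mat& Xq,
                 const arma::mat& Xkv, const arma::mat& Q,
                 const arma::mat& K, const arma::mat& V,
                 const arma::mat& O, const arma::cube& P,
                 const arma::mat& Wq, const arma::mat& Wk,
                 const arma::mat& Wv, const arma::mat& Wo,
                 int n_heads, int B, int Lq, int Lk) {
  const int d = Wq.n_cols;
  const int dk = d / n_heads;
  const double scale = 1.0 / std::sqrt((double)dk);
  arma::mat dO = dout * Wo.t();
  arma::mat dWo = O.t() * dout;
  arma::mat dQ(Q.n_rows, d, arma::fill::zeros);
  arma::mat dK(K.n_rows, d, arma::fill::zeros);
  arma::mat dV(V.n_rows, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const arma::span qr(b * Lq, (b + 1) * Lq - 1);
    const arma::span kr(b * Lk, (b + 1) * Lk - 1);
    for (int h = 0; h < n_heads; ++h) {
      const arma::span cols(h * dk, (h + 1) * dk - 1);
      const arma::mat& Pm = P.slice((size_t)b * n_heads + h);
      arma::mat dOb = dO(qr, cols);
      dV(kr, cols) += Pm.t() * dOb;
      arma::mat dP = dOb * V(kr, cols).t();
      arma::mat dS = Pm % (dP.each_col() - arma::sum(dP % Pm, 1));
      dS *= scale;
      dQ(qr, cols) += dS * K(kr, cols);
      dK(kr, cols) += dS.t() * Q(qr, cols);
    }
  }
  return List::create(
      _["dXq"] = arma::mat(dQ * Wq.t()),
      _["dXkv"] = arma::mat(dK * Wk.t() + dV * Wv.t()),
      _["dWq"] = arma::mat(Xq.t() * dQ), _["dWk"] = arma::mat(Xkv.t() * dK),
      _["dWv"] = arma::mat(Xkv.t() * dV), _["dWo"] = dWo);
}
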