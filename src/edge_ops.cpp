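// Hot kernels for the graph-attention layer: per-edge logits, neighborhood
// softmax, neighbor aggregation, and the reverse-mode gradients. Edges are
// passed as directed (i attends to j) index vectors sorted by i, with
// `ends_i` holding the 1-based end position of each node's segment so the
// softmax reductions are contiguous scans.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Forward pass of one attention head.
//   z      : transformed node features W h (n x F')
//   a_src  : attention weights for the attending node (length F')
//   a_dst  : attention weights for the neighbor (length F')
// Returns alpha (edge weights), pre (edge logits before LeakyReLU) and the
// aggregated output sum_j alpha_ij z_j (n x F').
// [[Rcpp::export(name = ".att_forward_cpp")]]
List att_forward_cpp(const arma::mat& z, const arma::vec& a_src,
                     const arma::vec& a_dst, const arma::ivec& ei,
                     const arma::ivec& ej, const arma::ivec& ends_i,
                     double slope) {
  const int m = ei.n_elem, n = z.n_rows, f = z.n_cols;
  arma::vec s = z * a_src;
  arma::vec t = z * a_dst;
  arma::vec pre(m), logit(m), alpha(m);
  for (int k = 0; k < m; ++k) {
    double v = s[ei[k] - 1] + t[ej[k] - 1];
    pre[k] = v;
    logit[k] = v > 0 ? v : slope * v;
  }
  int start = 0;
  for (int i = 0; i < n; ++i) {
    int end = ends_i[i];
    if (end > start) {
      double mx = logit[start];
      for (int k = start + 1; k < end; ++k)
        if (logit[k] > mx) mx = logit[k];
      double denom = 0.0;
      for (int k = start; k < end; ++k) {
        alpha[k] = std::exp(logit[k] - mx);
        denom += alpha[k];
      }
      for (int k = start; k < end; ++k) alpha[k] /= denom;
    }
    start = end;
  }
  arma::mat out(n, f, arma::fill::zeros);
  for (int k = 0; k < m; ++k)
    out.row(ei[k] - 1) += alpha[k] * z.row(ej[k] - 1);
  return List::create(_["alpha"] = alpha, _["pre"] = pre, _["out"] = out);
}

// Backward pass of one attention head. `g` is the loss gradient at the head
// output; `hin` the head input and `w` its weight matrix. Returns gradients
// for w, the stacked attention vector [a_src; a_dst] and (optionally) the
// head input.
// [[Rcpp::export(name = ".att_backward_cpp")]]
List att_backward_cpp(const arma::mat& z, const arma::vec& alpha,
                      const arma::vec& pre, const arma::mat& g,
                      const arma::ivec& ei, const arma::ivec& ej,
                      const arma::ivec& ends_i, const arma::vec& a_src,
                      const arma::vec& a_dst, double slope,
                      const arma::mat& hin, const arma::mat& w,
                      bool need_dh) {
  const int m = ei.n_elem, n = z.n_rows, f = z.n_cols;
  arma::mat dz(n, f, arma::fill::zeros);
  arma::vec dalpha(m);
  for (int k = 0; k < m; ++k) {
    const int i = ei[k] - 1, j = ej[k] - 1;
    dz.row(j) += alpha[k] * g.row(i);
    dalpha[k] = arma::dot(g.row(i), z.row(j));
  }
  // softmax jacobian per attending node, then LeakyReLU'
  arma::vec ds(n, arma::fill::zeros), dt(n, arma::fill::zeros);
  int start = 0;
  for (int i = 0; i < n; ++i) {
    int end = ends_i[i];
    double sdot = 0.0;
    for (int k = start; k < end; ++k) sdot += alpha[k] * dalpha[k];
    for (int k = start; k < end; ++k) {
      double de = alpha[k] * (dalpha[k] - sdot);
      double beta = de * (pre[k] > 0 ? 1.0 : slope);
      ds[i] += beta;
      dt[ej[k] - 1] += beta;
    }
    start = end;
  }
  dz += ds * a_src.t() + dt * a_dst.t();
  arma::mat dw = hin.t() * dz;
  arma::vec da = arma::join_cols(z.t() * ds, z.t() * dt);
  if (need_dh) {
    arma::mat dh = dz * w.t();
    return List::create(_["dW"] = dw, _["da"] = da, _["dH"] = dh);
  }
  return List::create(_["dW"] = dw, _["da"] = da);
}
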