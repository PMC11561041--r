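// Edge-indexed inner loops of the package: synchronous damped sum-product
// message passing on the pairwise Markov network, and the per-edge
// attention primitives of the graph attention classifier. Indices arrive
// 0-based from the R wrappers. Feature blocks are handled in transposed
// (feature x node) layout so per-node access is contiguous in Armadillo's
// column-major storage.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Damped synchronous LBP on a binary pairwise Markov network.
// phi: n x 2 node potentials; psi: 2 x 2 edge potential; src/dst/rev:
// directed-edge arrays (rev[e] = index of the reverse edge).
// [[Rcpp::export]]
List lbp_run_cpp(const arma::mat& phi, const arma::mat& psi,
                 const arma::uvec& src, const arma::uvec& dst,
                 const arma::uvec& rev, const int n, const double damping,
                 const double tol, const int max_iter) {
  const int ne = src.n_elem;
  // messages and per-edge constants in 2 x ne layout (contiguous pairs)
  arma::mat M(2, ne);
  M.fill(0.5);
  arma::mat logphi_src(2, ne);
  for (int e = 0; e < ne; ++e) {
    logphi_src(0, e) = std::log(phi(src[e], 0));
    logphi_src(1, e) = std::log(phi(src[e], 1));
  }
  const double ps00 = psi(0, 0), ps10 = psi(1, 0);
  const double ps01 = psi(0, 1), ps11 = psi(1, 1);
  arma::mat S(2, n), logM(2, ne), Mnew(2, ne);
  bool converged = false;
  int iter = 0;
  double delta = 0.0;
  for (iter = 1; iter <= max_iter; ++iter) {
    logM = arma::log(M);
    S.zeros();
    for (int e = 0; e < ne; ++e) {
      S(0, dst[e]) += logM(0, e);
      S(1, dst[e]) += logM(1, e);
    }
    delta = 0.0;
    for (int e = 0; e < ne; ++e) {
      const double p0 = logphi_src(0, e) + S(0, src[e]) - logM(0, rev[e]);
      const double p1 = logphi_src(1, e) + S(1, src[e]) - logM(1, rev[e]);
      const double mx = std::max(p0, p1);
      const double e0 = std::exp(p0 - mx), e1 = std::exp(p1 - mx);
      double u0 = e0 * ps00 + e1 * ps10;
      double u1 = e0 * ps01 + e1 * ps11;
      const double s = u0 + u1;
      u0 /= s;
      u1 /= s;
      const double m0 = (1 - damping) * u0 + damping * M(0, e);
      const double m1 = (1 - damping) * u1 + damping * M(1, e);
      delta = std::max(delta, std::max(std::abs(m0 - M(0, e)),
                                       std::abs(m1 - M(1, e))));
      Mnew(0, e) = m0;
      Mnew(1, e) = m1;
    }
    M = Mnew;
    if (delta < tol) {
      converged = true;
      break;
    }
  }
  // beliefs: node potential times all incoming messages, normalized
  logM = arma::log(M);
  S.zeros();
  for (int e = 0; e < ne; ++e) {
    S(0, dst[e]) += logM(0, e);
    S(1, dst[e]) += logM(1, e);
  }
  arma::mat B(n, 2);
  for (int i = 0; i < n; ++i) {
    const double b0 = std::log(phi(i, 0)) + S(0, i);
    const double b1 = std::log(phi(i, 1)) + S(1, i);
    const double mx = std::max(b0, b1);
    const double e0 = std::exp(b0 - mx), e1 = std::exp(b1 - mx);
    B(i, 0) = e0 / (e0 + e1);
    B(i, 1) = e1 / (e0 + e1);
  }
  return List::create(_["beliefs"] = B,
                      _["iterations"] = std::min(iter, max_iter),
                      _["converged"] = converged, _["delta"] = delta);
}

// One attention head forward pass given transposed projected features
// Zt = t(X W) (d x n). LeakyReLU(0.2) edge logits, softmax over incoming
// edges per destination (logits clamped to +-30), attention-weighted
// aggregation of sources. Returns Ot (d x n), pre and alpha.
// [[Rcpp::export]]
List att_forward_cpp(const arma::mat& Zt, const arma::vec& a_src,
                     const arma::vec& a_dst, const arma::uvec& src,
                     const arma::uvec& dst, const int n) {
  const int ne = src.n_elem;
  const int d = Zt.n_rows;
  const arma::vec gs = Zt.t() * a_src;
  const arma::vec gt = Zt.t() * a_dst;
  arma::vec pre(ne), ex(ne), denom(n, arma::fill::zeros);
  for (int e = 0; e < ne; ++e) {
    const double p = gs[src[e]] + gt[dst[e]];
    pre[e] = p;
    double a = p > 0 ? p : 0.2 * p;
    if (a > 30) a = 30;
    if (a < -30) a = -30;
    ex[e] = std::exp(a);
    denom[dst[e]] += ex[e];
  }
  arma::vec alpha(ne);
  arma::mat Ot(d, n, arma::fill::zeros);
  for (int e = 0; e < ne; ++e) {
    alpha[e] = ex[e] / denom[dst[e]];
    const double a = alpha[e];
    const double* z = Zt.colptr(src[e]);
    double* o = Ot.colptr(dst[e]);
    for (int j = 0; j < d; ++j) o[j] += a * z[j];
  }
  return List::create(_["Ot"] = Ot, _["pre"] = pre, _["alpha"] = alpha);
}

// Backward pass of one attention head in the same transposed layout;
// returns dZt plus the attention-vector gradients (the X/W chain is
// finished in R with BLAS).
// [[Rcpp::export]]
List att_backward_cpp(const arma::mat& dOt, const arma::mat& Zt,
                      const arma::vec& a_src, const arma::vec& a_dst,
                      const arma::uvec& src, const arma::uvec& dst,
                      const arma::vec& pre, const arma::vec& alpha,
                      const int n) {
  const int ne = src.n_elem;
  const int d = Zt.n_rows;
  arma::vec dalpha(ne);
  arma::mat dZt(d, n, arma::fill::zeros);
  for (int e = 0; e < ne; ++e) {
    const double* go = dOt.colptr(dst[e]);
    const double* z = Zt.colptr(src[e]);
    double* gz = dZt.colptr(src[e]);
    double acc = 0.0;
    const double a = alpha[e];
    for (int j = 0; j < d; ++j) {
      acc += go[j] * z[j];
      gz[j] += a * go[j];
    }
    dalpha[e] = acc;
  }
  arma::vec sgrp(n, arma::fill::zeros);
  for (int e = 0; e < ne; ++e) sgrp[dst[e]] += alpha[e] * dalpha[e];
  arma::vec dgs(n, arma::fill::zeros), dgt(n, arma::fill::zeros);
  for (int e = 0; e < ne; ++e) {
    const double de = alpha[e] * (dalpha[e] - sgrp[dst[e]]);
    const double dp = de * (pre[e] > 0 ? 1.0 : 0.2);
    dgs[src[e]] += dp;
    dgt[dst[e]] += dp;
  }
  for (int i = 0; i < n; ++i) {
    double* gz = dZt.colptr(i);
    const double s = dgs[i], t = dgt[i];
    for (int j = 0; j < d; ++j) gz[j] += s * a_src[j] + t * a_dst[j];
  }
  return List::create(_["dZt"] = dZt, _["da_src"] = arma::vec(Zt * dgs),
                      _["da_dst"] = arma::vec(Zt * dgt));
}
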