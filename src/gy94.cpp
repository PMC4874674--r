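// Felsenstein pruning for GY94 codon site-class mixtures.
// Transition probabilities via eigendecomposition of the reversible Q in
// the pi^{1/2}-symmetrised basis; per-pattern scaling guards underflow.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static mat build_q(const imat& pairclass, const vec& pi, double kappa,
                   double omega, double& rate_out) {
  const uword n = 61;
  mat Q(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    for (uword j = 0; j < n; ++j) {
      int pc = pairclass(i, j);
      if (pc == 0) continue;
      double m = 1.0;
      if (pc == 2) m = kappa;
      else if (pc == 3) m = omega;
      else if (pc == 4) m = kappa * omega;
      Q(i, j) = m * pi(j);
    }
  }
  vec rs = sum(Q, 1);
  Q.diag() = -rs;
  rate_out = dot(pi, rs);
  return Q;
}

// [[Rcpp::export]]
Rcpp::List gy94_loglik_cpp(const arma::imat& states,
                           const arma::vec& weights,
                           const arma::imat& edge,
                           const arma::vec& elen,
                           const int nnode,
                           const arma::vec& pi,
                           const arma::imat& pairclass,
                           const double kappa,
                           const arma::vec& omegas,
                           const arma::vec& cw,
                           double rho,
                           const bool per_site) {
  const uword ntaxa = states.n_rows;
  const uword npat = states.n_cols;
  const uword nedge = edge.n_rows;
  const uword K = omegas.n_elem;
  const uword ns = 61;

  // per-class rate matrices and mixture scale factor
  std::vector<mat> Qs(K);
  vec rates(K);
  for (uword k = 0; k < K; ++k) {
    double r;
    Qs[k] = build_q(pairclass, pi, kappa, omegas(k), r);
    rates(k) = r;
  }
  if (rho <= 0) rho = dot(cw, rates);
  if (!(rho > 0)) Rcpp::stop("non-positive mixture rate");

  vec sqpi = sqrt(pi);
  mat root_part;
  mat csl(npat, K);  // class-site log-likelihoods

  // tip partials (shared across classes)
  std::vector<mat> tip(ntaxa);
  for (uword t = 0; t < ntaxa; ++t) {
    mat tp(ns, npat, fill::zeros);
    for (uword j = 0; j < npat; ++j) {
      int s = states(t, j);
      if (s <= 0) tp.col(j).ones();
      else tp(s - 1, j) = 1.0;
    }
    tip[t] = tp;
  }

  const uword root = edge(nedge - 1, 0) - 1;  // last postorder edge's parent

  for (uword k = 0; k < K; ++k) {
    // symmetrised eigendecomposition
    mat S = Qs[k];
    S.each_col() %= sqpi;
    S.each_row() /= sqpi.t();
    S = 0.5 * (S + S.t());
    vec eval;
    mat evec;
    if (!eig_sym(eval, evec, S)) Rcpp::stop("eigendecomposition failed");
    mat left = evec;
    left.each_col() /= sqpi;          // D^{-1} U
    mat right = evec.t();
    right.each_row() %= sqpi.t();     // U' D

    std::vector<mat> part(nnode);
    std::vector<bool> seen(nnode, false);
    vec logscale(npat, fill::zeros);

    for (uword e = 0; e < nedge; ++e) {
      uword par = edge(e, 0) - 1;
      uword chl = edge(e, 1) - 1;
      vec ex = exp(eval * (elen(e) / rho));
      mat P = left * diagmat(ex) * right;
      P.clamp(0.0, datum::inf);
      const mat& child_part = (chl < ntaxa) ? tip[chl] : part[chl];
      mat contrib = P * child_part;
      if (!seen[par]) {
        part[par] = contrib;
        seen[par] = true;
      } else {
        part[par] %= contrib;
      }
      // rescale parent columns, accumulating per-pattern log factors
      rowvec m = max(part[par], 0);
      for (uword j = 0; j < npat; ++j) {
        double mj = m(j);
        if (mj > 0 && (mj < 1e-140 || mj > 1e140)) {
          part[par].col(j) /= mj;
          logscale(j) += std::log(mj);
        }
      }
    }
    rowvec sl = pi.t() * part[root];
    for (uword j = 0; j < npat; ++j) {
      csl(j, k) = (sl(j) > 0 ? std::log(sl(j)) : -datum::inf) + logscale(j);
    }
  }

  // mixture over classes via log-sum-exp
  vec site_ll(npat);
  vec lcw = log(cw);
  for (uword j = 0; j < npat; ++j) {
    double mx = -datum::inf;
    for (uword k = 0; k < K; ++k) {
      double v = lcw(k) + csl(j, k);
      if (v > mx) mx = v;
    }
    if (!std::isfinite(mx)) { site_ll(j) = -datum::inf; continue; }
    double s = 0;
    for (uword k = 0; k < K; ++k) s += std::exp(lcw(k) + csl(j, k) - mx);
    site_ll(j) = mx + std::log(s);
  }
  double total = dot(weights, site_ll);

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loglik") = total,
      Rcpp::Named("rho") = rho);
  if (per_site) {
    out["site_loglik"] = site_ll;
    out["class_site_loglik"] = csl;
  }
  return out;
}
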