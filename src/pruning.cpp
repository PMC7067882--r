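// Felsenstein pruning over site patterns, mixed over discrete-Gamma rate
// categories. Trees arrive as ape-style edge matrices in postorder; the
// reversible generator arrives eigendecomposed so P(t) = U exp(L t r) Uinv.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// tip_part: 4 x P x ntip cube of tip partial likelihoods (ambiguity-aware)
// edge:     E x 2 integer matrix (parent, child), 1-based ape ids, postorder
// blen:     branch length (expected substitutions/site) per edge row
// U, lam, Uinv: eigendecomposition of the normalized rate matrix Q
// pi:       stationary base frequencies
// crates:   relative rate per Gamma category (mean 1, equal probabilities)
// Returns the per-pattern log-likelihood, log mean_c L(pattern | c).
// [[Rcpp::export]]
arma::vec pruning_siteloglik_cpp(const arma::cube& tip_part,
                                 const arma::imat& edge,
                                 const arma::vec& blen,
                                 const arma::mat& U,
                                 const arma::vec& lam,
                                 const arma::mat& Uinv,
                                 const arma::vec& pi,
                                 const arma::vec& crates) {
  const uword P = tip_part.n_cols;
  const uword ntip = tip_part.n_slices;
  const uword E = edge.n_rows;
  const uword ncat = crates.n_elem;
  uword nnode = 0;
  for (uword e = 0; e < E; ++e) {
    nnode = std::max(nnode, (uword)edge(e, 0));
    nnode = std::max(nnode, (uword)edge(e, 1));
  }
  const uword root = (uword)edge(E - 1, 0);  // last parent in postorder

  mat ll(P, ncat);
  cube part(4, P, nnode);
  for (uword c = 0; c < ncat; ++c) {
    rowvec scaler(P, fill::zeros);
    for (uword i = 0; i < ntip; ++i) part.slice(i) = tip_part.slice(i);
    for (uword i = ntip; i < nnode; ++i) part.slice(i).ones();
    for (uword e = 0; e < E; ++e) {
      const uword par = (uword)edge(e, 0) - 1;
      const uword ch = (uword)edge(e, 1) - 1;
      const vec ev = exp(lam * (blen(e) * crates(c)));
      mat Pm = U * diagmat(ev) * Uinv;
      Pm.clamp(0.0, datum::inf);
      part.slice(par) %= (Pm * part.slice(ch));
      // rescale parent to dodge underflow; track per-pattern log factors
      rowvec m = max(part.slice(par), 0);
      m.clamp(std::numeric_limits<double>::min(), datum::inf);
      part.slice(par).each_row() /= m;
      scaler += log(m);
    }
    ll.col(c) = (log(pi.t() * part.slice(root - 1)) + scaler).t();
  }
  // log mean over equal-probability categories, column-wise logsumexp
  vec mx = max(ll, 1);
  vec out(P);
  for (uword i = 0; i < P; ++i) {
    double s = 0.0;
    for (uword c = 0; c < ncat; ++c) s += std::exp(ll(i, c) - mx(i));
    out(i) = mx(i) + std::log(s / ncat);
  }
  return out;
}

// Log-likelihood and its analytic gradient with respect to every branch
// length, via inside (up) and outside partials. No rescaling: intended for
// the shallow trees this package targets; callers treat non-finite returns
// as an optimizer penalty.
// Returns list(loglik, gradient[E], pattern_loglik[P]).
// [[Rcpp::export]]
Rcpp::List pruning_grad_cpp(const arma::cube& tip_part,
                            const arma::imat& edge,
                            const arma::vec& blen,
                            const arma::mat& U,
                            const arma::vec& lam,
                            const arma::mat& Uinv,
                            const arma::vec& pi,
                            const arma::vec& crates,
                            const arma::vec& weights) {
  const uword P = tip_part.n_cols;
  const uword ntip = tip_part.n_slices;
  const uword E = edge.n_rows;
  const uword ncat = crates.n_elem;
  uword nnode = 0;
  for (uword e = 0; e < E; ++e) {
    nnode = std::max(nnode, (uword)edge(e, 0));
    nnode = std::max(nnode, (uword)edge(e, 1));
  }
  const uword root = (uword)edge(E - 1, 0);

  std::vector<std::vector<uword>> kids(nnode + 1);
  for (uword e = 0; e < E; ++e) kids[(uword)edge(e, 0)].push_back(e);

  rowvec Lmix(P, fill::zeros);
  mat G(E, P, fill::zeros);
  cube up(4, P, nnode), msg(4, P, E), out(4, P, nnode);
  std::vector<mat> Pm(E), dPm(E);
  for (uword c = 0; c < ncat; ++c) {
    for (uword i = 0; i < ntip; ++i) up.slice(i) = tip_part.slice(i);
    for (uword i = ntip; i < nnode; ++i) up.slice(i).ones();
    for (uword e = 0; e < E; ++e) {
      const double t = blen(e) * crates(c);
      const vec ev = exp(lam * t);
      Pm[e] = U * diagmat(ev) * Uinv;
      dPm[e] = U * diagmat(crates(c) * lam % ev) * Uinv;  // d/d blen
      msg.slice(e) = Pm[e] * up.slice((uword)edge(e, 1) - 1);
      up.slice((uword)edge(e, 0) - 1) %= msg.slice(e);
    }
    rowvec Lc = pi.t() * up.slice(root - 1);
    Lmix += Lc / ncat;
    out.slice(root - 1) = repmat(pi, 1, P);
    for (uword ei = E; ei-- > 0;) {  // reverse postorder = preorder
      const uword par = (uword)edge(ei, 0) - 1;
      const uword ch = (uword)edge(ei, 1) - 1;
      mat op = out.slice(par);
      for (uword e2 : kids[par + 1]) {
        if (e2 != ei) op %= msg.slice(e2);
      }
      G.row(ei) += sum(op % (dPm[ei] * up.slice(ch)), 0) / ncat;
      if (ch + 1 > ntip) out.slice(ch) = Pm[ei].t() * op;
    }
  }
  rowvec logL = log(Lmix);
  double total = dot(weights, logL.t());
  vec grad(E);
  for (uword e = 0; e < E; ++e) {
    grad(e) = dot(weights, (G.row(e) / Lmix).t());
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = total,
                            Rcpp::Named("gradient") = grad,
                            Rcpp::Named("pattern_loglik") = logL.t());
}
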