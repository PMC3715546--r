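// Goldman-Yang codon model kernel: rate matrix construction, transition
// probabilities via symmetric eigendecomposition of the reversible
// generator, and Felsenstein pruning over site patterns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NSTATE = 61;

static arma::mat gy94_Q(double kappa, double omega, const arma::vec& pi,
                        const arma::imat& single, const arma::imat& ts,
                        const arma::imat& ns) {
  arma::mat Q(NSTATE, NSTATE, arma::fill::zeros);
  for (int i = 0; i < NSTATE; ++i) {
    for (int j = 0; j < NSTATE; ++j) {
      if (i == j || single(i, j) == 0) continue;
      double r = pi(j);
      if (ts(i, j)) r *= kappa;
      if (ns(i, j)) r *= omega;
      Q(i, j) = r;
    }
  }
  Q.diag() = -arma::sum(Q, 1);
  double scale = -arma::dot(pi, Q.diag());
  if (scale > 0) Q /= scale;
  return Q;
}

// Reversible Q = diag(pi)^{-1/2} B diag(pi)^{1/2} with B symmetric;
// eigendecompose B once, then P(t) = U exp(L t) Uinv for any t.
static void gy94_eig(const arma::mat& Q, const arma::vec& pi,
                     arma::mat& U, arma::mat& Uinv, arma::vec& lam) {
  arma::vec sp = arma::sqrt(arma::clamp(pi, 1e-300, arma::datum::inf));
  arma::mat B = Q;
  B.each_col() %= sp;
  B.each_row() /= sp.t();
  B = 0.5 * (B + B.t());
  arma::mat V;
  arma::eig_sym(lam, V, B);
  U = V;
  U.each_col() /= sp;
  Uinv = V;
  Uinv.each_col() %= sp;
  Uinv = Uinv.t();
}

static arma::mat ptrans(const arma::mat& U, const arma::mat& Uinv,
                        const arma::vec& lam, double t) {
  arma::mat P = U * arma::diagmat(arma::exp(lam * t)) * Uinv;
  P.clamp(0.0, 1.0);
  arma::vec rs = arma::sum(P, 1);
  P.each_col() /= rs;
  return P;
}

// [[Rcpp::export]]
List cl_transition_matrices(double kappa, double omega,
                            const arma::vec& pi, const arma::vec& t,
                            const arma::imat& single, const arma::imat& ts,
                            const arma::imat& ns) {
  arma::mat Q = gy94_Q(kappa, omega, pi, single, ts, ns);
  arma::mat U, Uinv;
  arma::vec lam;
  gy94_eig(Q, pi, U, Uinv, lam);
  List out(t.n_elem);
  for (arma::uword k = 0; k < t.n_elem; ++k)
    out[k] = ptrans(U, Uinv, lam, t(k));
  return out;
}

// [[Rcpp::export]]
arma::mat cl_rate_matrix(double kappa, double omega, const arma::vec& pi,
                         const arma::imat& single, const arma::imat& ts,
                         const arma::imat& ns) {
  return gy94_Q(kappa, omega, pi, single, ts, ns);
}

// Felsenstein pruning over compressed site patterns.
// tipPartials: cube 61 x npat x ntip; edge: postorder, 1-based ape node
// ids; edgeClass: 1-based index into omegas; nNode: internal node count.
// [[Rcpp::export]]
double cl_loglik(const arma::cube& tipPartials, const arma::vec& weights,
                 const arma::imat& edge, const arma::vec& edgeLen,
                 const arma::ivec& edgeClass, double kappa,
                 const arma::vec& omegas, const arma::vec& pi,
                 const arma::imat& single, const arma::imat& ts,
                 const arma::imat& ns, int nNode) {
  const int ntip = tipPartials.n_slices;
  const int npat = tipPartials.n_cols;
  const int ntotal = ntip + nNode;

  // eigendecomposition per omega class
  const int nclass = omegas.n_elem;
  std::vector<arma::mat> Us(nclass), Uinvs(nclass);
  std::vector<arma::vec> lams(nclass);
  for (int c = 0; c < nclass; ++c) {
    arma::mat Q = gy94_Q(kappa, omegas(c), pi, single, ts, ns);
    gy94_eig(Q, pi, Us[c], Uinvs[c], lams[c]);
  }

  arma::cube down(NSTATE, npat, ntotal, arma::fill::ones);
  for (int i = 0; i < ntip; ++i) down.slice(i) = tipPartials.slice(i);
  arma::rowvec logscale(npat, arma::fill::zeros);

  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child = edge(e, 1) - 1;
    const int c = edgeClass(e) - 1;
    arma::mat P = ptrans(Us[c], Uinvs[c], lams[c], edgeLen(e));
    arma::mat tmp = P * down.slice(child);
    arma::rowvec m = arma::max(tmp, 0);
    for (int p = 0; p < npat; ++p) {
      if (m(p) <= 0) return -std::numeric_limits<double>::infinity();
      tmp.col(p) /= m(p);
    }
    logscale += arma::log(m);
    down.slice(parent) %= tmp;
  }

  const int root = edge(edge.n_rows - 1, 0) - 1;
  double ll = 0.0;
  for (int p = 0; p < npat; ++p) {
    double site = arma::dot(pi, down.slice(root).col(p));
    if (!(site > 0)) return -std::numeric_limits<double>::infinity();
    ll += weights(p) * (std::log(site) + logscale(p));
  }
  return ll;
}
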