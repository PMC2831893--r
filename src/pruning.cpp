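// Felsenstein pruning for a reversible codon model with per-branch partition
// rate matrices. The generator of partition k is passed in pi^{1/2}-symmetrized
// form (Qsym slice k); its real eigendecomposition gives
//   P(t) = D^{-1/2} U exp(Lambda t) U' D^{1/2},  D = diag(pi).
// Doing the whole evaluation (eigendecompositions, branch P matrices, pruning
// over compressed site patterns) in one call keeps the per-iteration cost of
// the ML optimiser low.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// tip_states: ntip x npat, 0-based sense-codon indices.
// edges: nedge x 2 (parent, child), 1-based node ids, postorder
//        (every child's subtree precedes the edge to its parent).
// edge_part: 0-based partition index per edge.
// Qsym: 61 x 61 x K symmetrized generators. pi: stationary frequencies.
// root: 1-based id of the root node.
// [[Rcpp::export(name = ".cpp_prune_loglik")]]
double cpp_prune_loglik(const arma::imat& tip_states,
                        const arma::vec& weights,
                        const arma::imat& edges,
                        const arma::vec& edge_len,
                        const arma::ivec& edge_part,
                        const arma::cube& Qsym,
                        const arma::vec& pi,
                        const int root) {
  const arma::uword S = Qsym.n_rows;
  const arma::uword npat = weights.n_elem;
  const arma::uword ntip = tip_states.n_rows;
  const arma::uword nedge = edges.n_rows;
  const arma::uword K = Qsym.n_slices;

  arma::vec sqrtpi = arma::sqrt(pi);
  arma::vec isqrtpi(S);
  for (arma::uword i = 0; i < S; ++i)
    isqrtpi(i) = sqrtpi(i) > 0 ? 1.0 / sqrtpi(i) : 0.0;

  std::vector<arma::mat> U(K);
  std::vector<arma::vec> lam(K);
  for (arma::uword k = 0; k < K; ++k) {
    arma::vec ev;
    arma::mat evec;
    if (!arma::eig_sym(ev, evec, Qsym.slice(k)))
      stop("eigendecomposition of the symmetrized generator failed");
    U[k] = evec;
    lam[k] = ev;
  }

  arma::uword nnode = 0;
  for (arma::uword e = 0; e < nedge; ++e) {
    nnode = std::max(nnode, (arma::uword) edges(e, 0));
    nnode = std::max(nnode, (arma::uword) edges(e, 1));
  }
  std::vector<arma::mat> partial(nnode + 1);
  std::vector<bool> seen(nnode + 1, false);
  arma::rowvec logscale(npat, arma::fill::zeros);

  arma::mat P(S, S), A(S, S);
  for (arma::uword e = 0; e < nedge; ++e) {
    const arma::uword par = edges(e, 0);
    const arma::uword chd = edges(e, 1);
    const arma::uword k = edge_part(e);
    const double t = edge_len(e);
    // P(t) for this branch.
    arma::vec elt = arma::exp(lam[k] * t);
    A = U[k] * arma::diagmat(elt) * U[k].t();
    for (arma::uword i = 0; i < S; ++i)
      for (arma::uword j = 0; j < S; ++j) {
        double v = isqrtpi(i) * A(i, j) * sqrtpi(j);
        P(i, j) = v > 0 ? v : 0.0;
      }
    arma::mat msg(S, npat);
    if (chd <= ntip) {
      for (arma::uword p = 0; p < npat; ++p) {
        const int st = tip_states(chd - 1, p);
        if (st >= 0) {
          msg.col(p) = P.col(st);
        } else {
          msg.col(p) = arma::sum(P, 1);  // missing data: marginalise
        }
      }
    } else {
      if (!seen[chd]) stop("postorder violated: child partial not ready");
      msg = P * partial[chd];
    }
    if (!seen[par]) {
      partial[par] = msg;
      seen[par] = true;
    } else {
      partial[par] %= msg;
    }
    // Rescale to dodge underflow on long/low-rate paths.
    for (arma::uword p = 0; p < npat; ++p) {
      const double m = partial[par].col(p).max();
      if (m > 0 && (m < 1e-100 || m > 1e100)) {
        partial[par].col(p) /= m;
        logscale(p) += std::log(m);
      }
    }
  }

  if (!seen[(arma::uword) root]) stop("root has no incident edges");
  double lnL = 0.0;
  const arma::mat& rp = partial[(arma::uword) root];
  for (arma::uword p = 0; p < npat; ++p) {
    const double site = arma::dot(pi, rp.col(p));
    if (site <= 0) return -std::numeric_limits<double>::infinity();
    lnL += weights(p) * (std::log(site) + logscale(p));
  }
  return lnL;
}
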