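// Core CTMC machinery for discrete-trait likelihoods on trees.
// Edge matrices are ape-style (1-based, postorder: children before parents).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat expm_safe(const arma::mat& Q, double t) {
  if (t <= 0.0) return arma::eye(Q.n_rows, Q.n_cols);
  arma::mat P = arma::expmat(Q * t);
  // Numerical guard: clamp tiny negatives from the Pade/eigen routine.
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

// Exponentiate Q over many intervals at once: one eigendecomposition reused
// across edges, with a scaling-and-squaring fallback when Q is defective or
// the eigenbasis is ill-conditioned.
static arma::cube expm_edges(const arma::mat& Q, const arma::vec& t) {
  const int k = Q.n_rows;
  const int ne = t.n_elem;
  arma::cube P(k, k, ne);
  bool ok = false;
  arma::cx_vec eval;
  arma::cx_mat evec, evinv;
  if (arma::eig_gen(eval, evec, Q)) {
    arma::cx_mat inv_try;
    if (arma::inv(inv_try, evec)) {
      double cnd = arma::cond(evec);
      if (std::isfinite(cnd) && cnd < 1e8) {
        evinv = inv_try;
        ok = true;
      }
    }
  }
  for (int e = 0; e < ne; ++e) {
    if (t(e) <= 0.0) { P.slice(e) = arma::eye(k, k); continue; }
    if (ok) {
      arma::cx_mat D = arma::diagmat(arma::exp(eval * t(e)));
      arma::mat M = arma::real(evec * D * evinv);
      M.transform([](double x) { return x < 0.0 ? 0.0 : x; });
      P.slice(e) = M;
    } else {
      P.slice(e) = expm_safe(Q, t(e));
    }
  }
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& Q, double t) {
  return expm_safe(Q, t);
}

// Up-pass (Felsenstein pruning) with per-node scaling.
// edge: (Nedge x 2), col0 = parent id, col1 = child id (1-based, ape order,
// postorder). tipL: ntip x k partial likelihoods for tips (rows indexed by
// tip id 1..ntip). Returns list(loglik, up, logscale, msg) where up is the
// (ntip+nnode) x k matrix of scaled partials and msg the per-edge message
// sum_t P_e[s,t] L_child(t) for the downstream pass.
// [[Rcpp::export]]
List cpp_ctmc_uppass(const arma::imat& edge, const arma::vec& edge_len,
                     const arma::mat& Q, const arma::mat& tipL,
                     const arma::vec& root_prior, int n_node) {
  const int k = Q.n_rows;
  const int ntip = tipL.n_rows;
  const int ntot = ntip + n_node;
  const int nedge = edge.n_rows;

  arma::mat up(ntot, k, arma::fill::ones);
  arma::vec logscale(ntot, arma::fill::zeros);
  for (int i = 0; i < ntip; ++i) up.row(i) = tipL.row(i);

  arma::mat msg(nedge, k, arma::fill::zeros);
  arma::cube P = expm_edges(Q, edge_len);

  for (int e = 0; e < nedge; ++e) {
    int par = edge(e, 0) - 1;
    int chi = edge(e, 1) - 1;
    arma::rowvec m = up.row(chi) * P.slice(e).t(); // m(s)=sum_t P[s,t] L(t)
    msg.row(e) = m;
    up.row(par) %= m;
    logscale(par) += logscale(chi);
    double mx = up.row(par).max();
    if (mx <= 0.0) {
      // impossible data under this model
      return List::create(_["loglik"] = R_NegInf, _["up"] = up,
                          _["logscale"] = logscale, _["msg"] = msg);
    }
    if (mx < 1e-50 || mx > 1e50) {
      up.row(par) /= mx;
      logscale(par) += std::log(mx);
    }
  }
  int root = ntip; // ape root id = ntip + 1
  double lik = arma::dot(up.row(root).t(), root_prior);
  double loglik = (lik > 0.0) ? std::log(lik) + logscale(root) : R_NegInf;
  return List::create(_["loglik"] = loglik, _["up"] = up,
                      _["logscale"] = logscale, _["msg"] = msg);
}

// [[Rcpp::export]]
double cpp_ctmc_loglik(const arma::imat& edge, const arma::vec& edge_len,
                       const arma::mat& Q, const arma::mat& tipL,
                       const arma::vec& root_prior, int n_node) {
  List res = cpp_ctmc_uppass(edge, edge_len, Q, tipL, root_prior, n_node);
  return as<double>(res["loglik"]);
}

// Marginal state probabilities at every node (tips + internals) by the
// standard up/down message-passing algorithm.
// [[Rcpp::export]]
arma::mat cpp_ctmc_marginals(const arma::imat& edge, const arma::vec& edge_len,
                             const arma::mat& Q, const arma::mat& tipL,
                             const arma::vec& root_prior, int n_node) {
  const int k = Q.n_rows;
  const int ntip = tipL.n_rows;
  const int ntot = ntip + n_node;
  const int nedge = edge.n_rows;

  List upres = cpp_ctmc_uppass(edge, edge_len, Q, tipL, root_prior, n_node);
  arma::mat up = upres["up"];
  arma::mat msg = upres["msg"];

  arma::cube P = expm_edges(Q, edge_len);

  arma::mat down(ntot, k, arma::fill::zeros);
  int root = ntip;
  for (int s = 0; s < k; ++s) down(root, s) = root_prior(s);

  // Pre-order: reverse postorder visits parents before children.
  for (int e = nedge - 1; e >= 0; --e) {
    int par = edge(e, 0) - 1;
    int chi = edge(e, 1) - 1;
    // context at parent excluding this child's subtree
    arma::rowvec ctx = down.row(par);
    for (int e2 = 0; e2 < nedge; ++e2) {
      if (edge(e2, 0) - 1 == par && e2 != e) ctx %= msg.row(e2);
    }
    arma::rowvec d = ctx * P.slice(e); // d(t)=sum_s ctx(s) P[s,t]
    double mx = d.max();
    if (mx > 0) d /= mx;
    down.row(chi) = d;
  }

  arma::mat marg(ntot, k);
  for (int v = 0; v < ntot; ++v) {
    arma::rowvec m = up.row(v) % down.row(v);
    double tot = arma::accu(m);
    marg.row(v) = (tot > 0) ? m / tot : m;
  }
  return marg;
}
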