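// [[Rcpp::depends(RcppArmadillo)]]
#include "ctmc.h"

using namespace arma;

void init_prune_work(const TreeData &td, PruneWork &wk) {
  const int n_all = td.n_tip + td.n_node;
  wk.partial.set_size(td.k, n_all);
  wk.logscale.set_size(n_all);
  wk.P.set_size(td.k, td.k, td.edge.n_rows);
}

void edge_transition_probs(const mat &Q, const vec &elen, cube &P) {
  const int k = Q.n_rows;
  const uword n_edge = elen.n_elem;
  bool ok = false;

  cx_vec w;
  cx_mat V, Vi;
  if (eig_gen(w, V, Q) && inv(Vi, V)) {
    // reconstruction check guards against (near-)defective Q
    mat rec = real(V * diagmat(w) * Vi);
    double scale = 1.0 + norm(Q, "inf");
    if (norm(rec - Q, "inf") <= 1e-9 * scale) ok = true;
  }

  if (ok) {
    for (uword e = 0; e < n_edge; ++e) {
      mat Pe = real(V * diagmat(exp(w * elen[e])) * Vi);
      Pe.clamp(0.0, 1.0);
      P.slice(e) = Pe;
    }
  } else {
    for (uword e = 0; e < n_edge; ++e) {
      mat Pe = expmat(Q * elen[e]);
      Pe.clamp(0.0, 1.0);
      P.slice(e) = Pe;
    }
  }
  (void)k;
}

double prune_loglik(const TreeData &td, const mat &Q, const vec &root_prior,
                    PruneWork &wk, vec &root_post) {
  const int k = td.k;
  const int n_all = td.n_tip + td.n_node;
  const uword n_edge = td.edge.n_rows;

  edge_transition_probs(Q, td.elen, wk.P);

  wk.partial.zeros();
  wk.logscale.zeros();
  for (int i = 0; i < td.n_tip; ++i)
    wk.partial(td.tip_state[i] - 1, i) = 1.0;
  for (int i = td.n_tip; i < n_all; ++i)
    wk.partial.col(i).ones();

  for (uword e = 0; e < n_edge; ++e) {
    const int par = td.edge(e, 0) - 1;
    const int chi = td.edge(e, 1) - 1;
    vec contrib = wk.P.slice(e) * wk.partial.col(chi);
    wk.partial.col(par) %= contrib;
    wk.logscale[par] += wk.logscale[chi];
    double m = wk.partial.col(par).max();
    if (m <= 0.0) {
      root_post.set_size(k);
      root_post.fill(datum::nan);
      return -datum::inf;
    }
    wk.partial.col(par) /= m;
    wk.logscale[par] += std::log(m);
  }

  const int root = td.n_tip;  // 0-based index of node n_tip + 1
  vec w = root_prior % wk.partial.col(root);
  double tot = accu(w);
  if (tot <= 0.0) {
    root_post.set_size(k);
    root_post.fill(datum::nan);
    return -datum::inf;
  }
  root_post = w / tot;
  return std::log(tot) + wk.logscale[root];
}

static TreeData tree_from_r(const Rcpp::IntegerMatrix &edge,
                            const Rcpp::NumericVector &elen, int n_tip,
                            int n_node, const Rcpp::IntegerVector &tip_state,
                            int k) {
  TreeData td;
  td.edge = imat(edge.nrow(), 2);
  for (int i = 0; i < edge.nrow(); ++i) {
    td.edge(i, 0) = edge(i, 0);
    td.edge(i, 1) = edge(i, 1);
  }
  td.elen = Rcpp::as<vec>(elen);
  td.n_tip = n_tip;
  td.n_node = n_node;
  td.k = k;
  td.tip_state = Rcpp::as<ivec>(tip_state);
  return td;
}

// [[Rcpp::export(name = ".cpp_expm")]]
Rcpp::NumericMatrix cpp_expm(const Rcpp::NumericMatrix &Q, double t) {
  mat Qm = Rcpp::as<mat>(Q);
  mat P = expmat(Qm * t);  // scaling-and-squaring Pade approximant
  P.clamp(0.0, 1.0);
  return Rcpp::wrap(P);
}

// [[Rcpp::export(name = ".cpp_prune_loglik")]]
Rcpp::List cpp_prune_loglik(const Rcpp::IntegerMatrix &edge,
                            const Rcpp::NumericVector &elen, int n_tip,
                            int n_node, const Rcpp::IntegerVector &tip_state,
                            const Rcpp::NumericMatrix &Q,
                            const Rcpp::NumericVector &root_prior) {
  const int k = Q.nrow();
  TreeData td = tree_from_r(edge, elen, n_tip, n_node, tip_state, k);
  PruneWork wk;
  init_prune_work(td, wk);
  vec root_post;
  mat Qm = Rcpp::as<mat>(Q);
  vec rp = Rcpp::as<vec>(root_prior);
  double ll = prune_loglik(td, Qm, rp, wk, root_post);
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("root_probs") = Rcpp::wrap(root_post));
}
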