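#pragma once
#include <RcppArmadillo.h>

// Rooted tree in postorder edge form (ape convention, 1-based node ids:
// tips 1..n_tip, root n_tip+1, internal nodes n_tip+1..n_tip+n_node).
struct TreeData {
  arma::imat edge;       // n_edge x 2, (parent, child), postorder
  arma::vec  elen;       // branch lengths
  int n_tip;
  int n_node;
  int k;                 // number of character states
  arma::ivec tip_state;  // 1-based state per tip, length n_tip
};

// Workspace reused across likelihood evaluations.
struct PruneWork {
  arma::mat  partial;    // k x (n_tip + n_node)
  arma::vec  logscale;   // per-node log scaling factor
  arma::cube P;          // k x k x n_edge transition matrices
};

void init_prune_work(const TreeData &td, PruneWork &wk);

// Per-edge transition probabilities exp(Q * t_e). Uses one eigendecomposition
// of Q for all edges, falling back to scaling-and-squaring (arma::expmat)
// per edge when Q is defective or the reconstruction error is large.
void edge_transition_probs(const arma::mat &Q, const arma::vec &elen,
                           arma::cube &P);

// Felsenstein pruning. Returns log-likelihood (may be -Inf); fills root_post
// with the normalized root-state probabilities (NaN when likelihood is 0).
double prune_loglik(const TreeData &td, const arma::mat &Q,
                    const arma::vec &root_prior, PruneWork &wk,
                    arma::vec &root_post);
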