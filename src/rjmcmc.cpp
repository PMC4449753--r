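// Reversible-jump MCMC over transition-rate configurations.
//
// A configuration assigns each of the K = k(k-1) directed transitions either
// to ZERO or to one of m shared-value rate classes; class values carry a
// gamma prior whose shape/scale hyperparameters are themselves uniform on a
// bounded interval and updated by Metropolis steps.  The model-space prior is
// uniform over canonical configurations (signatures), so a likelihood-off
// chain must visit each of the Bell(K+1) structures equally often; the
// Hastings factors below are derived so that new-class values drawn from the
// current gamma prior cancel exactly (unit Jacobian).
//
// [[Rcpp::depends(RcppArmadillo)]]
#include "ctmc.h"
#include <Rmath.h>

using namespace arma;

namespace {

struct Config {
  ivec assign;  // length K; 0 = fixed to zero, 1..m = rate class
  vec values;   // length m, class values (>= 0)
  int m() const { return values.n_elem; }
  int n_nonzero() const {
    int n = 0;
    for (uword i = 0; i < assign.n_elem; ++i)
      if (assign[i] > 0) ++n;
    return n;
  }
};

// Relabel classes by order of first appearance along the fixed transition
// ordering; permutes values accordingly.  Canonical form makes signatures
// relabel-invariant.
void canonicalize(Config &cf) {
  const int m = cf.m();
  if (m == 0) return;
  ivec relab(m + 1, fill::zeros);
  vec newvals(m);
  int next = 0;
  for (uword i = 0; i < cf.assign.n_elem; ++i) {
    int c = cf.assign[i];
    if (c > 0) {
      if (relab[c] == 0) {
        ++next;
        relab[c] = next;
        newvals[next - 1] = cf.values[c - 1];
      }
      cf.assign[i] = relab[c];
    }
  }
  cf.values = newvals.head(next);
}

int count_splittable(const Config &cf) {
  const int m = cf.m();
  ivec sz(m + 1, fill::zeros);
  for (uword i = 0; i < cf.assign.n_elem; ++i)
    if (cf.assign[i] > 0) ++sz[cf.assign[i]];
  int s = 0;
  for (int c = 1; c <= m; ++c)
    if (sz[c] >= 2) ++s;
  return s;
}

// Valid structural move types: 0 zero-out, 1 un-zero, 2 merge, 3 split.
int valid_types(const Config &cf, int K, bool valid[4]) {
  const int n = cf.n_nonzero();
  valid[0] = n >= 1;
  valid[1] = n < K;
  valid[2] = cf.m() >= 2;
  valid[3] = count_splittable(cf) >= 1;
  int t = 0;
  for (int i = 0; i < 4; ++i)
    if (valid[i]) ++t;
  return t;
}

int n_valid_types(const Config &cf, int K) {
  bool v[4];
  return valid_types(cf, K, v);
}

mat build_Q(const Config &cf, int k) {
  mat Q(k, k, fill::zeros);
  int t = 0;
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j < k; ++j) {
      if (i == j) continue;
      int c = cf.assign[t];
      Q(i, j) = (c > 0) ? cf.values[c - 1] : 0.0;
      ++t;
    }
  }
  Q.diag() = -sum(Q, 1);
  return Q;
}

double values_logprior(const vec &v, double shape, double scale) {
  double s = 0.0;
  for (uword i = 0; i < v.n_elem; ++i)
    s += R::dgamma(v[i], shape, scale, 1);
  return s;
}

int runif_int(int n) {  // uniform on 0..n-1
  int r = (int)(unif_rand() * n);
  return (r >= n) ? n - 1 : r;
}

double reflect_interval(double x, double lo, double hi) {
  if (hi <= lo) return lo;
  // proposal steps are a fraction of the interval width, so this terminates
  // after at most a couple of reflections
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    else x = 2.0 * hi - x;
  }
  return x;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_run_chain")]]
Rcpp::List cpp_run_chain(
    const Rcpp::IntegerMatrix &edge, const Rcpp::NumericVector &elen,
    int n_tip, int n_node, const Rcpp::IntegerVector &tip_state, int k,
    const Rcpp::NumericVector &root_prior, const Rcpp::IntegerVector &init_assign,
    const Rcpp::NumericVector &init_values, int iterations, int burn_in,
    int sample_every, int post_thin, double ratedev0, double acc_lo,
    double acc_hi, int adapt_window, const Rcpp::NumericVector &shape_bounds,
    const Rcpp::NumericVector &scale_bounds, double p_rate_move,
    int hyper_every, bool likelihood_on) {
  const int K = k * (k - 1);

  TreeData td;
  PruneWork wk;
  vec rp = Rcpp::as<vec>(root_prior);
  if (likelihood_on) {
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
    init_prune_work(td, wk);
  }

  Config cf;
  cf.assign = Rcpp::as<ivec>(init_assign);
  cf.values = Rcpp::as<vec>(init_values);
  canonicalize(cf);

  const double sh_lo = shape_bounds[0], sh_hi = shape_bounds[1];
  const double sc_lo = scale_bounds[0], sc_hi = scale_bounds[1];
  double shape = sh_lo + unif_rand() * (sh_hi - sh_lo);
  double scale = sc_lo + unif_rand() * (sc_hi - sc_lo);

  vec root_post(k, fill::value(datum::nan));
  double ll = 0.0;
  if (likelihood_on) {
    mat Q = build_Q(cf, k);
    ll = prune_loglik(td, Q, rp, wk, root_post);
    int tries = 0;
    while (!std::isfinite(ll) && tries < 50) {
      // reinitialize: all transitions share one freshly drawn rate
      cf.assign.fill(1);
      cf.values = vec(1);
      cf.values[0] = R::rgamma(std::max(shape, 0.5), std::max(scale, 1e-8));
      Q = build_Q(cf, k);
      ll = prune_loglik(td, Q, rp, wk, root_post);
      ++tries;
    }
    if (!std::isfinite(ll))
      Rcpp::stop("could not find a finite-likelihood starting configuration");
  } else {
    root_post = rp;
  }

  double ratedev = ratedev0;

  // retained sample storage
  const int n_stage1 = (iterations - burn_in) / sample_every;
  const int n_keep = n_stage1 / post_thin;
  Rcpp::IntegerMatrix out_assign(n_keep, K);
  Rcpp::NumericMatrix out_rates(n_keep, K);
  Rcpp::NumericVector out_ll(n_keep);
  Rcpp::NumericMatrix out_root(n_keep, k);
  Rcpp::NumericMatrix out_hyper(n_keep, 2);
  Rcpp::IntegerVector out_iter(n_keep);
  int kept = 0;

  // move accounting: rate, zero-out, un-zero, merge, split, hyper
  ivec prop(6, fill::zeros), acc(6, fill::zeros);
  int win_prop = 0, win_acc = 0;

  for (int iter = 1; iter <= iterations; ++iter) {
    // the rate-update arm must be selected with the same probability in
    // every state (detailed balance); with no free classes it is a null move
    bool is_rate = unif_rand() < p_rate_move;

    if (is_rate && cf.m() == 0) {
      // null move
    } else if (is_rate) {
      ++prop[0];
      ++win_prop;
      int c = runif_int(cf.m());
      double v0 = cf.values[c];
      double v1 = std::fabs(v0 + (2.0 * unif_rand() - 1.0) * ratedev);
      double la = R::dgamma(v1, shape, scale, 1) -
                  R::dgamma(v0, shape, scale, 1);
      double ll1 = ll;
      vec root1 = root_post;
      if (likelihood_on) {
        cf.values[c] = v1;
        mat Q = build_Q(cf, k);
        ll1 = prune_loglik(td, Q, rp, wk, root1);
        cf.values[c] = v0;
        la += ll1 - ll;
      }
      if (std::log(unif_rand()) < la) {
        cf.values[c] = v1;
        ll = ll1;
        root_post = root1;
        ++acc[0];
        ++win_acc;
      }
    } else {
      bool valid[4];
      int Tx = valid_types(cf, K, valid);
      int pick = runif_int(Tx);
      int type = -1;
      for (int i = 0; i < 4; ++i) {
        if (valid[i]) {
          if (pick == 0) { type = i; break; }
          --pick;
        }
      }
      ++prop[1 + type];

      Config nf = cf;
      double log_hastings = 0.0;
      const int n = cf.n_nonzero();
      const int m = cf.m();

      if (type == 0) {  // zero-out one transition
        int pickn = runif_int(n);
        int t = -1;
        for (int i = 0; i < K; ++i)
          if (cf.assign[i] > 0 && pickn-- == 0) { t = i; break; }
        int c = cf.assign[t];
        int size_c = 0;
        for (int i = 0; i < K; ++i)
          if (cf.assign[i] == c) ++size_c;
        nf.assign[t] = 0;
        if (size_c == 1) {
          // drop the now-empty class and its value
          vec nv(m - 1);
          int j = 0;
          for (int cc = 1; cc <= m; ++cc)
            if (cc != c) nv[j++] = cf.values[cc - 1];
          for (int i = 0; i < K; ++i)
            if (nf.assign[i] > c) --nf.assign[i];
          nf.values = nv;
        }
        int m2 = nf.m();
        int Ty = n_valid_types(nf, K);
        log_hastings = std::log((double)Tx) + std::log((double)n) -
                       std::log((double)Ty) - std::log((double)(K - n + 1)) -
                       std::log((double)(m2 + 1));
      } else if (type == 1) {  // un-zero into existing or new class
        int z = K - n;
        int pickz = runif_int(z);
        int t = -1;
        for (int i = 0; i < K; ++i)
          if (cf.assign[i] == 0 && pickz-- == 0) { t = i; break; }
        int dest = runif_int(m + 1);
        if (dest < m) {
          nf.assign[t] = dest + 1;
        } else {
          nf.assign[t] = m + 1;
          vec nv(m + 1);
          if (m > 0) nv.head(m) = cf.values;
          nv[m] = R::rgamma(shape, scale);  // prior draw: unit Jacobian
          nf.values = nv;
        }
        int Ty = n_valid_types(nf, K);
        log_hastings = std::log((double)Tx) + std::log((double)z) +
                       std::log((double)(m + 1)) - std::log((double)Ty) -
                       std::log((double)(n + 1));
      } else if (type == 2) {  // merge class j into class i (keep v_i)
        int ci = runif_int(m);
        int cj = runif_int(m - 1);
        if (cj >= ci) ++cj;
        int usize = 0;
        for (int i = 0; i < K; ++i) {
          if (cf.assign[i] == cj + 1) nf.assign[i] = ci + 1;
          if (cf.assign[i] == ci + 1 || cf.assign[i] == cj + 1) ++usize;
        }
        vec nv(m - 1);
        int j = 0;
        for (int cc = 0; cc < m; ++cc)
          if (cc != cj) nv[j++] = cf.values[cc];
        for (int i = 0; i < K; ++i)
          if (nf.assign[i] > cj + 1) --nf.assign[i];
        nf.values = nv;
        int Ty = n_valid_types(nf, K);
        int Sy = count_splittable(nf);
        double nsplit = std::pow(2.0, (double)usize) - 2.0;
        log_hastings = std::log((double)Tx) + std::log((double)m) +
                       std::log((double)(m - 1)) - std::log((double)Ty) -
                       std::log((double)Sy) - std::log(nsplit);
      } else {  // split a class: peeled subset gets a fresh prior draw
        int Sx = count_splittable(cf);
        int picks = runif_int(Sx);
        int c = -1;
        ivec sz(m + 1, fill::zeros);
        for (int i = 0; i < K; ++i)
          if (cf.assign[i] > 0) ++sz[cf.assign[i]];
        for (int cc = 1; cc <= m; ++cc)
          if (sz[cc] >= 2 && picks-- == 0) { c = cc; break; }
        int s_c = sz[c];
        double nsub = std::pow(2.0, (double)s_c) - 2.0;
        int mask = 1 + runif_int((int)nsub);  // proper nonempty subset
        int bit = 0;
        for (int i = 0; i < K; ++i) {
          if (cf.assign[i] == c) {
            if (mask & (1 << bit)) nf.assign[i] = m + 1;
            ++bit;
          }
        }
        vec nv(m + 1);
        nv.head(m) = cf.values;
        nv[m] = R::rgamma(shape, scale);
        nf.values = nv;
        int Ty = n_valid_types(nf, K);
        log_hastings = std::log((double)Tx) + std::log((double)Sx) +
                       std::log(nsub) - std::log((double)Ty) -
                       std::log((double)(m + 1)) - std::log((double)m);
      }

      double la = log_hastings;
      double ll1 = ll;
      vec root1 = root_post;
      if (likelihood_on) {
        mat Q = build_Q(nf, k);
        ll1 = prune_loglik(td, Q, rp, wk, root1);
        la += ll1 - ll;
      }
      if (std::log(unif_rand()) < la) {
        cf = nf;
        canonicalize(cf);
        ll = ll1;
        root_post = root1;
        ++acc[1 + type];
      }
    }

    // interleaved Metropolis update of the gamma hyperparameters
    if (hyper_every > 0 && iter % hyper_every == 0) {
      ++prop[5];
      double sh1 = reflect_interval(
          shape + (2.0 * unif_rand() - 1.0) * 0.25 * (sh_hi - sh_lo), sh_lo,
          sh_hi);
      double sc1 = reflect_interval(
          scale + (2.0 * unif_rand() - 1.0) * 0.25 * (sc_hi - sc_lo), sc_lo,
          sc_hi);
      double la = values_logprior(cf.values, sh1, sc1) -
                  values_logprior(cf.values, shape, scale);
      if (std::log(unif_rand()) < la) {
        shape = sh1;
        scale = sc1;
        ++acc[5];
      }
    }

    // ratedev adaptation, burn-in only (keeps the retained chain Markovian)
    if (iter <= burn_in && adapt_window > 0 && iter % adapt_window == 0 &&
        win_prop > 0) {
      double r = (double)win_acc / win_prop;
      if (r > acc_hi) ratedev *= 1.5;
      else if (r < acc_lo) ratedev /= 1.5;
      win_prop = win_acc = 0;
    }

    if (iter > burn_in) {
      int s = iter - burn_in;
      if (s % sample_every == 0) {
        int j = s / sample_every;
        if (j % post_thin == 0 && kept < n_keep) {
          for (int t = 0; t < K; ++t) {
            out_assign(kept, t) = cf.assign[t];
            out_rates(kept, t) =
                cf.assign[t] > 0 ? cf.values[cf.assign[t] - 1] : 0.0;
          }
          out_ll[kept] = ll;
          for (int s2 = 0; s2 < k; ++s2) out_root(kept, s2) = root_post[s2];
          out_hyper(kept, 0) = shape;
          out_hyper(kept, 1) = scale;
          out_iter[kept] = iter;
          ++kept;
        }
      }
    }
  }

  Rcpp::CharacterVector move_names = Rcpp::CharacterVector::create(
      "rate", "zero_out", "un_zero", "merge", "split", "hyper");
  Rcpp::IntegerVector proposed(6), accepted(6);
  for (int i = 0; i < 6; ++i) {
    proposed[i] = prop[i];
    accepted[i] = acc[i];
  }
  proposed.names() = move_names;
  accepted.names() = move_names;

  return Rcpp::List::create(
      Rcpp::Named("assign") = out_assign, Rcpp::Named("rates") = out_rates,
      Rcpp::Named("loglik") = out_ll, Rcpp::Named("root_probs") = out_root,
      Rcpp::Named("hyper") = out_hyper, Rcpp::Named("iteration") = out_iter,
      Rcpp::Named("proposed") = proposed, Rcpp::Named("accepted") = accepted,
      Rcpp::Named("ratedev") = ratedev);
}
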