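# Continuous-time Markov chain machinery: transition probabilities and the
# pruning likelihood on a phylogeny.

#' Transition probability matrix over a branch
#'
#' Computes `P(t) = exp(Q t)` by scaling-and-squaring with a Pade
#' approximant, with entries clipped to `[0, 1]`.
#'
#' @param Q A rate matrix (rows summing to zero, non-negative off-diagonal).
#' @param t Branch length, `t >= 0`.
#' @return A stochastic matrix of the same dimension as `Q`.
#' @export
transition_matrix <- function(Q, t) {
  Q <- as.matrix(Q)
  if (t < 0) stop("branch length must be non-negative")
  check_rate_matrix(Q)
  P <- .cpp_expm(unname(Q), t)
  dimnames(P) <- dimnames(Q)
  P
}

check_rate_matrix <- function(Q) {
  if (nrow(Q) != ncol(Q)) stop("rate matrix must be square")
  off <- Q
  diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-8 * (1 + max(abs(Q)))))
    stop("rate matrix rows must sum to zero")
  invisible(Q)
}

#' Stationary distribution of a rate matrix
#'
#' Left null vector of `Q`, normalized to sum to one. Only meaningful for
#' irreducible matrices; for reducible ones the returned vector is one of
#' the stationary distributions.
#'
#' @param Q A rate matrix.
#' @return A probability vector.
#' @export
stationary_distribution <- function(Q) {
  Q <- as.matrix(Q)
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- stats::lsfit(A, b, intercept = FALSE)$coefficients
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

# map characters/vector to integer tip states in tree tip order
tip_state_vector <- function(tree, characters, states = PATTERN_STATES) {
  if (inherits(characters, "pattern_characters")) {
    st <- characters$state
    names(st) <- characters$taxon
  } else {
    st <- stats::setNames(as.character(characters), names(characters))
    if (is.null(names(st))) stop("tip states must be named by taxon")
  }
  miss <- setdiff(tree$tip.label, names(st))
  if (length(miss) > 0)
    stop("tips without a character state: ", paste(miss, collapse = ", "))
  st <- st[tree$tip.label]
  if (anyNA(st)) stop("missing (NA) tip states are not supported")
  idx <- match(st, states)
  if (anyNA(idx))
    stop("states outside the model alphabet: ",
         paste(unique(st[is.na(idx)]), collapse = ", "))
  as.integer(idx)
}

prepare_tree <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  list(edge = tree$edge, elen = tree$edge.length,
       n_tip = length(tree$tip.label), n_node = tree$Nnode)
}

resolve_root_prior <- function(root_prior, Q, k) {
  if (is.null(root_prior)) return(rep(1 / k, k))
  if (is.character(root_prior)) {
    root_prior <- match.arg(root_prior, c("uniform", "stationary"))
    if (root_prior == "uniform") return(rep(1 / k, k))
    return(stationary_distribution(Q))
  }
  root_prior <- as.numeric(root_prior)
  if (length(root_prior) != k || any(root_prior < 0) ||
      abs(sum(root_prior) - 1) > 1e-8)
    stop("root prior must be a length-", k, " probability vector")
  root_prior
}

#' Pruning log-likelihood of tip states under a multistate model
#'
#' Felsenstein's pruning algorithm: partial likelihoods are propagated from
#' the tips to the root with per-node rescaling, and the result is
#' `log sum_s root_prior[s] * L_root(s)`. A dataset that is impossible
#' under `Q` returns `-Inf` without error.
#'
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @param characters A `pattern_characters` data frame or a named character
#'   vector of tip states.
#' @param Q A rate matrix whose dimnames (or `states`) give the state
#'   alphabet.
#' @param root_prior `NULL` (uniform, the default), `"stationary"`, or a
#'   probability vector over states. The root treatment is a modeling
#'   choice; uniform corresponds to the equivocal-root convention.
#' @param states State alphabet; defaults to the dimnames of `Q` or the
#'   pattern states.
#' @return Log-likelihood (scalar, possibly `-Inf`).
#' @export
log_likelihood <- function(tree, characters, Q, root_prior = NULL,
                           states = NULL) {
  res <- prune_eval(tree, characters, Q, root_prior, states)
  res$loglik
}

#' Posterior root-state probabilities
#'
#' Vector proportional to `root_prior[s] * L_root(s)`, normalized to sum to
#' one; the most-recent-common-ancestor state estimate for the sampled
#' model.
#'
#' @inheritParams log_likelihood
#' @return A probability vector over states.
#' @export
root_state_probabilities <- function(tree, characters, Q, root_prior = NULL,
                                     states = NULL) {
  res <- prune_eval(tree, characters, Q, root_prior, states)
  if (!is.finite(res$loglik))
    stop("all root partial likelihoods are zero: data impossible under Q")
  p <- res$root_probs
  names(p) <- res$states
  p
}

prune_eval <- function(tree, characters, Q, root_prior, states) {
  Q <- as.matrix(Q)
  check_rate_matrix(Q)
  k <- nrow(Q)
  if (is.null(states))
    states <- if (!is.null(rownames(Q))) rownames(Q)
  else if (k == 4) PATTERN_STATES else paste0("s", seq_len(k))
  td <- prepare_tree(tree)
  tip_state <- tip_state_vector(tree, characters, states)
  rp <- resolve_root_prior(root_prior, Q, k)
  out <- .cpp_prune_loglik(td$edge, td$elen, td$n_tip, td$n_node, tip_state,
                           unname(Q), rp)
  out$states <- states
  out$root_probs <- as.numeric(out$root_probs)
  out
}
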