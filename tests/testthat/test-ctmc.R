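test_that("rate matrices are assembled from configurations", {
  cf0 <- rate_config(rep(0L, 12))
  expect_equal(build_rate_matrix(cf0), matrix(0, 4, 4,
    dimnames = list(pattern_states(), pattern_states())))

  cf2 <- rate_config(c(1L, 1L), values = 0.7, k = 2)
  Q2 <- build_rate_matrix(cf2)
  expect_equal(unname(Q2), matrix(c(-0.7, 0.7, 0.7, -0.7), 2, byrow = TRUE))

  a <- c(1, 1, 2, 2, 3, 3, 1, 2, 3, 1, 2, 3)
  cf3 <- rate_config(a, values = c(0.1, 0.2, 0.3))
  Q3 <- build_rate_matrix(cf3)
  off <- Q3[row(Q3) != col(Q3)]
  expect_setequal(unique(off), c(0.1, 0.2, 0.3))
  expect_true(all(abs(rowSums(Q3)) < 1e-12))
  expect_error(rate_config(c(1L, 1L), values = -1, k = 2), "non-negative")
})

test_that("signatures are canonical under class relabeling", {
  expect_equal(canonical_signature(rep(0L, 12)),
               paste(rep("Z", 12), collapse = "-"))
  a1 <- c(1, 1, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  a2 <- c(2, 2, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(canonical_signature(a1), canonical_signature(a2))
  cf1 <- rate_config(a1, values = c(0.5, 0.9))
  cf2 <- rate_config(a2, values = c(0.9, 0.5))
  expect_equal(canonical_signature(cf1), canonical_signature(cf2))
  expect_equal(cf1$assignment, cf2$assignment)
})

test_that("transition probabilities satisfy CTMC identities", {
  set.seed(21)
  Q <- random_rate_matrix(4)
  expect_equal(transition_matrix(Q, 0), diag(4), tolerance = 1e-12)

  # 2-state symmetric chain: closed-form stay probability
  q <- 0.8
  Q2 <- matrix(c(-q, q, q, -q), 2, byrow = TRUE)
  for (t in c(0.1, 1, 3))
    expect_equal(transition_matrix(Q2, t)[1, 1], (1 + exp(-2 * q * t)) / 2,
                 tolerance = 1e-12)

  # rows are distributions; long branches reach the stationary distribution
  for (r in 1:10) {
    Qr <- random_rate_matrix(4)
    P <- transition_matrix(Qr, runif(1, 0, 5))
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-9)
  }
  Pinf <- transition_matrix(Q, 400)
  expect_true(max(apply(Pinf, 2, function(col) diff(range(col)))) < 1e-6)
  pi_hat <- stationary_distribution(Q)
  expect_equal(unname(Pinf[1, ]), unname(pi_hat), tolerance = 1e-6)
})

test_that("scaling-and-squaring agrees with the eigendecomposition oracle", {
  set.seed(22)
  for (r in 1:25) {
    Q <- random_rate_matrix(sample(2:4, 1))
    t <- runif(1, 0, 4)
    expect_equal(transition_matrix(Q, t), oracle_transition_matrix(Q, t),
                 tolerance = 1e-9)
  }
})

test_that("pruning equals exhaustive enumeration on random instances", {
  set.seed(23)
  maxerr <- 0
  for (r in 1:100) {
    n <- sample(3:5, 1)
    tree <- ape::rtree(n)
    Q <- random_rate_matrix(4)
    sidx <- sample(1:4, n, replace = TRUE)
    st <- stats::setNames(pattern_states()[sidx], tree$tip.label)
    ora <- oracle_prune(tree, sidx, Q, rep(0.25, 4))
    ll <- log_likelihood(tree, st, Q, states = pattern_states())
    maxerr <- max(maxerr, abs(ll - ora$loglik))
    rp <- root_state_probabilities(tree, st, Q, states = pattern_states())
    maxerr <- max(maxerr, max(abs(rp - ora$root_probs)))
  }
  expect_lt(maxerr, 1e-10)
})

test_that("likelihood respects state relabeling and rate-time confounding", {
  set.seed(24)
  tree <- ape::rtree(8)
  Q <- random_rate_matrix(4)
  sidx <- sample(1:4, 8, replace = TRUE)
  st <- stats::setNames(pattern_states()[sidx], tree$tip.label)
  ll <- log_likelihood(tree, st, Q, states = pattern_states())

  perm <- sample(4)
  Qp <- Q[perm, perm]
  stp <- stats::setNames(pattern_states()[match(sidx, perm)], tree$tip.label)
  expect_equal(log_likelihood(tree, stp, Qp, states = pattern_states()), ll,
               tolerance = 1e-10)

  c_scale <- 3.7
  tree2 <- tree
  tree2$edge.length <- tree2$edge.length * c_scale
  expect_equal(log_likelihood(tree2, st, Q / c_scale,
                              states = pattern_states()), ll,
               tolerance = 1e-10)
})

test_that("degenerate inputs behave as specified", {
  tree <- ape::read.tree(text = "(A:1,B:1,C:1);")  # star tree
  st <- c(A = "regular", B = "regular", C = "regular")
  Q0 <- matrix(0, 4, 4, dimnames = list(pattern_states(), pattern_states()))
  expect_equal(log_likelihood(tree, st, Q0), log(0.25))
  rp <- root_state_probabilities(tree, st, Q0)
  expect_equal(unname(rp), c(0, 0, 1, 0))

  st2 <- c(A = "regular", B = "bimodal", C = "regular")
  expect_equal(log_likelihood(tree, st2, Q0), -Inf)
  expect_error(root_state_probabilities(tree, st2, Q0), "impossible")

  # symmetric rates and symmetric data: equivocal root (0.25 each)
  Qs <- matrix(1, 4, 4)
  diag(Qs) <- -3
  tree4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  st4 <- c(A = "uniform", B = "irregular", C = "regular", D = "bimodal")
  expect_equal(unname(root_state_probabilities(tree4, st4, Qs,
                                               states = pattern_states())),
               rep(0.25, 4), tolerance = 1e-10)

  expect_error(log_likelihood(tree, st[1:2], Q0), "without a character state")
})
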