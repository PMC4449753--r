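# helper: rebuild the rate matrix of one retained sample
sample_Q <- function(post, i) {
  k <- post$k
  Q <- matrix(0, k, k)
  t <- 1L
  for (r in seq_len(k)) for (c in seq_len(k)) {
    if (r == c) next
    Q[r, c] <- post$rates[i, t]
    t <- t + 1L
  }
  diag(Q) <- -rowSums(Q)
  Q
}

test_that("settings validate and the thinning contract holds", {
  expect_error(sampler_settings(iterations = 100, burn_in = 100), "burn_in")
  expect_error(sampler_settings(sample_every = 0), "sample_every")
  st_paper <- sampler_settings("paper")
  expect_equal(st_paper$iterations, 10050000L)
  expect_equal(st_paper$burn_in, 50000L)
  expect_equal(st_paper$sample_every, 1000L)
  expect_equal(st_paper$post_thin, 20L)

  # (105,000 - 50,000) / 1000 = 55 first-stage samples -> 2 after thin-by-20
  st <- sampler_settings(iterations = 105000, burn_in = 50000,
                         sample_every = 1000, post_thin = 20, seed = 3)
  post <- run_chain(settings = st, likelihood_on = FALSE, k = 4)
  expect_equal(nrow(post$samples), 2)
})

test_that("chains are deterministic given the seed", {
  st <- sampler_settings(iterations = 20000, burn_in = 1000,
                         sample_every = 10, post_thin = 2, seed = 99)
  a <- run_chain(settings = st, likelihood_on = FALSE, k = 4)
  b <- run_chain(settings = st, likelihood_on = FALSE, k = 4)
  expect_identical(a$samples, b$samples)
  expect_identical(a$rates, b$rates)
  c1 <- run_chain(settings = st, likelihood_on = FALSE, k = 4, chain_id = 2)
  expect_false(identical(a$samples$signature, c1$samples$signature))
})

test_that("sampled rate values stay non-negative under reflection", {
  st <- sampler_settings(iterations = 100000, burn_in = 100,
                         sample_every = 1, post_thin = 1,
                         ratedev = 5, seed = 4)
  post <- run_chain(settings = st, likelihood_on = FALSE, k = 2)
  expect_true(all(post$rates >= 0))
})

test_that("tiny rate proposals are accepted at rate ~1", {
  # with ratedev -> 0 the prior ratio -> 1, so rate moves all accept;
  # adaptation is disabled by a zero-length window
  st <- sampler_settings(iterations = 30000, burn_in = 100,
                         sample_every = 100, post_thin = 1,
                         ratedev = 1e-9, adapt_window = 0, seed = 5)
  post <- run_chain(settings = st, likelihood_on = FALSE, k = 4)
  acc <- post$acceptance[[1]]
  rate_acc <- acc$accepted[["rate"]] / acc$proposed[["rate"]]
  expect_gt(rate_acc, 0.999)
})

test_that("likelihood-off chain visits the K=2 structures uniformly", {
  st <- sampler_settings(iterations = 1000000, burn_in = 5000,
                         sample_every = 50, post_thin = 1, seed = 7)
  post <- run_chain(settings = st, likelihood_on = FALSE, k = 2)
  tab <- table(post$samples$signature)
  expect_equal(length(tab), 5)  # all five structures reached
  chi <- stats::chisq.test(tab, p = rep(0.2, 5))
  expect_gt(chi$p.value, 0.01)
})

test_that("reported log-likelihoods match fresh pruning evaluations", {
  ds <- make_dataset(generator_preset("galliformes_like", n_tips = 40))
  st <- sampler_settings(iterations = 20000, burn_in = 2000,
                         sample_every = 50, post_thin = 2, seed = 6)
  post <- run_chain(ds$tree, ds$characters, st)
  idx <- seq(1, nrow(post$samples), length.out = 10)
  for (i in unique(round(idx))) {
    ll <- log_likelihood(ds$tree, ds$characters, sample_Q(post, i),
                         states = post$states)
    expect_equal(post$samples$loglik[i], ll, tolerance = 1e-8)
    rp <- root_state_probabilities(ds$tree, ds$characters, sample_Q(post, i),
                                   states = post$states)
    expect_equal(unname(post$root_probs[i, ]), unname(rp), tolerance = 1e-8)
  }
})

test_that("adaptation lands rate-move acceptance in the target window", {
  ds <- make_dataset("galliformes_like")
  st <- sampler_settings(iterations = 40000, burn_in = 20000,
                         sample_every = 100, post_thin = 1, seed = 8)
  post <- run_chain(ds$tree, ds$characters, st)
  acc <- post$acceptance[[1]]
  rate_acc <- acc$accepted[["rate"]] / acc$proposed[["rate"]]
  # the counter includes the pre-adaptation prefix, so allow slack around
  # the [0.20, 0.40] window
  expect_gt(rate_acc, 0.15)
  expect_lt(rate_acc, 0.45)
})

test_that("structure frequencies match the exact posterior on k=2", {
  # exact reference: quadrature over the rates of each of the 5 structures
  # at fixed gamma hyperparameters
  set.seed(3)
  tree <- ape::rtree(6)
  tree$edge.length <- tree$edge.length * 2
  sts <- c("s1", "s2")
  tipst <- stats::setNames(sample(sts, 6, replace = TRUE, prob = c(0.6, 0.4)),
                           tree$tip.label)
  shape <- 2; scale <- 0.5
  lik <- function(q12, q21) {
    Q <- matrix(c(-q12, q12, q21, -q21), 2, 2, byrow = TRUE)
    exp(log_likelihood(tree, tipst, Q, states = sts))
  }
  g <- function(v) stats::dgamma(v, shape, scale = scale)
  m <- c(
    "Z-Z" = lik(0, 0),
    "Z-1" = stats::integrate(function(v) sapply(v, function(x)
      lik(0, x) * g(x)), 0, 20)$value,
    "1-Z" = stats::integrate(function(v) sapply(v, function(x)
      lik(x, 0) * g(x)), 0, 20)$value,
    "1-1" = stats::integrate(function(v) sapply(v, function(x)
      lik(x, x) * g(x)), 0, 20)$value,
    "1-2" = stats::integrate(function(a) sapply(a, function(x)
      stats::integrate(function(b) sapply(b, function(y)
        lik(x, y) * g(y)), 0, 20)$value * g(x)), 0, 20)$value)
  exact <- m / sum(m)

  st <- sampler_settings(iterations = 1200000, burn_in = 10000,
                         sample_every = 30, post_thin = 1,
                         shape_bounds = c(2, 2), scale_bounds = c(0.5, 0.5),
                         seed = 9)
  post <- run_chain(tree, tipst, st, k = 2, states = sts)
  obs <- table(factor(post$samples$signature, levels = names(exact)))
  obs <- as.numeric(obs) / nrow(post$samples)
  expect_lt(max(abs(obs - unname(exact))), 0.01)
})

test_that("multi-chain runs merge samples and posterior TSV round-trips", {
  st <- sampler_settings(iterations = 10000, burn_in = 1000,
                         sample_every = 20, post_thin = 1, n_chains = 2,
                         seed = 10)
  post <- run_chains(settings = st, likelihood_on = FALSE, k = 4)
  expect_setequal(unique(post$samples$chain), 1:2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_posterior(post, path)
  back <- read_posterior(path)
  expect_equal(back$samples$signature, post$samples$signature)
  expect_equal(back$rates, post$rates, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$assign, post$assign, ignore_attr = TRUE)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# plumevol posterior; states=uniform,irregular",
               "nonsense"), bad)
  expect_error(read_posterior(bad))
})
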