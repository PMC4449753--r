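test_that("model-space combinatorics match direct enumeration", {
  expect_equal(sapply(0:5, bell_number), c(1, 1, 2, 5, 15, 52))
  expect_equal(model_space_size(0), 1)
  for (K in 0:5)
    expect_equal(model_space_size(K), oracle_model_count(K))
  for (K in 0:12)
    expect_equal(model_space_size(K), bell_number(K + 1))
  expect_identical(model_space_size(12), 27644437)
  expect_equal(prior_probability(2), 0.2)
  expect_equal(prior_probability(12), 1 / 27644437)
})

# build a minimal posterior object by hand
fake_posterior <- function(assigns, rates = NULL, k = 4,
                           root = NULL, loglik = NULL, chain = NULL) {
  n <- nrow(assigns)
  K <- k * (k - 1)
  if (is.null(rates)) rates <- (assigns > 0) * 0.5
  if (is.null(root)) root <- matrix(1 / k, n, k)
  if (is.null(loglik)) loglik <- rep(-10, n)
  if (is.null(chain)) chain <- rep(1L, n)
  sig <- if (n > 0) apply(assigns, 1, canonical_signature) else character(0)
  structure(list(
    samples = data.frame(chain = chain, iteration = seq_len(n),
                         signature = sig, loglik = loglik,
                         shape = rep(2, n), scale = rep(0.5, n),
                         stringsAsFactors = FALSE),
    assign = assigns, rates = rates, root_probs = root, k = k,
    states = if (k == 4) pattern_states() else paste0("s", 1:k),
    transitions = transition_index(k), settings = NULL,
    likelihood_on = TRUE, acceptance = list()),
    class = "pattern_posterior")
}

test_that("model scores give posterior, prior and Bayes factor", {
  one <- matrix(rep(c(1L, rep(0L, 11)), 10), nrow = 10, byrow = TRUE)
  post <- fake_posterior(one)
  sc <- score_models(post)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$posterior, 1)
  expect_equal(sc$bf, 27644437)

  # a signature visited 3 times in a sample of 2000
  a <- matrix(0L, 2000, 12)
  a[1:3, 1] <- 1L
  sc2 <- score_models(fake_posterior(a))
  row <- sc2[sc2$frequency == 3, ]
  expect_equal(row$posterior, 0.0015)
  expect_equal(row$bf, 0.0015 * 27644437, tolerance = 1e-12)

  expect_equal(sum(sc2$posterior), 1)
  expect_error(score_models(fake_posterior(matrix(0L, 0, 12))), "empty")
})

test_that("top model set applies the inclusive threshold", {
  a <- rbind(matrix(rep(c(1L, rep(0L, 11)), 5), 5, byrow = TRUE),
             matrix(rep(c(0L, 1L, rep(0L, 10)), 2), 2, byrow = TRUE),
             matrix(0L, 1, 12))
  post <- fake_posterior(a)
  sc <- score_models(post)
  # with n = 8 every visited signature has a huge BF; emulate thresholds
  top <- top_model_set(sc, threshold = min(sc$bf))
  expect_equal(nrow(top), nrow(sc))  # inclusive at the boundary
  expect_warning(none <- top_model_set(sc, threshold = max(sc$bf) * 2),
                 "no model")
  expect_equal(nrow(none), 0)
  # log convention: 2 log BF
  top_log <- top_model_set(sc, threshold = 2 * log(min(sc$bf)),
                           convention = "log")
  expect_equal(nrow(top_log), nrow(sc))
})

test_that("marginal probabilities count zero/positive mass correctly", {
  # 10 samples; transition 1 is zero in 3 of them
  a <- matrix(1L, 10, 12)
  a[1:3, 1] <- 0L
  post <- fake_posterior(a)
  ts <- transition_summary(post, reference = "full")
  expect_equal(ts$mp_zero[1], 0.3)
  expect_equal(ts$mp_positive[1], 0.7)
  expect_equal(ts$mp_zero + ts$mp_positive, rep(1, 12))

  # over the top set the sums equal the top-set posterior mass (< 1):
  # six visits of one signature plus six distinct single-visit signatures
  a2 <- matrix(1L, 12, 12)
  for (i in 1:6) a2[6 + i, 1:i] <- 0L
  post2 <- fake_posterior(a2)
  sc2 <- score_models(post2)
  thr <- sc2$bf[sc2$frequency == 6]  # keeps only the repeated signature
  ts_top <- transition_summary(post2, reference = "top", threshold = thr)
  mass <- 6 / 12
  expect_equal(ts_top$mp_zero + ts_top$mp_positive, rep(mass, 12))

  # mean positive rate averages only over samples where positive
  r <- (a > 0) * 0.5
  r[4:10, 1] <- 0.9
  ts3 <- transition_summary(fake_posterior(a, rates = r), reference = "full")
  expect_equal(ts3$mean_rate[1], 0.9)
  expect_equal(ts3$mean_rate[2], 0.5)
})

test_that("ancestral averaging is the mean of root vectors", {
  a <- matrix(1L, 2, 12)
  rp <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  anc <- ancestral_average(fake_posterior(a, root = rp))
  expect_equal(unname(anc), c(0.5, 0.5, 0, 0))
  rp2 <- matrix(0.25, 5, 4)
  expect_equal(unname(ancestral_average(fake_posterior(matrix(1L, 5, 12),
                                                       root = rp2))),
               rep(0.25, 4))
})

test_that("DOT export colors edges by occurrence and omits zero edges", {
  a <- matrix(0L, 10, 12)
  a[, 2] <- 1L          # uniform->regular always positive
  a[1:8, 5] <- 1L       # irregular->regular mostly positive
  post <- fake_posterior(a)
  ts <- transition_summary(post, reference = "full")
  dot <- export_transition_graph(ts)
  lines <- strsplit(dot, "\n")[[1]]
  expect_true(any(grepl("uniform.*->.*regular.*color=black", lines)))
  expect_false(any(grepl("bimodal.*->.*uniform.*->", lines)))
  expect_equal(sum(grepl("->", lines)), 2)

  all_zero <- transition_summary(fake_posterior(matrix(0L, 4, 12)),
                                 reference = "full")
  dot0 <- export_transition_graph(all_zero)
  expect_false(grepl("color=black", dot0))
  p <- withr::local_tempfile(fileext = ".dot")
  export_transition_graph(ts, p)
  expect_true(file.exists(p))
})
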