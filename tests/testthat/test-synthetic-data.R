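test_that("presets encode the intended zero structures", {
  g <- generator_preset("galliformes_like")
  expect_equal(g$n_tips, 170L)
  idx <- transition_index(4)
  zeros <- idx$label[g$config$assignment == 0]
  expect_setequal(zeros, c("uniform->bimodal", "bimodal->uniform",
                           "regular->irregular"))
  a <- generator_preset("anseriformes_like")
  expect_equal(a$n_tips, 118L)
  expect_true(all(c("uniform->irregular", "regular->irregular") %in%
                    idx$label[a$config$assignment == 0]))
  f <- generator_preset("fig2_hypothesis")
  expect_setequal(idx$label[f$config$assignment == 0],
                  c("uniform->bimodal", "bimodal->uniform",
                    "irregular->regular", "regular->irregular"))
  expect_true(all(generator_preset("full_model")$config$assignment > 0))
  expect_true(all(generator_preset("null_uniform")$config$assignment == 0))
  expect_error(generator_preset("nope"), "available")
})

test_that("yule trees are reproducible and height grows like log(n)/b", {
  t1 <- simulate_yule_tree(20, 1, seed = 51)
  t2 <- simulate_yule_tree(20, 1, seed = 51)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$tip.label), 20)
  expect_equal(t1$Nnode, 19)

  set.seed(52)
  h <- function(n, b) mean(replicate(60,
    max(ape::node.depth.edgelength(simulate_yule_tree(n, b)))))
  h_small <- h(10, 1)
  h_big <- h(80, 1)
  expect_gt(h_big, h_small)
  # ratio tracks log(n) growth loosely (Monte-Carlo tolerance)
  expect_gt(h_big / h_small, log(80) / log(10) * 0.5)
  expect_lt(h_big / h_small, log(80) / log(10) * 2.0)
  # doubling the birth rate halves the height
  expect_equal(h(40, 2) / h(40, 1), 0.5, tolerance = 0.25)
})

test_that("character simulation respects the zero structure", {
  tree <- simulate_yule_tree(50, 1, seed = 53)
  chars0 <- simulate_character(tree, generator_preset("null_uniform")$config,
                               root_state = "regular", seed = 53)
  expect_true(all(chars0$state == "regular"))

  # states unreachable from the root under the structure never appear
  cfg <- rate_config_from_labels(c("uniform->irregular" = 0.5))
  ch <- simulate_character(tree, cfg, root_state = "uniform", seed = 54)
  expect_true(all(ch$state %in% c("uniform", "irregular")))
})

test_that("tip-state frequencies approach the stationary distribution", {
  tree <- ape::stree(2000, "star")
  tree$edge.length <- rep(60, 2000)  # effectively infinite branches
  cfg <- generator_preset("galliformes_like")$config
  Q <- build_rate_matrix(cfg)
  pi_exp <- stationary_distribution(Q)
  ch <- simulate_character(tree, cfg, root_state = "uniform", seed = 55,
                           sex_codes = FALSE)
  freq <- as.numeric(table(factor(ch$state, levels = pattern_states()))) / 2000
  se <- sqrt(pi_exp * (1 - pi_exp) / 2000)
  expect_true(all(abs(freq - pi_exp) < 3 * se + 1e-3))
})

test_that("single-branch transition frequencies match exp(Qt)", {
  cfg <- generator_preset("fig2_hypothesis")$config
  Q <- build_rate_matrix(cfg)
  t_len <- 1.3
  P_row <- transition_matrix(Q, t_len)[1, ]
  tree <- ape::stree(5000, "star")
  tree$edge.length <- rep(t_len, 5000)
  ch <- simulate_character(tree, cfg, root_state = "uniform", seed = 56,
                           sex_codes = FALSE)
  obs <- table(factor(ch$state, levels = pattern_states()))
  keep <- P_row > 0
  chi <- stats::chisq.test(obs[keep], p = P_row[keep] / sum(P_row[keep]))
  expect_gt(chi$p.value, 0.001)
  expect_equal(sum(obs[!keep]), 0)
})

test_that("emitted sex codes classify back to the simulated state", {
  tree <- simulate_yule_tree(150, 1, seed = 57)
  cfg <- generator_preset("galliformes_like")$config
  ch <- simulate_character(tree, cfg, root_state = "uniform", seed = 57)
  derived <- vapply(seq_len(nrow(ch)), function(i)
    classify_species(ch$male[i], ch$female[i]), character(1))
  expect_equal(derived, ch$state)
  # tabulated counts equal direct counts of simulated states
  tab <- tabulate_frequencies(ch)
  for (s in pattern_states())
    expect_equal(tab[[s]] * nrow(ch) / 100, sum(ch$state == s))
})

test_that("the bimodal sex-phenotype split follows its configuration", {
  tree <- ape::stree(4000, "star")
  tree$edge.length <- rep(1, 4000)
  cfg <- rate_config(rep(0L, 12))
  ch <- simulate_character(tree, cfg, root_state = "bimodal", seed = 58,
                           bimodal_split = c(0.51, 0.37, 0.12))
  bk <- bimodal_sex_breakdown(ch)
  expect_equal(unname(bk), c(0.51, 0.37, 0.12), tolerance = 0.05)
  expect_equal(sum(bk), 1)
})

test_that("make_dataset writes tree, characters and truth that round-trip", {
  dir <- withr::local_tempdir()
  res <- make_dataset(generator_preset("galliformes_like", n_tips = 25),
                      dir = dir, seed = 59)
  expect_true(all(file.exists(unlist(res$paths))))
  tr <- read_tree(res$paths$tree)
  ch <- read_characters(res$paths$characters)
  expect_equal(length(tr$tip.label), 25)
  expect_setequal(tr$tip.label, ch$taxon)
  truth <- read_truth(res$paths$truth)
  expect_equal(truth$config$assignment, res$truth$assignment)
  expect_equal(canonical_signature(truth$config), res$truth$signature)
})
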