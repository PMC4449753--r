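# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: transition probabilities come from an
# eigendecomposition, likelihoods from exhaustive enumeration over
# internal-node states, combinatorics from direct enumeration, and the
# Ljung-Box statistic from its defining formula.

oracle_transition_matrix <- function(Q, t) {
  ev <- eigen(Q * t)
  Re(ev$vectors %*% diag(exp(ev$values), nrow(Q)) %*% solve(ev$vectors))
}

random_rate_matrix <- function(k, max_rate = 1.5) {
  Q <- matrix(runif(k * k, 0, max_rate), k, k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# brute-force tip likelihood: sum over every assignment of states to the
# internal nodes; returns the log-likelihood and the root-state posterior
oracle_prune <- function(tree, states_idx, Q, root_prior) {
  tree <- ape::reorder.phylo(tree, "postorder")
  k <- nrow(Q)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    oracle_transition_matrix(Q, tree$edge.length[e]))
  internal <- (n_tip + 1):n_all
  grid <- as.matrix(expand.grid(rep(list(1:k), length(internal))))
  by_root <- numeric(k)
  for (g in seq_len(nrow(grid))) {
    assign <- integer(n_all)
    assign[1:n_tip] <- states_idx
    assign[internal] <- grid[g, ]
    p <- root_prior[assign[n_tip + 1]]
    for (e in seq_len(nrow(tree$edge)))
      p <- p * Ps[[e]][assign[tree$edge[e, 1]], assign[tree$edge[e, 2]]]
    by_root[assign[n_tip + 1]] <- by_root[assign[n_tip + 1]] + p
  }
  list(loglik = log(sum(by_root)), root_probs = by_root / sum(by_root))
}

# count canonical zero/rate-class configurations of K transitions by direct
# recursive enumeration (each position: zero, an existing class, or the
# next new class)
oracle_model_count <- function(K) {
  rec <- function(pos, maxclass) {
    if (pos > K) return(1)
    n <- rec(pos + 1, maxclass)                     # zero
    for (c in seq_len(maxclass)) n <- n + rec(pos + 1, maxclass)  # existing
    n + rec(pos + 1, maxclass + 1)                  # new class
  }
  # note: loop above adds rec() once per existing class
  rec(1, 0)
}

logsumexp_test <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Ljung-Box from the defining formula (no stats::Box.test, no stats::acf)
oracle_ljung_box <- function(x, lags) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  r <- vapply(seq_len(lags), function(h)
    sum(xc[1:(n - h)] * xc[(1 + h):n]) / denom, numeric(1))
  Q <- n * (n + 2) * sum(r^2 / (n - seq_len(lags)))
  list(statistic = Q, p_value = 1 - pchisq(Q, df = lags))
}

# small deterministic character table exercising every classification rule;
# state counts are (uniform 2, irregular 1, regular 4, bimodal 3)
toy_characters <- function() {
  pattern_characters(
    taxon = paste0("sp", 1:10),
    male = c("NONE", "NONE", "MOTTLE", "BAR", "SPOT", "MOTTLE;BAR",
             "SCALE", "MOTTLE", "SCALE", "BAR"),
    female = c("NONE", "NONE", "NONE", "NONE", "SCALE", "NONE",
               "MOTTLE", "MOTTLE;SPOT", "NONE", "BAR"))
}

toy_clade_map <- function() {
  data.frame(taxon = paste0("sp", 1:10),
             order = "Toyiformes",
             subfamily = rep(c("Alphinae", "Betinae"), each = 5),
             tribe = rep(c("Alphini", "Gammini", "Betini", "Deltini"),
                         c(3, 2, 3, 2)),
             stringsAsFactors = FALSE)
}
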