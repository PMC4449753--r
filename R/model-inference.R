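# Multimodel inference over the posterior sample: Bell-number model-space
# priors, Bayes factors, top model sets, marginal transition probabilities,
# and model-averaged ancestral states.

#' Bell numbers
#'
#' Number of set partitions of `n` elements, computed by the Bell-triangle
#' recurrence. Values are exact up to `n = 22` (below 2^53, the integer
#' limit of a double).
#'
#' @param n Non-negative integer (at most 22).
#' @return The Bell number `B(n)` as a numeric scalar.
#' @export
#' @examples
#' sapply(0:5, bell_number)  # 1 1 2 5 15 52
bell_number <- function(n) {
  stopifnot(n >= 0, n <= 22)
  if (n == 0) return(1)
  row <- 1
  for (i in seq_len(n - 1)) row <- cumsum(c(row[length(row)], row))
  row[length(row)]
}

#' Size of the model space over K directed transitions
#'
#' Counts the configurations in which each of `K` transitions is either
#' fixed to zero or assigned to a shared-value rate class: choosing the
#' zero set with a binomial coefficient and partitioning the remainder into
#' classes with a Bell number gives
#' `sum_z choose(K, z) * B(K - z) = B(K + 1)`. For the 12 transitions of a
#' 4-state model this is 27,644,437.
#'
#' @param K Number of directed transitions, `K >= 0`.
#' @return Exact count as a numeric scalar.
#' @export
model_space_size <- function(K) {
  stopifnot(K >= 0, K <= 21)
  sum(vapply(0:K, function(z) choose(K, z) * bell_number(K - z), numeric(1)))
}

#' Prior probability of a model signature
#'
#' The model-space prior is uniform over unique canonical signatures, so
#' every signature has probability `1 / model_space_size(K)`.
#'
#' @param K Number of directed transitions.
#' @return A probability.
#' @export
prior_probability <- function(K) 1 / model_space_size(K)

#' Score the unique models of a posterior sample
#'
#' For each unique canonical signature: its frequency in the retained
#' sample, posterior probability (frequency / sample size), prior
#' probability under the uniform model-space prior, and Bayes factor
#' (posterior / prior).
#'
#' @param post A `pattern_posterior`.
#' @return A `model_scores` data frame sorted by decreasing Bayes factor.
#' @export
score_models <- function(post) {
  stopifnot(inherits(post, "pattern_posterior"))
  n <- nrow(post$samples)
  if (n == 0) stop("empty posterior sample")
  K <- post$k * (post$k - 1)
  tab <- table(post$samples$signature)
  prior <- prior_probability(K)
  out <- data.frame(signature = names(tab), frequency = as.integer(tab),
                    posterior = as.integer(tab) / n, prior = prior,
                    bf = (as.integer(tab) / n) / prior,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$bf, out$signature), ]
  rownames(out) <- NULL
  attr(out, "sample_size") <- n
  attr(out, "K") <- K
  class(out) <- c("model_scores", "data.frame")
  out
}

#' Derive the top model set
#'
#' Models with positive evidence: Bayes factor at least `threshold`
#' (default 2) under the raw-odds convention, or `2 log(BF) >= threshold`
#' under the log convention.
#'
#' @param scores A `model_scores` data frame from [score_models()].
#' @param threshold Inclusion threshold (inclusive).
#' @param convention `"raw"` compares the odds ratio itself; `"log"`
#'   compares `2 log(BF)`.
#' @return A `model_scores` data frame restricted to the top set, sorted by
#'   decreasing Bayes factor; empty (with a warning) when no model reaches
#'   the threshold.
#' @export
top_model_set <- function(scores, threshold = 2,
                          convention = c("raw", "log")) {
  stopifnot(inherits(scores, "model_scores"))
  convention <- match.arg(convention)
  keep <- if (convention == "raw") scores$bf >= threshold
  else 2 * log(scores$bf) >= threshold
  out <- scores[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("no model reaches the Bayes factor threshold")
  attr(out, "sample_size") <- attr(scores, "sample_size")
  attr(out, "K") <- attr(scores, "K")
  attr(out, "threshold") <- threshold
  class(out) <- c("model_scores", "data.frame")
  out
}

#' Marginal transition probabilities and mean rates
#'
#' For every directed transition, the marginal probability (MP) of it being
#' fixed to zero and of it having a positive value, cumulated over the
#' models of the reference set (each retained sample counts once), plus the
#' frequency-weighted mean of the rate over the samples where it is
#' positive. Over the full sample `mp_zero + mp_positive = 1` for every
#' transition; over the top model set the sums equal the posterior mass of
#' the top set and need not reach 1.
#'
#' @param post A `pattern_posterior`.
#' @param reference `"full"` (entire sample distribution) or `"top"` (top
#'   model set).
#' @param threshold,convention Passed to [top_model_set()] when
#'   `reference = "top"`.
#' @return A `transition_summary` data frame with columns `from`, `to`,
#'   `label`, `mp_zero`, `mp_positive`, `mean_rate`; the reference set is
#'   recorded in attributes.
#' @export
transition_summary <- function(post, reference = c("full", "top"),
                               threshold = 2, convention = "raw") {
  stopifnot(inherits(post, "pattern_posterior"))
  reference <- match.arg(reference)
  n_total <- nrow(post$samples)
  if (n_total == 0) stop("empty posterior sample")
  keep <- rep(TRUE, n_total)
  if (reference == "top") {
    top <- top_model_set(score_models(post), threshold, convention)
    keep <- post$samples$signature %in% top$signature
  }
  A <- post$assign[keep, , drop = FALSE]
  R <- post$rates[keep, , drop = FALSE]
  out <- post$transitions
  out$mp_zero <- colSums(A == 0) / n_total
  out$mp_positive <- colSums(A > 0) / n_total
  out$mean_rate <- vapply(seq_len(ncol(A)), function(j) {
    pos <- A[, j] > 0
    if (any(pos)) mean(R[pos, j]) else 0
  }, numeric(1))
  attr(out, "reference") <- reference
  attr(out, "n_reference") <- sum(keep)
  attr(out, "n_total") <- n_total
  class(out) <- c("transition_summary", "data.frame")
  out
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("marginal transition probabilities (reference set: ",
      attr(x, "reference"), ", ", attr(x, "n_reference"), "/",
      attr(x, "n_total"), " samples)\n", sep = "")
  df <- data.frame(transition = x$label, mp_zero = round(x$mp_zero, 3),
                   mp_positive = round(x$mp_positive, 3),
                   mean_rate = signif(x$mean_rate, 4),
                   call = ifelse(x$mp_positive > x$mp_zero,
                                 "probably occurs", "probably does not occur"))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Model-averaged ancestral state probabilities
#'
#' Arithmetic mean, over the retained posterior sample, of the per-sample
#' root-state probability vectors; the model-averaged estimate of the
#' ancestral pattern state at the root (most recent common ancestor).
#'
#' @param post A `pattern_posterior` carrying root-state vectors.
#' @return A named probability vector over the states.
#' @export
ancestral_average <- function(post) {
  stopifnot(inherits(post, "pattern_posterior"))
  if (nrow(post$root_probs) == 0) stop("posterior carries no root vectors")
  p <- colMeans(post$root_probs)
  names(p) <- post$states
  p / sum(p)
}

#' Export the transition graph as a DOT file
#'
#' Directed graph over the states: a transition is drawn black when its
#' marginal probability of occurring exceeds that of not occurring, gray
#' otherwise; edge width is proportional to the mean positive rate, and
#' each edge is annotated with `mp_zero / mp_positive`.
#'
#' @param summary A `transition_summary`.
#' @param path Output path for the DOT file; `NULL` returns the DOT text
#'   only.
#' @param min_mp Transitions with `mp_positive` below this are omitted from
#'   the drawing (nodes are always kept).
#' @return The DOT source, invisibly (also written to `path` if given).
#' @export
export_transition_graph <- function(summary, path = NULL, min_mp = 0) {
  stopifnot(inherits(summary, "transition_summary"))
  states <- unique(c(summary$from, summary$to))
  max_rate <- max(summary$mean_rate, 1e-12)
  lines <- c("digraph pattern_evolution {",
             "  rankdir=LR;",
             sprintf("  // reference set: %s", attr(summary, "reference")),
             sprintf("  \"%s\" [shape=box];", states))
  for (i in seq_len(nrow(summary))) {
    if (summary$mp_positive[i] < min_mp || summary$mp_positive[i] == 0) next
    occurs <- summary$mp_positive[i] > summary$mp_zero[i]
    w <- 0.5 + 4 * summary$mean_rate[i] / max_rate
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [color=%s, penwidth=%.2f, label=\"%.2f/%.2f\"];",
      summary$from[i], summary$to[i], if (occurs) "black" else "gray",
      w, summary$mp_zero[i], summary$mp_positive[i]))
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(dot, path)
  invisible(dot)
}
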