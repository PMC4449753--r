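# Reversible-jump MCMC front end: settings, single chains, multi-chain runs.

#' Sampler settings
#'
#' The `"paper"` profile reproduces the published run lengths: four chains
#' of 10,050,000 iterations, 50,000 burn-in, sampling every 1000th model and
#' then every 20th retained model. The `"desk"` profile scales this to runs
#' that finish in minutes (200,000 iterations, 5,000 burn-in, sampling every
#' 100th then every 5th model) while keeping the same double-thinning
#' structure.
#'
#' @param profile `"desk"` or `"paper"`; presets that any named argument
#'   overrides.
#' @param iterations,burn_in,sample_every,post_thin Chain length, discarded
#'   prefix, first-stage sampling stride, and second-stage thinning.
#' @param n_chains Number of independent chains.
#' @param ratedev Initial scale of the symmetric reflected proposal kernel
#'   for rate values; `NULL` starts at the empirical rate scale and lets
#'   burn-in adaptation take over.
#' @param acceptance_window Target acceptance-rate window for rate-update
#'   moves; `ratedev` is adapted during burn-in (only) to stay inside it.
#' @param shape_bounds,scale_bounds Bounds of the uniform hyperprior on the
#'   gamma rate prior's shape and scale. The shape is kept at or above 1 so
#'   the prior density stays finite at zero; shapes below 1 concentrate
#'   unbounded density at 0 and degenerate the reversible-jump comparison
#'   between "fixed to zero" and "arbitrarily small positive rate".
#'   `scale_bounds = NULL` is resolved at run time to
#'   `(0, 2 x empirical rate scale)`, where the empirical scale is the
#'   parsimony change count divided by the total tree length.
#' @param p_rate_move Probability of a rate-value update per iteration (the
#'   remainder are structural reversible-jump moves).
#' @param hyper_every Interleave a Metropolis update of the gamma
#'   hyperparameters every this many iterations.
#' @param adapt_window Iterations between ratedev adaptation checks during
#'   burn-in.
#' @param seed Integer seed; chain `i` uses `seed + i - 1`.
#' @return A list of class `sampler_settings`.
#' @export
sampler_settings <- function(profile = c("desk", "paper"), iterations = NULL,
                             burn_in = NULL, sample_every = NULL,
                             post_thin = NULL, n_chains = 4, ratedev = NULL,
                             acceptance_window = c(0.20, 0.40),
                             shape_bounds = c(1, 3),
                             scale_bounds = NULL, p_rate_move = 0.6,
                             hyper_every = 10, adapt_window = 500,
                             seed = 1L) {
  profile <- match.arg(profile)
  def <- if (profile == "paper")
    list(iterations = 10050000L, burn_in = 50000L, sample_every = 1000L,
         post_thin = 20L)
  else
    list(iterations = 200000L, burn_in = 5000L, sample_every = 100L,
         post_thin = 5L)
  s <- list(
    profile = profile,
    iterations = as.integer(iterations %||% def$iterations),
    burn_in = as.integer(burn_in %||% def$burn_in),
    sample_every = as.integer(sample_every %||% def$sample_every),
    post_thin = as.integer(post_thin %||% def$post_thin),
    n_chains = as.integer(n_chains), ratedev = ratedev,
    acceptance_window = acceptance_window, shape_bounds = shape_bounds,
    scale_bounds = scale_bounds, p_rate_move = p_rate_move,
    hyper_every = as.integer(hyper_every),
    adapt_window = as.integer(adapt_window), seed = as.integer(seed))
  if (s$burn_in >= s$iterations) stop("burn_in must be < iterations")
  if (s$sample_every < 1 || s$post_thin < 1)
    stop("sample_every and post_thin must be >= 1")
  if (length(acceptance_window) != 2 ||
      acceptance_window[1] >= acceptance_window[2])
    stop("acceptance_window must be an increasing pair")
  class(s) <- "sampler_settings"
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Empirical rate scale of a dataset
#'
#' Parsimony-count heuristic used to seed proposal scales and the hyperprior
#' interval: the minimum number of state changes (Fitch parsimony) divided
#' by the total tree length, i.e. a lower bound on changes per unit branch
#' length.
#'
#' @param tree A rooted [ape::phylo].
#' @param characters Tip states (see [log_likelihood()]).
#' @param states State alphabet.
#' @return A positive scalar.
#' @export
empirical_rate_scale <- function(tree, characters, states = PATTERN_STATES) {
  st <- tip_state_vector(tree, characters, states)
  dat <- lapply(st, function(i) as.character(i))
  names(dat) <- tree$tip.label
  pd <- phangorn::phyDat(dat, type = "USER",
                         levels = as.character(seq_along(states)))
  score <- phangorn::parsimony(tree, pd)
  max(score, 0.5) / sum(tree$edge.length)
}

#' Run one reversible-jump MCMC chain
#'
#' Metropolis-Hastings over transition-rate configurations. Each iteration
#' proposes, with probability `p_rate_move`, a symmetric reflected update
#' of one rate-class value, and otherwise one of four structural moves
#' (fix a transition to zero; release a zero transition into an existing or
#' new class; merge two classes; split a class), each with the exact
#' dimension-matching Hastings correction so that a likelihood-off chain
#' targets the uniform model-space prior. New-class values are drawn from
#' the current gamma rate prior, making the reversible-jump Jacobian one.
#' Gamma hyperparameters are updated by interleaved Metropolis steps under
#' a bounded uniform hyperprior. `ratedev` is adapted during burn-in only.
#'
#' @param tree,characters Reconciled phylogeny and tip states; may be
#'   `NULL` for a prior-only run (`likelihood_on = FALSE`).
#' @param settings A [sampler_settings()] object.
#' @param likelihood_on When `FALSE` the likelihood is held at zero and the
#'   chain samples the prior (used for prior-recovery checks).
#' @param k Number of states (inferred from `characters`/`states` when
#'   possible; required for data-free prior-only runs).
#' @param states State alphabet.
#' @param root_prior Root prior (see [log_likelihood()]).
#' @param init Optional starting `rate_config`; the default starts with all
#'   transitions in one shared class at the empirical rate scale.
#' @param chain_id Chain index, used to offset the seed.
#' @return A `pattern_posterior` object with one chain.
#' @export
run_chain <- function(tree = NULL, characters = NULL, settings = sampler_settings(),
                      likelihood_on = TRUE, k = NULL, states = NULL,
                      root_prior = NULL, init = NULL, chain_id = 1L) {
  stopifnot(inherits(settings, "sampler_settings"))
  if (likelihood_on && (is.null(tree) || is.null(characters)))
    stop("tree and characters are required unless likelihood_on = FALSE")
  if (is.null(k)) {
    k <- if (!is.null(states)) length(states)
    else if (!is.null(init)) init$k else 4L
  }
  if (is.null(states))
    states <- if (k == 4) PATTERN_STATES else paste0("s", seq_len(k))
  K <- k * (k - 1)

  emp <- 1.0
  td <- list(edge = matrix(0L, 0, 2), elen = numeric(0), n_tip = 0L,
             n_node = 0L)
  tip_state <- integer(0)
  if (likelihood_on) {
    td <- prepare_tree(tree)
    tip_state <- tip_state_vector(tree, characters, states)
    emp <- empirical_rate_scale(tree, characters, states)
  }
  scale_bounds <- settings$scale_bounds %||% c(1e-6, 2 * emp)
  ratedev0 <- settings$ratedev %||% emp
  rp <- if (likelihood_on) {
    Q0 <- matrix(emp, k, k); diag(Q0) <- -(k - 1) * emp
    resolve_root_prior(root_prior, Q0, k)
  } else rep(1 / k, k)

  if (is.null(init)) init <- rate_config(rep(1L, K), values = emp, k = k,
                                         states = states)
  stopifnot(inherits(init, "rate_config"), init$k == k)

  set.seed(settings$seed + chain_id - 1L)
  raw <- .cpp_run_chain(td$edge, td$elen, td$n_tip, td$n_node, tip_state,
                        as.integer(k), rp, init$assignment, init$values,
                        settings$iterations, settings$burn_in,
                        settings$sample_every, settings$post_thin,
                        ratedev0, settings$acceptance_window[1],
                        settings$acceptance_window[2], settings$adapt_window,
                        settings$shape_bounds, scale_bounds,
                        settings$p_rate_move, settings$hyper_every,
                        likelihood_on)

  n <- nrow(raw$assign)
  sig <- apply(raw$assign, 1, function(a)
    paste(ifelse(a == 0, "Z", a), collapse = "-"))
  samples <- data.frame(chain = chain_id, iteration = raw$iteration,
                        signature = if (n > 0) sig else character(0),
                        loglik = raw$loglik, shape = raw$hyper[, 1],
                        scale = raw$hyper[, 2], stringsAsFactors = FALSE)
  structure(list(samples = samples, assign = raw$assign, rates = raw$rates,
                 root_probs = raw$root_probs, k = k, states = states,
                 transitions = transition_index(k, states),
                 settings = settings, likelihood_on = likelihood_on,
                 acceptance = list(list(chain = chain_id,
                                        proposed = raw$proposed,
                                        accepted = raw$accepted,
                                        ratedev = raw$ratedev))),
            class = "pattern_posterior")
}

#' Run several independent chains and merge their retained samples
#'
#' @inheritParams run_chain
#' @return A merged `pattern_posterior`; the `samples$chain` column records
#'   the originating chain.
#' @export
run_chains <- function(tree = NULL, characters = NULL,
                       settings = sampler_settings(), likelihood_on = TRUE,
                       k = NULL, states = NULL, root_prior = NULL,
                       init = NULL) {
  posts <- lapply(seq_len(settings$n_chains), function(i)
    run_chain(tree, characters, settings, likelihood_on, k, states,
              root_prior, init, chain_id = i))
  merge_posteriors(posts)
}

merge_posteriors <- function(posts) {
  p <- posts[[1]]
  p$samples <- do.call(rbind, lapply(posts, `[[`, "samples"))
  p$assign <- do.call(rbind, lapply(posts, `[[`, "assign"))
  p$rates <- do.call(rbind, lapply(posts, `[[`, "rates"))
  p$root_probs <- do.call(rbind, lapply(posts, `[[`, "root_probs"))
  p$acceptance <- do.call(c, lapply(posts, `[[`, "acceptance"))
  rownames(p$samples) <- NULL
  p
}

#' @export
print.pattern_posterior <- function(x, ...) {
  cat("pattern evolution posterior sample\n")
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  cat("  chains:", length(unique(x$samples$chain)),
      " retained samples:", nrow(x$samples), "\n")
  cat("  unique model signatures:", length(unique(x$samples$signature)), "\n")
  if (x$likelihood_on)
    cat("  log-likelihood range: [",
        paste(signif(range(x$samples$loglik), 6), collapse = ", "), "]\n")
  else cat("  prior-only run (likelihood off)\n")
  invisible(x)
}

#' Write or read a posterior sample as TSV
#'
#' The TSV holds one retained sample per row: chain, iteration, signature,
#' log-likelihood, hyperparameters, per-transition rates and root-state
#' probabilities. A header comment records the state alphabet.
#'
#' @param post A `pattern_posterior`.
#' @param path Output path.
#' @return `path` (write) or a `pattern_posterior` (read).
#' @export
write_posterior <- function(post, path) {
  rates <- post$rates
  colnames(rates) <- paste0("rate.", post$transitions$label)
  rootp <- post$root_probs
  colnames(rootp) <- paste0("root.", post$states)
  df <- cbind(post$samples, as.data.frame(rates), as.data.frame(rootp))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# plumevol posterior; states=",
                    paste(post$states, collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "# plumevol posterior"))
    stop("not a plumevol posterior TSV: ", path)
  states <- strsplit(sub(".*states=", "", header), ",")[[1]]
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          stringsAsFactors = FALSE, check.names = FALSE)
  k <- length(states)
  idx <- transition_index(k, states)
  rate_cols <- paste0("rate.", idx$label)
  root_cols <- paste0("root.", states)
  miss <- setdiff(c(rate_cols, root_cols), names(df))
  if (length(miss) > 0)
    stop("malformed posterior TSV, missing columns: ",
         paste(miss, collapse = ", "))
  assign <- t(vapply(strsplit(df$signature, "-", fixed = TRUE),
                     function(s) as.integer(ifelse(s == "Z", 0L, s)),
                     integer(k * (k - 1))))
  structure(list(
    samples = df[c("chain", "iteration", "signature", "loglik", "shape",
                   "scale")],
    assign = assign, rates = as.matrix(df[rate_cols]),
    root_probs = as.matrix(df[root_cols]), k = k, states = states,
    transitions = idx, settings = NULL, likelihood_on = any(df$loglik != 0),
    acceptance = list()), class = "pattern_posterior")
}
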