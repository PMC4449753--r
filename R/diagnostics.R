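# Convergence and autocorrelation diagnostics for the retained chains.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log harmonic mean of likelihoods
#'
#' `-(logsumexp(-logL) - log n)`, computed entirely in log space so that
#' very negative log-likelihoods do not underflow. Used as a cross-chain
#' convergence heuristic (chains agreeing to within 1 lnHM), not as a
#' marginal-likelihood estimate.
#'
#' @param logL Numeric vector of log-likelihoods.
#' @return A scalar.
#' @export
log_harmonic_mean <- function(logL) {
  if (length(logL) == 0) stop("empty log-likelihood sequence")
  -(logsumexp(-logL) - log(length(logL)))
}

#' Ljung-Box autocorrelation test
#'
#' Portmanteau test `Q = n (n + 2) sum_h r_h^2 / (n - h)` against a
#' chi-square with `lags` degrees of freedom (computed via
#' [stats::Box.test()]). A small p-value indicates residual autocorrelation
#' in the retained trace, calling for further thinning.
#'
#' @param series Numeric trace (e.g. retained log-likelihoods).
#' @param lags Number of lags; default `min(10, floor(n / 5))`.
#' @return List with `statistic`, `p_value` and `lags`.
#' @export
ljung_box <- function(series, lags = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  if (is.null(lags)) lags <- max(1L, min(10L, n %/% 5L))
  if (n <= lags) stop("series must be longer than the number of lags")
  if (sd(series) == 0)
    stop("constant series: autocorrelation is undefined")
  bt <- stats::Box.test(series, lag = lags, type = "Ljung-Box")
  list(statistic = unname(bt$statistic), p_value = unname(bt$p.value),
       lags = lags)
}

#' Cross-chain harmonic-mean convergence check
#'
#' Chains are considered converged when the maximum pairwise difference of
#' their log harmonic means is below `tol` (default 1 lnHM).
#'
#' @param lnHM Numeric vector of per-chain log harmonic means (>= 2 chains).
#' @param tol Allowed spread.
#' @return List with `converged`, `spread` and the input `lnHM`.
#' @export
check_convergence <- function(lnHM, tol = 1) {
  if (length(lnHM) < 2) stop("convergence check needs at least two chains")
  spread <- max(lnHM) - min(lnHM)
  list(converged = spread < tol, spread = spread, lnHM = lnHM)
}

#' Diagnostics for a multi-chain posterior sample
#'
#' Per-chain log harmonic means, the cross-chain spread rule, per-move
#' acceptance rates, and a Ljung-Box test on the retained log-likelihood
#' trace of each chain.
#'
#' @param post A `pattern_posterior` with at least two chains.
#' @param lags Lags for the Ljung-Box test (default as in [ljung_box()]).
#' @return A list of class `chain_diagnostics`.
#' @export
chain_diagnostics <- function(post, lags = NULL) {
  stopifnot(inherits(post, "pattern_posterior"))
  chains <- sort(unique(post$samples$chain))
  lnHM <- vapply(chains, function(ch)
    log_harmonic_mean(post$samples$loglik[post$samples$chain == ch]),
    numeric(1))
  names(lnHM) <- paste0("chain", chains)
  conv <- if (length(chains) >= 2) check_convergence(lnHM) else
    list(converged = NA, spread = NA_real_, lnHM = lnHM)
  lb <- lapply(chains, function(ch) {
    tr <- post$samples$loglik[post$samples$chain == ch]
    if (length(tr) > 5 && sd(tr) > 0) ljung_box(tr, lags) else NULL
  })
  names(lb) <- names(lnHM)
  acc <- lapply(post$acceptance, function(a) {
    r <- a$accepted / pmax(a$proposed, 1)
    names(r) <- names(a$proposed)
    list(chain = a$chain, rate = r, ratedev = a$ratedev)
  })
  structure(list(lnHM = lnHM, convergence = conv, ljung_box = lb,
                 acceptance = acc), class = "chain_diagnostics")
}

#' @export
print.chain_diagnostics <- function(x, ...) {
  cat("chain diagnostics\n  lnHM:",
      paste(sprintf("%s=%.3f", names(x$lnHM), x$lnHM), collapse = ", "), "\n")
  if (!is.na(x$convergence$converged))
    cat(sprintf("  spread %.3f -> %s\n", x$convergence$spread,
                if (x$convergence$converged) "converged (< 1 lnHM)"
                else "NOT converged (>= 1 lnHM)"))
  for (lb in x$ljung_box)
    if (!is.null(lb))
      cat(sprintf("  Ljung-Box: Q = %.2f, p = %.3f (%d lags)\n",
                  lb$statistic, lb$p_value, lb$lags))
  for (a in x$acceptance)
    cat(sprintf("  chain %d acceptance: %s (ratedev %.3g)\n", a$chain,
                paste(sprintf("%s=%.2f", names(a$rate), a$rate),
                      collapse = " "), a$ratedev))
  invisible(x)
}

#' Thin a posterior until its trace passes the Ljung-Box test
#'
#' Applies successively stronger thinning to the retained sample until the
#' per-chain log-likelihood traces show no significant autocorrelation
#' (`p > p_target`) or a floor sample size per chain is reached, mirroring
#' the further-sample-every-20th convention.
#'
#' @param post A `pattern_posterior`.
#' @param p_target Ljung-Box p-value to reach.
#' @param floor_n Minimum retained samples per chain.
#' @return A thinned `pattern_posterior` with attribute `"thin"`.
#' @export
autothin_posterior <- function(post, p_target = 0.05, floor_n = 100) {
  thin <- 1L
  repeat {
    sub <- thin_posterior(post, thin)
    chains <- unique(sub$samples$chain)
    n_min <- min(table(sub$samples$chain))
    ps <- vapply(chains, function(ch) {
      tr <- sub$samples$loglik[sub$samples$chain == ch]
      if (length(tr) <= 10 || sd(tr) == 0) return(1)
      ljung_box(tr)$p_value
    }, numeric(1))
    if (all(ps > p_target) || n_min / 2 < floor_n) break
    thin <- thin * 2L
  }
  attr(sub, "thin") <- thin
  sub
}

thin_posterior <- function(post, thin) {
  if (thin <= 1) return(post)
  keep <- unlist(lapply(unique(post$samples$chain), function(ch) {
    idx <- which(post$samples$chain == ch)
    idx[seq_along(idx) %% thin == 0]
  }))
  keep <- sort(keep)
  post$samples <- post$samples[keep, , drop = FALSE]
  post$assign <- post$assign[keep, , drop = FALSE]
  post$rates <- post$rates[keep, , drop = FALSE]
  post$root_probs <- post$root_probs[keep, , drop = FALSE]
  rownames(post$samples) <- NULL
  post
}
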