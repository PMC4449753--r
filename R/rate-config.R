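# Transition-rate configurations: each directed transition is either fixed
# to zero or assigned to a shared-value rate class.

#' Directed transitions of a k-state model
#'
#' The fixed transition ordering used throughout the package: row-major over
#' the off-diagonal of the rate matrix. For `k = 4` the states are the four
#' pattern states, giving 12 directed transitions.
#'
#' @param k Number of character states.
#' @param states Optional state labels (defaults to the pattern states when
#'   `k = 4`, otherwise `s1..sk`).
#' @return Data frame with columns `from`, `to`, `label`.
#' @export
transition_index <- function(k = 4, states = NULL) {
  if (is.null(states))
    states <- if (k == 4) PATTERN_STATES else paste0("s", seq_len(k))
  stopifnot(length(states) == k)
  from <- rep(seq_len(k), each = k)
  to <- rep(seq_len(k), k)
  keep <- from != to
  data.frame(from = states[from[keep]], to = states[to[keep]],
             label = paste0(states[from[keep]], "->", states[to[keep]]),
             stringsAsFactors = FALSE)
}

#' Create a transition-rate configuration
#'
#' A configuration assigns each of the `k(k-1)` directed transitions either
#' to zero (`assignment` entry 0) or to one of `m` shared-value rate
#' classes (entries `1..m`). Class labels are canonicalized to first
#' appearance along the fixed transition ordering, so two configurations
#' differing only by class relabeling are identical.
#'
#' @param assignment Integer vector of length `k(k-1)`; 0 marks a
#'   transition fixed to zero.
#' @param values Non-negative rate value for each class, in class-label
#'   order (units: expected transitions per unit branch length).
#' @param k Number of states.
#' @param states Optional state labels.
#' @return An object of class `rate_config`.
#' @export
#' @examples
#' # all 12 transitions share one rate
#' rate_config(rep(1, 12), values = 0.5)
rate_config <- function(assignment, values = numeric(0), k = 4, states = NULL) {
  K <- k * (k - 1)
  assignment <- as.integer(assignment)
  if (length(assignment) != K)
    stop("assignment must have length k(k-1) = ", K)
  if (any(assignment < 0)) stop("assignment entries must be >= 0")
  m <- length(unique(assignment[assignment > 0]))
  if (m > 0 && !setequal(unique(assignment[assignment > 0]), seq_len(m)))
    stop("class ids must be contiguous 1..m")
  values <- as.numeric(values)
  if (length(values) != m)
    stop("need one value per rate class (", m, "), got ", length(values))
  if (anyNA(values) || any(values < 0))
    stop("class values must be non-negative")
  cf <- canonicalize_config(list(assignment = assignment, values = values))
  idx <- transition_index(k, states)
  structure(list(k = k, states = if (is.null(states) && k == 4) PATTERN_STATES
                 else if (is.null(states)) paste0("s", seq_len(k)) else states,
                 transitions = idx, assignment = cf$assignment,
                 values = cf$values),
            class = "rate_config")
}

canonicalize_config <- function(cf) {
  a <- cf$assignment
  seen <- unique(a[a > 0])
  relab <- match(a, seen)
  a2 <- ifelse(a == 0, 0L, relab)
  list(assignment = as.integer(a2), values = cf$values[seen])
}

#' @export
print.rate_config <- function(x, ...) {
  cat("rate configuration (k =", x$k, "):\n")
  lab <- ifelse(x$assignment == 0, "0",
                paste0("class ", x$assignment, " = ",
                       signif(x$values[pmax(x$assignment, 1)], 4)))
  df <- data.frame(transition = x$transitions$label, rate = lab)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Build a rate configuration from named nonzero transitions
#'
#' Convenience wrapper around [rate_config()]: every transition named in
#' `positive` is assigned a rate; unnamed transitions are fixed to zero.
#'
#' @param positive Named numeric vector; names are transition labels such as
#'   `"uniform->regular"` and values are rates. Transitions sharing the
#'   same value are still placed in distinct classes unless `share_classes`
#'   is `TRUE`, in which case all positive transitions share one class (and
#'   `positive` must then be constant).
#' @param k,states See [rate_config()].
#' @param share_classes Put all positive transitions into a single class.
#' @return A `rate_config`.
#' @export
rate_config_from_labels <- function(positive, k = 4, states = NULL,
                                    share_classes = FALSE) {
  idx <- transition_index(k, states)
  pos <- match(names(positive), idx$label)
  if (anyNA(pos))
    stop("unknown transition labels: ",
         paste(names(positive)[is.na(pos)], collapse = ", "))
  K <- k * (k - 1)
  a <- integer(K)
  if (share_classes) {
    if (length(unique(positive)) > 1)
      stop("share_classes = TRUE requires a single shared rate value")
    a[pos] <- 1L
    rate_config(a, values = positive[[1]], k = k, states = states)
  } else {
    a[pos] <- seq_along(pos)
    rate_config(a, values = as.numeric(positive), k = k, states = states)
  }
}

#' Build the k x k rate matrix of a configuration
#'
#' Off-diagonal entry `q[i, j]` is the class value of transition `i -> j`
#' (zero for transitions fixed to zero); the diagonal is set to minus the
#' row sum, so rows sum to zero.
#'
#' @param config A `rate_config`.
#' @return A `k x k` numeric matrix with state dimnames.
#' @export
build_rate_matrix <- function(config) {
  stopifnot(inherits(config, "rate_config"))
  k <- config$k
  Q <- matrix(0, k, k, dimnames = list(config$states, config$states))
  rate <- ifelse(config$assignment == 0, 0,
                 config$values[pmax(config$assignment, 1)])
  t <- 1L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    Q[i, j] <- rate[t]
    t <- t + 1L
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Canonical model signature of a configuration
#'
#' Deterministic string encoding of which transitions are fixed to zero and
#' how the remainder partition into shared-value rate classes, with classes
#' numbered by first appearance along the fixed transition ordering. Two
#' configurations differing only by class relabeling map to the same
#' signature; rate values do not enter the signature.
#'
#' @param config A `rate_config`, or a bare integer assignment vector.
#' @return A single string, e.g. `"Z-1-1-2-..."`.
#' @export
canonical_signature <- function(config) {
  a <- if (inherits(config, "rate_config")) config$assignment
  else as.integer(config)
  seen <- unique(a[a > 0])
  relab <- match(a, seen)
  paste(ifelse(a == 0, "Z", relab), collapse = "-")
}
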