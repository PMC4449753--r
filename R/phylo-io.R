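# Tree input, validation, and reconciliation with character tables.

validate_tree <- function(tree, zero_epsilon = NULL) {
  if (!inherits(tree, "phylo")) stop("expected an object of class 'phylo'")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) stop("branch lengths are required")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    bad <- which(is.na(tree$edge.length) | tree$edge.length < 0)
    stop("missing or negative branch lengths on edges: ",
         paste(bad, collapse = ", "))
  }
  if (!ape::is.rooted(tree)) stop("a rooted tree is required")
  n_tip <- length(tree$tip.label)
  term <- tree$edge[, 2] <= n_tip
  zero_term <- term & tree$edge.length == 0
  if (any(zero_term)) {
    height <- max(ape::node.depth.edgelength(tree))
    eps <- if (is.null(zero_epsilon)) 1e-6 * height else zero_epsilon
    if (eps <= 0) eps <- 1e-8
    tree$edge.length[zero_term] <- eps
    message(sum(zero_term), " zero-length terminal branch(es) replaced by ",
            format(eps))
  }
  tree
}

#' Read and validate a phylogeny
#'
#' Reads Newick (or a NEXUS trees block, detected from the file header) and
#' validates: unique tip labels, a single root, and a branch length on every
#' edge. Polytomies are allowed. Zero-length terminal branches are replaced
#' by a small epsilon (default `1e-6` times the tree height) so that
#' transition matrices stay nondegenerate; the replacement is logged.
#' Branch lengths are otherwise used as supplied, with no ultrametric
#' enforcement.
#'
#' @param path Path to a tree file.
#' @param zero_epsilon Replacement for zero-length terminal branches;
#'   default `1e-6` times the tree height.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path, zero_epsilon = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- toupper(readLines(path, n = 1, warn = FALSE))
  tree <- if (startsWith(trimws(header), "#NEXUS"))
    ape::read.nexus(path) else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse a tree from ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  validate_tree(tree, zero_epsilon)
}

#' Reconcile a tree with a character table
#'
#' Under `policy = "prune"`, tips absent from the character table are
#' dropped from the tree (collapsing the resulting degree-2 nodes, so path
#' lengths between retained tips are preserved) and character rows absent
#' from the tree are dropped, with both lists reported. Under
#' `policy = "strict"` any mismatch is an error.
#'
#' @param tree An [ape::phylo] object.
#' @param characters A `pattern_characters` data frame.
#' @param policy `"prune"` or `"strict"`.
#' @return A list with elements `tree`, `characters` and `report` (character
#'   vectors `dropped_tips` and `dropped_taxa`).
#' @export
reconcile <- function(tree, characters, policy = c("prune", "strict")) {
  policy <- match.arg(policy)
  stopifnot(inherits(characters, "pattern_characters"))
  tips <- tree$tip.label
  taxa <- characters$taxon
  drop_tips <- setdiff(tips, taxa)
  drop_taxa <- setdiff(taxa, tips)
  if (policy == "strict" && (length(drop_tips) > 0 || length(drop_taxa) > 0))
    stop("tree/character mismatch: tips without data [",
         paste(drop_tips, collapse = ", "), "]; data without tips [",
         paste(drop_taxa, collapse = ", "), "]")
  if (length(tips) - length(drop_tips) < 3)
    stop("fewer than 3 tips remain after reconciliation")
  if (length(drop_tips) > 0) tree <- ape::drop.tip(tree, drop_tips)
  if (length(drop_taxa) > 0)
    characters <- new_pattern_characters(
      characters[!characters$taxon %in% drop_taxa, , drop = FALSE])
  list(tree = tree, characters = characters,
       report = list(dropped_tips = drop_tips, dropped_taxa = drop_taxa))
}
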