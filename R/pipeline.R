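# End-to-end analysis steps: tabulation, fitting, and posterior summary.

#' Tabulate pattern frequencies at all clade levels
#'
#' Reads a character CSV (and optionally a clade map), computes frequency
#' tables at the order, subfamily and tribe levels plus the bimodal
#' sex-phenotype breakdown, and optionally writes them as TSV.
#'
#' @param characters_csv Path to a character CSV (see [read_characters()]).
#' @param clade_map_csv Optional path to a clade map CSV; when absent only
#'   the order-level table is produced, with a warning.
#' @param out_dir Optional output directory for TSV files.
#' @return List with `tables` (one `pattern_freq_table` per level) and
#'   `bimodal_breakdown` (or `NULL` when no bimodal species with sex codes
#'   exist).
#' @export
tabulate_patterns <- function(characters_csv, clade_map_csv = NULL,
                              out_dir = NULL) {
  chars <- read_characters(characters_csv)
  cmap <- NULL
  levels <- "order"
  if (is.null(clade_map_csv)) {
    warning("no clade map supplied; reporting the order level only")
  } else {
    cmap <- read_clade_map(clade_map_csv)
    levels <- c("order", "subfamily", "tribe")
  }
  tables <- lapply(levels, function(lv)
    tabulate_frequencies(chars, cmap, level = lv))
  names(tables) <- levels
  breakdown <- tryCatch(bimodal_sex_breakdown(chars), error = function(e) NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (lv in levels)
      utils::write.table(tables[[lv]],
                         file.path(out_dir, paste0("frequencies_", lv, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(breakdown))
      utils::write.table(data.frame(category = names(breakdown),
                                    proportion = as.numeric(breakdown)),
                         file.path(out_dir, "bimodal_breakdown.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(tables = tables, bimodal_breakdown = breakdown)
}

#' Fit the pattern evolution model
#'
#' Reconciles the tree with the character table, runs `n_chains`
#' independent reversible-jump chains, and attaches convergence
#' diagnostics. By default a cross-chain harmonic-mean spread of 1 lnHM or
#' more raises an error; set `force = TRUE` to keep the sample anyway.
#'
#' @param tree A rooted [ape::phylo] (or a path readable by [read_tree()]).
#' @param characters A `pattern_characters` table (or a CSV path).
#' @param settings A [sampler_settings()] object.
#' @param root_prior Root prior (see [log_likelihood()]).
#' @param policy Reconciliation policy (see [reconcile()]).
#' @param force Keep the sample when the convergence rule fails.
#' @param out_dir Optional directory: posterior TSV, diagnostics JSON and
#'   the archived run configuration are written there.
#' @return List of class `pattern_fit` with `posterior`, `diagnostics`,
#'   `reconcile_report`, `settings`.
#' @export
fit_pattern_evolution <- function(tree, characters,
                                  settings = sampler_settings(),
                                  root_prior = NULL, policy = "prune",
                                  force = FALSE, out_dir = NULL) {
  if (is.character(tree)) tree <- read_tree(tree)
  if (is.character(characters)) characters <- read_characters(characters)
  rec <- reconcile(tree, characters, policy = policy)
  post <- run_chains(rec$tree, rec$characters, settings,
                     root_prior = root_prior)
  diags <- chain_diagnostics(post)
  conv <- diags$convergence
  if (!is.na(conv$converged) && !conv$converged) {
    msg <- sprintf("chains have not converged: lnHM spread %.3f >= 1",
                   conv$spread)
    if (force) warning(msg) else stop(msg)
  }
  fit <- structure(list(posterior = post, diagnostics = diags,
                        reconcile_report = rec$report, settings = settings),
                   class = "pattern_fit")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_posterior(post, file.path(out_dir, "posterior.tsv"))
    jsonlite::write_json(
      list(lnHM = as.list(diags$lnHM), spread = conv$spread,
           converged = conv$converged,
           settings = unclass(settings)),
      file.path(out_dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  }
  fit
}

#' Summarize a posterior sample
#'
#' Computes model scores, the top model set, marginal transition
#' probabilities (naming the reference set in the output), the
#' model-averaged ancestral state vector, and the DOT transition graph.
#'
#' @param post A `pattern_posterior` (or a posterior TSV path).
#' @param reference Reference set for marginal probabilities: `"top"` or
#'   `"full"`.
#' @param threshold Bayes factor threshold for the top model set.
#' @param out_dir Optional output directory (TSV/JSON/DOT files).
#' @return List with `scores`, `top_set`, `summary`, `ancestral`, `dot`.
#' @export
summarize_posterior <- function(post, reference = c("top", "full"),
                                threshold = 2, out_dir = NULL) {
  if (is.character(post)) post <- read_posterior(post)
  reference <- match.arg(reference)
  scores <- score_models(post)
  top <- top_model_set(scores, threshold)
  summ <- transition_summary(post, reference = reference,
                             threshold = threshold)
  anc <- ancestral_average(post)
  dot <- export_transition_graph(summ)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(scores, file.path(out_dir, "model_scores.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(top, file.path(out_dir, "top_model_set.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    sm <- cbind(reference = reference, summ)
    utils::write.table(sm, file.path(out_dir, "transition_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(as.list(anc), file.path(out_dir, "ancestral.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(dot, file.path(out_dir, "transition_graph.dot"))
  }
  list(scores = scores, top_set = top, summary = summ, ancestral = anc,
       dot = dot)
}
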