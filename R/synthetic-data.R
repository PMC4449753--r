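# Synthetic data with the statistical structure the analysis assumes:
# Yule trees plus exact stochastic simulation of the 4-state pattern
# character, so every stage of the pipeline can be validated end to end.

PRESET_ZEROS <- list(
  # bimodal patterning gained/lost only via the singular pattern types
  fig2_hypothesis = c("uniform->bimodal", "bimodal->uniform",
                      "irregular->regular", "regular->irregular"),
  # waterfowl-like: regular/bimodal arise from uniform; regular patterns
  # are not lost to irregular and do not feed bimodal directly
  anseriformes_like = c("uniform->irregular", "regular->irregular",
                        "regular->bimodal"),
  # game-bird-like: no direct uniform <-> bimodal, regular not lost to
  # irregular
  galliformes_like = c("uniform->bimodal", "bimodal->uniform",
                       "regular->irregular"),
  full_model = character(0),
  null_uniform = NULL  # all transitions fixed to zero
)

# default rates are calibrated so a root-to-tip path carries about three
# expected state changes (informative but not saturated); full_model
# deliberately saturates
PRESET_DEFAULTS <- list(
  fig2_hypothesis = list(n_tips = 150, rate = 0.31),
  anseriformes_like = list(n_tips = 118, rate = 0.36),
  galliformes_like = list(n_tips = 170, rate = 0.30),
  full_model = list(n_tips = 150, rate = 2.0),
  null_uniform = list(n_tips = 150, rate = 0)
)

#' Named generator presets
#'
#' Each preset fixes a true rate configuration, root state, tip count and
#' birth rate. `"fig2_hypothesis"` encodes the increasing-complexity
#' hypothesis (bimodal patterning reached only via the singular types);
#' `"anseriformes_like"` and `"galliformes_like"` encode the waterfowl- and
#' game-bird-like transition structures (three transitions fixed to zero,
#' nine positive); `"full_model"` has all 12 transitions positive at a high
#' shared rate (a saturating, state-symmetric configuration under which the
#' root is equivocal); `"null_uniform"` fixes every transition to zero.
#' Default rates give roughly three expected state changes along a
#' root-to-tip path, informative but not saturated; `"full_model"`
#' deliberately saturates.
#'
#' @param name Preset name.
#' @param n_tips,rate,birth_rate,root_state,seed Optional overrides of the
#'   preset's stored conditions.
#' @return A list of class `generator_preset` with fields `name`, `config`
#'   (a [rate_config()]), `root_state`, `n_tips`, `birth_rate`, `seed`.
#' @export
generator_preset <- function(name, n_tips = NULL, rate = NULL,
                             birth_rate = 1, root_state = "uniform",
                             seed = 1L) {
  if (!name %in% names(PRESET_ZEROS))
    stop("unknown preset '", name, "'; available: ",
         paste(names(PRESET_ZEROS), collapse = ", "))
  def <- PRESET_DEFAULTS[[name]]
  n_tips <- n_tips %||% def$n_tips
  rate <- rate %||% def$rate
  idx <- transition_index(4)
  if (name == "null_uniform") {
    config <- rate_config(rep(0L, 12))
  } else {
    zeros <- PRESET_ZEROS[[name]]
    a <- ifelse(idx$label %in% zeros, 0L, 1L)
    config <- rate_config(a, values = rate)
  }
  if (!root_state %in% PATTERN_STATES)
    stop("root_state must be one of: ", paste(PATTERN_STATES, collapse = ", "))
  structure(list(name = name, config = config, root_state = root_state,
                 n_tips = as.integer(n_tips), birth_rate = birth_rate,
                 seed = as.integer(seed)),
            class = "generator_preset")
}

#' Simulate a pure-birth (Yule) tree
#'
#' A neutral stand-in for published order-level phylogenies: a pure-birth
#' tree conditioned on the number of extant tips, with branch lengths in
#' time units, via [ape::rphylo()] with the death rate set to zero.
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth_rate Speciation rate.
#' @param seed Optional integer seed (makes the tree reproducible).
#' @return An [ape::phylo] object with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 3, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree
}

#' Simulate a pattern character along a tree
#'
#' Exact stochastic simulation of the continuous-time Markov process: along
#' each branch, exponential waiting times between state jumps, with jump
#' probabilities proportional to the current state's outgoing rates. Tip
#' states are optionally decomposed into per-sex motif codes consistent
#' with [classify_species()]; bimodal tips are emitted as both-sexes
#' bimodal, one-sex bimodal, or across-sex (one sex regular, the other
#' irregular) phenotypes with probabilities `bimodal_split`.
#'
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @param config The true `rate_config`.
#' @param root_state State at the root (name or index).
#' @param seed Optional integer seed.
#' @param sex_codes Emit per-sex motif codes (`TRUE`) or states only.
#' @param bimodal_split Probabilities of the three bimodal sex-phenotype
#'   categories; default `c(0.51, 0.37, 0.12)`, the published breakdown.
#' @return A `pattern_characters` data frame; the attribute
#'   `"node_states"` carries the simulated states of every node.
#' @export
simulate_character <- function(tree, config, root_state = "uniform",
                               seed = NULL, sex_codes = TRUE,
                               bimodal_split = c(0.51, 0.37, 0.12)) {
  stopifnot(inherits(config, "rate_config"))
  if (!is.null(seed)) set.seed(seed)
  Q <- build_rate_matrix(config)
  k <- config$k
  root_idx <- if (is.character(root_state)) match(root_state, config$states)
  else as.integer(root_state)
  if (is.na(root_idx) || root_idx < 1 || root_idx > k)
    stop("root state out of range")
  stopifnot(abs(sum(bimodal_split) - 1) < 1e-8, all(bimodal_split >= 0))

  tree_pre <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  node_state <- integer(n_all)
  node_state[n_tip + 1L] <- root_idx
  for (e in seq_len(nrow(tree_pre$edge))) {
    s <- node_state[tree_pre$edge[e, 1]]
    t_left <- tree_pre$edge.length[e]
    repeat {
      out <- -Q[s, s]
      if (out <= 0) break
      dt <- rexp(1, out)
      if (dt > t_left) break
      t_left <- t_left - dt
      targets <- seq_len(k)[-s]
      s <- targets[sample.int(k - 1, 1, prob = Q[s, targets])]
    }
    node_state[tree_pre$edge[e, 2]] <- s
  }
  states <- config$states[node_state[seq_len(n_tip)]]

  if (!sex_codes) {
    out <- pattern_characters(tree$tip.label, state = states)
  } else {
    codes <- t(vapply(states, emit_sex_codes, character(2),
                      bimodal_split = bimodal_split))
    out <- pattern_characters(tree$tip.label, male = codes[, 1],
                              female = codes[, 2])
    stopifnot(identical(out$state, unname(states)))
  }
  attr(out, "node_states") <- config$states[node_state]
  out
}

# decompose one tip state into per-sex motif strings
emit_sex_codes <- function(state, bimodal_split) {
  motif <- function() sample(c("BAR", "SCALE", "SPOT"), 1)
  both <- runif(1) < 0.5
  flip <- function(a, b) if (runif(1) < 0.5) c(a, b) else c(b, a)
  switch(state,
    uniform = c("NONE", "NONE"),
    irregular = if (both) c("MOTTLE", "MOTTLE") else flip("MOTTLE", "NONE"),
    regular = {
      m <- motif()
      if (both) c(m, motif()) else flip(m, "NONE")
    },
    bimodal = {
      cat3 <- sample.int(3, 1, prob = bimodal_split)
      bi <- function() paste("MOTTLE", motif(), sep = ";")
      if (cat3 == 1) c(bi(), bi())
      else if (cat3 == 2) flip(bi(), if (runif(1) < 0.5) "MOTTLE" else motif())
      else flip(motif(), "MOTTLE")
    })
}

#' Generate a complete synthetic dataset from a preset
#'
#' Simulates the tree and character data of a [generator_preset()] and
#' writes three files: the Newick tree, the character CSV, and a truth JSON
#' recording the generating configuration, root state and seed for
#' downstream recovery scoring.
#'
#' @param preset A `generator_preset` (or a preset name).
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @param seed Optional seed override.
#' @return List with `tree`, `characters`, `truth`, and (when written)
#'   `paths`.
#' @export
make_dataset <- function(preset, dir = NULL, seed = NULL) {
  if (is.character(preset)) preset <- generator_preset(preset)
  stopifnot(inherits(preset, "generator_preset"))
  seed <- seed %||% preset$seed
  tree <- simulate_yule_tree(preset$n_tips, preset$birth_rate, seed = seed)
  chars <- simulate_character(tree, preset$config, preset$root_state,
                              seed = seed + 1L)
  truth <- list(name = preset$name,
                assignment = preset$config$assignment,
                values = preset$config$values,
                signature = canonical_signature(preset$config),
                root_state = preset$root_state,
                n_tips = preset$n_tips, birth_rate = preset$birth_rate,
                seed = seed)
  out <- list(tree = tree, characters = chars, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(tree = file.path(dir, "tree.nwk"),
                  characters = file.path(dir, "characters.csv"),
                  truth = file.path(dir, "truth.json"))
    ape::write.tree(tree, paths$tree)
    write_characters(chars, paths$characters)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

#' Read a truth record back into a rate configuration
#'
#' @param path Path to a `truth.json` written by [make_dataset()].
#' @return A list with the truth fields and `config`, the reconstructed
#'   [rate_config()].
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$config <- rate_config(truth$assignment,
                              values = as.numeric(truth$values))
  truth
}
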