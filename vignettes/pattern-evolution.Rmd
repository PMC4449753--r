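---
title: "Modeling the evolution of plumage pattern types on phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the evolution of plumage pattern types on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Avian plumage patterning falls into a small number of functional types:
uniform coloration, *irregular* patterning (heterogeneous pigmentation
without a repeated motif, such as mottling, associated with static
camouflage), *regular* patterning (a repeating motif — bars, scales,
spots — associated with motion camouflage and signaling), and *bimodal*
patterning (irregular and regular elements combined, within one sex or
across the sexes). Comparative questions about these types — which are most
frequent in a clade, which evolved first, which transitions between them
occur at all — can be answered by modeling the pattern type as a discrete
character evolving along a phylogeny.

`plumevol` implements that analysis end to end: coding species into the
four states from per-sex motif scores, tabulating state frequencies by
clade, and, at its core, reversible-jump MCMC over multistate
transition-rate models, followed by a multimodel-inference summary (Bayes
factors, top model sets, marginal transition probabilities, model-averaged
ancestral states).

## The model

The pattern state evolves as a continuous-time Markov chain with `k = 4`
states and rate matrix `Q`, whose off-diagonal entry `q_ij >= 0` is the
instantaneous rate of the directed transition `i -> j` (diagonal entries
make rows sum to zero). Tip states are observed; the likelihood of `Q` is
computed by Felsenstein's pruning algorithm, propagating per-node partial
likelihoods from the tips to the root with per-node rescaling, and summing
over root states under a root prior (uniform by default; see below). The
likelihood depends on rates and branch lengths only through their products,
so the rate unit is "expected transitions per unit branch length" on
whatever scale the supplied tree uses.

A *model* (in the reversible-jump sense) is a configuration assigning each
of the `K = k(k-1) = 12` directed transitions either to zero — the
transition does not occur — or to one of `m` *rate classes* that share one
positive value. Configurations are identified by a canonical *signature*
(classes numbered by first appearance along a fixed transition ordering),
so relabeling classes does not create a new model. The number of distinct
models is

```
sum_z C(K, z) * Bell(K - z)  =  Bell(K + 1)
```

(choose the zero set, partition the rest into classes); for `K = 12` this
is `Bell(13) = 27,644,437`. The prior over models is uniform on
signatures, `1/Bell(K+1)` each.

Positive class values carry a gamma prior whose shape and scale are
themselves uniform on bounded intervals (a hyperprior), updated by
interleaved Metropolis steps.

## The sampler

Each iteration proposes, with probability 0.6, a *rate update* — one class
value perturbed by a symmetric uniform kernel of scale `ratedev`, reflected
at zero — and otherwise one of four *structural* moves, chosen uniformly
among those currently valid:

* **zero-out**: remove one transition from its class (deleting the class if
  it empties);
* **un-zero**: move a zero transition into an existing class or a new
  class, whose value is drawn from the current gamma prior;
* **merge**: absorb one class into another, discarding the absorbed value;
* **split**: peel a proper subset of a class into a new class with a
  freshly drawn value.

Drawing new-class values from the current rate prior makes the
reversible-jump Jacobian one, and each move carries the exact
dimension-matching Hastings correction, so a chain run with the likelihood
switched off targets the uniform model-space prior exactly. We verify this
two ways: the five `K = 2` structures are visited uniformly (chi-square),
and at `K = 12` the sampled distribution of the number of zeroed
transitions matches `C(12, z) Bell(12 - z)/Bell(13)` to Monte Carlo error.
With the likelihood on, sampled structure frequencies on a small two-state
problem match an exact quadrature over each structure's rates to three
decimals.

Two details matter for correctness. First, when the configuration has no
free class, the rate-update arm must be a null move rather than falling
through to a structural move — otherwise the structural proposal
probability becomes state-dependent and the all-zero model is undervisited
by exactly the move-mixture factor. Second, `ratedev` is adapted (toward a
0.20–0.40 acceptance window) during burn-in only, so the retained chain is
a fixed Markov kernel.

## Priors and the zero/positive comparison

The gamma shape is bounded in `[1, 3]` by default. This is deliberate: for
shapes below 1 the gamma density diverges at zero, so an arbitrarily small
positive rate becomes as cheap as a structural zero and the comparison
"fixed to zero vs. small positive value" — the entire point of the
reversible jump — degenerates. With shape at least 1 the density at zero is
finite and removing an unneeded rate is rewarded by the usual Occam factor.
The scale interval defaults to `(0, 2 * s_hat)` where `s_hat` is an
empirical rate scale, the Fitch parsimony change count divided by total
tree length — a lower bound on the average change rate that gives the
hyperprior a data-appropriate magnitude without fixing it.

The root prior is uniform over the four states by default (the equivocal
convention; a stationary-distribution or user-supplied prior is
available). Root-state probabilities reported per sample are proportional
to `root_prior[s] * L_root(s)`.

## Posterior summaries

With `n` retained samples: each unique signature's posterior probability is
its frequency over `n`; its Bayes factor is posterior over prior
(`1/Bell(K+1)`); the *top model set* is every model with BF at least 2
(raw-odds convention; a `2 log BF` convention is available). Marginal
probabilities (MP) of a transition being zero or positive are cumulated
over a named reference set — the full sample (where `mp_zero + mp_positive
= 1`) or the top set (where the sums equal the top set's posterior mass).
The model-averaged ancestral state is the arithmetic mean of per-sample
root vectors. The transition graph is exported as DOT, edges black where
`mp_positive > mp_zero`, width proportional to the mean positive rate.

One caveat at desk scale: with a few thousand retained samples against a
27-million-model space, every *visited* signature has posterior far above
its prior, so the BF >= 2 filter excludes little; top-set sizes comparable
to published analyses (tens of models) arise only when the posterior
concentrates strongly on few structures, which requires long chains and
strongly informative data.

## Run-length profiles and diagnostics

The `"paper"` profile uses four chains of 10,050,000 iterations, 50,000
burn-in, sampling every 1000th and then every 20th model (10,000 then 500
retained per chain). The `"desk"` profile — the default, used throughout
the tests — scales this to 200,000 iterations, 5,000 burn-in, sampling
every 100th then every 5th model (390 retained per chain), keeping the
double-thinning structure while finishing in about a minute per four-chain
run on one core. Convergence is monitored by the cross-chain log harmonic
mean rule (spread below 1 lnHM), computed entirely in log space;
autocorrelation of the retained log-likelihood trace is checked with a
Ljung–Box test, and `autothin_posterior()` doubles the thinning until the
trace passes or a floor sample size is reached. At desk scale the lnHM
spread rule fails intermittently — the harmonic mean is dominated by the
smallest sampled likelihood, so its chain-to-chain spread shrinks only
slowly with chain length; `fit_pattern_evolution(force = TRUE)` keeps such
samples with a warning.

## Numerical choices

* `transition_matrix()` computes `exp(Qt)` by scaling-and-squaring with a
  Padé approximant, entries clipped to `[0, 1]`.
* Inside the sampler, one likelihood evaluation needs `exp(Qt)` for every
  edge. There the eigendecomposition of `Q` is computed once and reused
  across edges, with an automatic fallback to scaling-and-squaring per
  edge whenever the eigendecomposition fails or reconstructs `Q` with
  error above `1e-9` (near-defective matrices, which arise for the highly
  structured `Q` of sparse configurations). The eigenvalue path is an
  order of magnitude faster on 100+-tip trees and agrees with the direct
  exponential to well below the Monte Carlo noise.
* Partial likelihoods are rescaled at every internal node; an impossible
  dataset returns `-Inf` rather than an error in the likelihood (but is an
  error in `root_state_probabilities()`).
* Zero-length terminal branches are replaced on input by `1e-6` times the
  tree height (logged), keeping transition matrices nondegenerate.
* Bell numbers use the Bell-triangle recurrence in doubles, exact through
  `Bell(22) < 2^53`; `K` is capped accordingly.

## The synthetic generator

`make_dataset()` pairs a pure-birth (Yule) tree, simulated via
`ape::rphylo()` with the death rate at zero and conditioned on the tip
count, with an exact stochastic simulation of the pattern character
(exponential waiting times between jumps along each branch). Presets fix
the true structure: `fig2_hypothesis` (bimodal patterning reached and lost
only via the singular types), `galliformes_like` and `anseriformes_like`
(three transitions fixed to zero, nine positive, mirroring the game-bird-
and waterfowl-like results), `full_model` (all twelve positive at a high
shared rate), and `null_uniform` (no evolution). Tip counts follow the
published order-level trees (170 and 118). Preset rates are calibrated by
numerical integration so a root-to-tip path carries about three expected
state changes — informative but not saturated; `full_model` deliberately
saturates. Bimodal tips are decomposed into per-sex motif codes
(both-sexes-bimodal : one-sex-bimodal : across-sex at 51 : 37 : 12 by
default, the published breakdown), always consistent with
`classify_species()`.

What the generator does *not* emulate: extinction and sampling biases in
real trees, rate heterogeneity across lineages, correlated evolution with
other traits, and scoring noise. Recovery results on synthetic data
therefore speak to the correctness and calibration of the inference
machinery, not to the reliability of any particular empirical dataset.

## What recovery is and is not achievable at this scale

Two regimes matter, and they pull in opposite directions.

*Structure recovery* (which transitions are zero) needs many realized
events, hence the ~3-changes calibration. Even so, its power at 118–170
tips is limited: under the uniform-signature prior the marginal prior
probability that a given transition is zero is `Bell(12)/Bell(13) = 0.15`,
so for `mp_zero` to exceed `mp_positive` the data must supply a Bayes
factor of about 5.7 toward zero for that single transition. In our
simulations the nine truly-positive transitions of the galliformes-like
structure are recovered essentially always, while the three truly-zero
transitions typically reach `mp_zero` of only 0.25–0.5: a four-state
character on one 170-tip tree often genuinely supports routing some
probability through a forbidden transition (the full-model maximum
likelihood estimate itself frequently does so). This is a property of the
data size, not of the sampler — the sampler's posterior matches exact
quadrature where that is computable. Decisive zero-classifications like
those reported for the real orders require data whose transitions are
better separated than this generator's single shared rate.

*Ancestral-root recovery* needs the opposite: information about the root
decays with saturation, and at ~3 expected changes per path the root is
close to equivocal regardless of the sampler. Ancestral-recovery
demonstrations therefore use a root-informative override (rate 0.06,
about half an expected state change per path, so most tip lineages retain
the root state), where the model-averaged root probability concentrates
on the true state (typically 0.65-1); the saturated
symmetric `full_model` preset conversely returns 0.25 per state — the
equivocal outcome — to within 0.02.

## Known limitations

* No polymorphic or ambiguous tip states; one state per species.
* No rate variation across branches or hidden states; no
  trait-dependent diversification.
* The harmonic mean is used only as the published convergence heuristic,
  never as a marginal-likelihood estimate.
* Model priors other than uniform-over-signatures (e.g. uniform over the
  number of zeroed transitions) are not implemented; with 27 million
  models the uniform-signature prior concentrates prior mass on
  middling-complexity structures, which is part of why zeroing evidence
  accumulates slowly.
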