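# plumevol

Bayesian comparative analysis of plumage pattern evolution on phylogenies.

Bird plumage patterning falls into four functional types: **uniform**
coloration, **irregular** patterning (heterogeneous pigmentation without a
repeated motif, e.g. mottling — static camouflage), **regular** patterning
(a repeating motif: bars, scales, spots — motion camouflage and
signaling), and **bimodal** patterning (irregular and regular elements
combined within one sex or across the sexes). `plumevol` answers two kinds
of comparative questions about these types: *how frequent is each type in
a clade?* and *which evolutionary transitions between types occur at all,
and at what rate?*

## The model

The pattern type evolves along a rooted phylogeny as a continuous-time
Markov chain over the four states with rate matrix `Q`; the likelihood of
`Q` given tip states is computed with Felsenstein's pruning algorithm. A
*model* assigns each of the `K = 12` directed transition rates `q_ij`
either to zero ("the transition does not occur") or to one of `m`
shared-value rate classes. Counting the zero subsets with binomial
coefficients and the class partitions with Bell numbers, the model space
has

    sum_z C(12, z) * Bell(12 - z) = Bell(13) = 27,644,437

members, with a uniform prior over canonical model signatures. A
reversible-jump MCMC sampler moves through this space (rate updates plus
zero-out / un-zero / merge / split structural moves, gamma rate prior with
a bounded uniform hyperprior on its shape and scale). The retained sample
is summarized by multimodel inference:

* posterior of a model = its sample frequency; Bayes factor
  `BF = posterior / prior`; the **top model set** is every model with
  `BF >= 2`;
* **marginal probability (MP)** of each transition being fixed to zero or
  positive, cumulated over the full sample or the top set, plus its mean
  positive rate (exportable as a DOT transition graph);
* the **model-averaged ancestral state**: the mean of per-sample root
  state probabilities.

Convergence diagnostics follow the published protocol: cross-chain log
harmonic mean spread (< 1 lnHM), proposal-acceptance windows, and a
Ljung–Box autocorrelation check with automatic further thinning.

A synthetic-data module (Yule trees via `ape`, exact stochastic character
simulation, named presets with known zero structures) makes the whole
pipeline testable end to end without any external data.

## Worked example

Simulate a 60-species game-bird-like dataset (three transitions truly
zero), fit it with two desk-scale chains, and summarize:

```r
library(plumevol)
ds  <- make_dataset(generator_preset("galliformes_like", n_tips = 60), seed = 7)
tabulate_frequencies(ds$characters)
#>  clade n_species uniform irregular regular bimodal
#>  (all)        60      30         3      40      27

st  <- sampler_settings(profile = "desk", n_chains = 2, seed = 7)
fit <- fit_pattern_evolution(ds$tree, ds$characters, st, force = TRUE)
summ <- summarize_posterior(fit$posterior, reference = "full")
summ$summary
#> marginal transition probabilities (reference set: full, 780/780 samples)
#>          transition mp_zero mp_positive mean_rate            call
#>  uniform->irregular   0.382       0.618    0.1625 probably occurs
#>    uniform->regular   0.018       0.982    0.3185 probably occurs
#>    uniform->bimodal   0.267       0.733    0.1965 probably occurs
#>  ...
round(summ$ancestral, 3)
#>   uniform irregular   regular   bimodal
#>     0.464     0.124     0.236     0.176
```

The table reads: 98% of the posterior mass has `uniform -> regular`
positive (it "probably occurs", mean rate 0.32 per unit branch length),
while the truly-zero transitions (here e.g. `uniform -> bimodal`) carry
elevated `mp_zero`. The ancestral vector puts most mass on the true
(uniform) root; with saturated rates it returns the equivocal 0.25 per
state. A thin command-line wrapper for the same pipeline lives at
`inst/scripts/plumevol.R` (subcommands `simulate`, `tabulate`, `run`,
`summarize`).

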