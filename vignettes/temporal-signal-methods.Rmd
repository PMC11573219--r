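---
title: "Testing temporal signal with Bayes factors: models, priors and pitfalls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing temporal signal with Bayes factors: models, priors and pitfalls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Molecular clock dating needs calibration: rates and times are jointly
unidentifiable from sequence divergence alone. For microbes the usual
calibration is the sampling times of the sequences themselves ("tip
calibration"), which is only defensible when the population is *measurably
evolving* -- when appreciable change accumulates across the sampling window.
`betsig` implements the fully Bayesian test of that premise: the same
phylogenetic model is fitted with the true sampling times (heterochronous)
and with every sample placed at the present (isochronous), and the two are
compared by log marginal likelihood. A log Bayes factor of at least +3
(posterior model probability about 0.95 under equal prior odds) is read as
strong evidence *for* temporal signal, at most -3 as strong evidence
*against*, and anything between as inconclusive.

The scientific point of the package is not the comparison itself but its
fragility: the tree prior and its hyperprior can dominate the result. The
package therefore bundles, alongside the test, the simulation and
prior-predictive machinery needed to diagnose when the prior -- not the data
-- is answering the question.

## The model

The posterior over tree `T`, population size `theta`, substitution
parameters and clock rate `r` factorises as likelihood x tree prior x
hyperpriors:

* **Phylogenetic likelihood** `p(D | T, r, kappa)` -- Felsenstein pruning
  over compressed site patterns, JC or HKY (optionally +Gamma with
  mean-of-interval discrete rates, 4 categories by default), branch
  distances `rate x duration`. Partial likelihoods are rescaled per node
  whenever the largest entry drops below 1e-140; this matters because tree
  extension (below) produces branches hundreds of time units long. Gaps and
  ambiguity codes contribute a partial likelihood of 1 in every state.
  SNP-only alignments can be augmented with counts of invariant A/C/G/T
  columns so the likelihood refers to the full genome.
* **Tree prior** -- the serial constant-size coalescent
  (`coalescent_log_density()`), or the exponential-growth coalescent with
  `N(t) = Phi exp(-g t)` and a proper `Laplace(0, 1)` prior on `g`. Both are
  evaluated interval-by-interval with lineages activating at their sampling
  ages.
* **Hyperprior on `theta`/`Phi`** -- one of `Exponential(mean 1)`,
  `LogNormal(mu 1, sigma 5)` or `Gamma(shape 0.001, scale 1000)`. All three
  are proper, which marginal-likelihood comparison requires; the improper
  `1/x` prior is deliberately not offered. The lognormal's `mu`/`sigma` are
  read as log-space location and scale (the convention of the major Bayesian
  phylogenetics packages); a flag switches to a real-space-mean reading,
  since the source convention is genuinely ambiguous.
* **Clock** -- strict (single rate) or uncorrelated lognormal (UCLN)
  relaxed clock with i.i.d. branch rates, real-space mean `M`, log-space
  standard deviation `S`. Heterochronous fits place the CTMC-rate reference
  prior `Gamma(0.5, rate = tree length)` on `r` (or on `M`), so the rate
  prior's mean `0.5/L` moves with the tree; `S` gets an `Exponential(mean
  0.33)` prior. Isochronous fits fix the rate -- to the true simulation
  value in experiments, or to an order-of-magnitude guess on real data --
  so that `theta` and branch lengths stay in time units comparable across
  the two dating modes.
* **Optional hard bound** -- `Uniform(0, B)` on the root height, the
  pragmatic remedy for prior-driven false positives.

## Marginal likelihoods

Log marginal likelihoods are estimated by stepping-stone sampling along a
ladder of powers `beta_k = (k/K)^(1/0.3)` (quantiles of Beta(0.3, 1), dense
near 0). Chains anneal from the posterior (`beta = 1`) down to the prior,
each warm-started from the previous power's final state; the estimator
centres each step on its maximum observed log likelihood for overflow
safety, and the standard error aggregates per-step delta-method terms with
ESS-corrected sample sizes. Because every prior in the model is proper, the
path from the prior is a valid marginal-likelihood path; the generalised
(working-distribution) variant used by some reference software improves
efficiency, not the estimand, and is not implemented.

The sampler is a Metropolis-Hastings kernel with multiplier moves on all
positive scalars (log Hastings correction `log m` per scaled dimension),
a uniform node-age move, root-age and whole-tree scale moves, narrow and
wide exchanges of time-compatible subtrees, per-branch rate multipliers
(UCLN), and a joint "up-down" move that scales `theta` and all node ages up
while scaling clock rates down. The up-down move is what makes the prior
end of the ladder mix: under the coalescent, `theta` and the node ages are
strongly coupled, and the move rides that ridge exactly (for ultrametric
trees the tree-prior term is invariant along it). Proposal scales adapt by
Robbins-Monro towards 23.4% acceptance during burn-in only, so recorded
samples come from a fixed kernel.

Defaults are `K = 30` steps and 2x10^4 iterations per step. These are
deliberate desk-scale choices: the reference analyses in the literature use
`K = 100` and 2x10^6 iterations per step for genome-scale alignments, and
both numbers are plain arguments when that regime is wanted. Repeatability
should be checked with `repeatability_check()`; the conventional adequacy
criterion is a spread below 1.0 log unit across independent estimates.

## The synthetic-data generator

`make_replicates()` reproduces the study conditions the package is designed
around: 50-taxon constant-size coalescent trees with `theta = 1`; tip ages
drawn uniformly from {0, 0.10, 0.35, 0.50} (four discrete sampling epochs)
or all zero; JC sequences of 1,000 nt at 0.05 substitutions/site/time,
either strict-clock or UCLN (mean 0.05, log-sd 0.25). Under these settings
an alignment carries around 250 unique site patterns. A second,
"cholera-like" design mimics a bacterial SNP data set: 50 taxa,
`theta = 100`, isochronous truth, fake sampling ages drawn from an
exponential with mean one tenth of the root height; its sequence length
(2,000) and rate (0.003) defaults were chosen once so that the simulated
alignments carry site-pattern counts of the same order (~1,400) as the
empirical SNP alignment that design mimics.

Two generator facts are worth stating plainly. First, the isochronous
50-tip design has mean root height `2(1 - 1/50) = 1.96 ~ 2.0` time units
(the value usually quoted for this design), while the four-epoch
heterochronous variant necessarily sits higher, at about 2.40: staggered
tips delay coalescence by roughly the sampling span minus attrition. Both
values are reproduced by an independent coalescent simulator (msprime) and
are asserted in the test suite. Second, the generator emulates i.i.d. sites,
a single unstructured population, and no recombination or indels -- passing
tests therefore demonstrate correctness of the method under its own model,
not robustness to the violations real data bring.

`sample_prior_predictive()` draws `(theta, T, r)` generatively from the
joint prior (exactly, by construction, with rejection under a root bound)
rather than by prior-only MCMC; the `beta = 0` chain in the sampler targets
the same distribution and serves as a cross-check in the tests. Under the
lognormal hyperprior (sigma = 5) the induced root-height distribution is so
heavy-tailed that Monte-Carlo means are unstable -- summaries always report
medians and quantile ranges alongside means, and tail-dominated means should
not be treated as sharp targets.

## Tree extension and the experiment harness

When isochronous data are analysed with (incorrect) sampling times, the
sampler can inflate the root height until the 0.5-unit sampling window is a
negligible fraction of the tree -- the tree becomes effectively ultrametric
again and the likelihood penalty of the wrong dates evaporates
(`sampling_span_fraction()` is the diagnostic; values like 0.05% arise at
root height 1,000). Whether this *tree extension* pathway is available is
controlled almost entirely by the `theta` hyperprior: vague priors (the
gamma and lognormal above) leave it open and produce spurious "temporal
signal" (type I errors); the exponential prior, or a hard `Uniform(0, 5)`
root bound, closes it. `run_experiment()` tallies correct classifications
per cell of the (true clock x dating truth x hyperprior x analysis clock x
bound) grid, counting `|log BF| < 3` as a misclassification, with
heterochronous and isochronous truths simulated as disjoint replicate sets.

## Numerical and design choices

* Node ages are measured backward from the youngest tip; Newick branch
  lengths are age differences. Trees are strictly binary; ties in node ages
  are excluded by construction (continuous proposals).
* The exponential-growth simulator refuses `g < 0` (backward-in-time
  shrinking hazard leaves a positive probability of never coalescing); the
  density side supports `g < 0`, which the Laplace prior requires.
* Isochronous UCLN fits fix the relaxed-clock mean and sample `S` and the
  branch rates; continuous per-branch rates are used rather than the
  rate-category discretisation of some reference implementations -- an
  approximation that exchanges exactness of that discretisation for a
  simpler, fully continuous state space.
* Starting states are coalescent trees drawn at a moderate `theta` with the
  rate at the CTMC-reference mean; under a root bound the starting `theta`
  shrinks geometrically until the tree fits.
* The `Gamma(0.001, scale 1000)` hyperprior places roughly half its mass
  below 10^-300. Multiplier chains cannot traverse 300 decades in any
  practical run, so prior-end samples effectively condition on the
  numerically reachable part of that spike. The affected mass carries
  essentially zero likelihood and enters both dating modes identically, so
  log Bayes factors are insensitive to it, but absolute log marginal
  likelihoods under this prior should be read with that caveat.
* Every stage takes a seed and spawns independent child seeds per
  replicate, per model and per ladder step, so any single replicate can be
  re-run in isolation; `(configuration, seed)` determines all outputs.

## Test-scale choices

The test suite exercises the full pipeline at reduced problem sizes chosen
as the smallest at which each phenomenon is still expressed: classification
cells run 30-taxon, 1,000-nt replicates with `K = 12` and 4,000 iterations
per step; parameter-recovery checks use 15 taxa and 600 nt with
posterior-only chains. At these sizes the type I/II error pattern of the
full study appears with replicate-to-replicate noise, so the tests assert
scaled count tolerances rather than exact tallies; `run_experiment()` at
its defaults reproduces the full grid when more compute is available.

## Limitations

* Only fully parametric coalescent tree priors (constant, exponential
  growth); no skyline/skyride or birth-death priors.
* JC and HKY(+Gamma) only; no GTR, partitions, or +I mixture.
* Topology moves are exchange-based; for data sets much larger than the
  study designs, mixing should be verified (ESS gates of 100 on the log
  likelihood and `theta` are the recommended minimum).
* Marginal-likelihood estimates at desk-scale settings carry standard
  errors of order one log unit; Bayes factors near the +/-3 thresholds
  should be re-run with larger `K` and chain lengths before being believed.
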