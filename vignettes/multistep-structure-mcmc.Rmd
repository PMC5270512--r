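---
title: "Multi-step proposal MCMC for Bayesian network structures"
author: "mcmcDag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-step proposal MCMC for Bayesian network structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcmcDag)
```

## The problem

Given discrete multivariate observations — typically discretized molecular
measurements such as phosphoprotein levels, possibly including perturbation
experiments — we want the posterior distribution over directed acyclic
graphs (DAGs) encoding the dependency structure of the variables. The DAG
space grows superexponentially (25 DAGs at $n=3$, 29281 at $n=5$), so
beyond $n \approx 6$ the posterior must be sampled, and the standard tool is
Metropolis–Hastings over DAG space. Its weakness is well known: with
realistic dataset sizes the posterior landscape is rugged and multimodal,
and a sampler proposing only single-edge changes oscillates inside a local
maximum whose every exit has minuscule acceptance probability.

## Model and score

For multinomial data with independent Dirichlet priors the marginal
likelihood factorizes over families (a node and its parent set) and is
available in closed form. We use the BDeu parameterisation: with equivalent
sample size $s$ (`ess`, default 1), each cell of the conditional table of
child $i$ with $q_i$ parent configurations and arity $r_i$ receives
pseudo-count $s/(r_i q_i)$. The default $s = 1$ is the common
uninformative choice; the score is computed entirely in log space with
`lgamma`, and per-family results are cached under a `(child, parent-set)`
key so that a chain step rescores only the one or two families a move
touches.

Interventional samples are handled in the Cooper–Yoo manner: a clamped
value is excluded from its own family's counts (the experiment, not the
parents, set it) but still conditions its children. This is what breaks
score equivalence and orients edges: the test suite asserts that with
observational data the two orientations of a correlated pair score
identically, while clamping one variable favours the generating direction.

The structure prior is uniform over the DAGs admitted by the fan-in cap, so
acceptance ratios reduce to likelihood ratios times the Hastings ratio. A
`logPrior` function hook exists on `scoreSettings()` for informative priors
(honoured by `exactPosterior()` and `mhStep()`; the compiled chain runner
deliberately supports only the uniform prior).

## The multi-step mixture proposal

The one-step proposal draws uniformly from the neighbourhood
$\mathcal N(G)$ of single-edge additions, deletions and reversals whose
result is acyclic, with $q(G) = |\mathcal N(G)|$. Because $q$ varies over
the space, the Hastings ratio $q(G)/q(G')$ must be computed — and for
proposals composed of $t$ sequential uniform single-edge steps one might
fear having to sum over all routes and all interior neighbourhood sizes.
The key identity is that for every route from $G$ to $G'$ the reversed
route exists, and the product of interior $1/q$ factors is the same in both
directions; only the first factor differs. Summing over routes therefore
telescopes to

$$\frac{Q^t(G \mid G')}{Q^t(G' \mid G)} = \frac{q(G)}{q(G')},$$

independent of $t$, and the identity survives mixing over $t$ with any
probabilities $[p_1, \dots, p_{max}]$. `hastingsLogRatio()` is exactly
`log q(start) - log q(end)`; the test suite verifies the identity against
exhaustive route enumeration on the 3-node space and against $10^6$
simulated proposals.

Design choices worth stating explicitly:

* **Admissibility and symmetry.** A move is in the neighbourhood iff the
  result is acyclic and the child gaining a parent stays within
  `maxFanin`; deletions are always admissible. This keeps the relation
  symmetric (if $G'$ is reachable from $G$, then $G$ from $G'$), which the
  endpoint-ratio identity requires — an asymmetric cap rule would silently
  invalidate it.
* **Inefficient transitions are kept.** A multi-step walk may legally
  return to its start or reach a one-step neighbour; such proposals are
  improbable in large neighbourhoods and rejecting or resampling them
  would distort the proposal distribution. A walk ending at its start is
  always accepted (both deltas vanish).
* **Endpoint-only work.** Sampling a $t$-step walk enumerates $t$
  neighbourhoods anyway; the only extra cost of the Hastings correction is
  one enumeration at the walk's end. Mixture proposals therefore cost
  essentially the same per step as the classical sampler.
* **Mixture length.** `proposalSpec()` warns above length 5. A loose upper
  bound on a useful jump length is twice the maximal edge count (one such
  jump can connect any two DAGs), but jumps of that order are just random
  restarts and make the chain inefficient; in practice `[0.8, 0.2]` or
  `[0.5, 0.5]` over lengths 1–2 is where the benefit lies.
* **RNG discipline.** Each chain consumes its seeded stream in a fixed
  documented order (length draw, one draw per sub-step, acceptance draw),
  so runs are bit-reproducible given `chainConfig`'s seed.

Ergodicity is not merely asserted: `reachabilityWalk()` constructs, for any
ordered DAG pair and any $t$, a sequence of whole $t$-transitions
connecting them (tearing one graph down to the empty graph, spending
residual steps as reversals of a single edge, and rebuilding the target
with a parity-correcting edge), and `selfReturnWalks()` produces
self-returning sequences of both $s$ and $s+1$ transitions, forcing period
1. Both are exercised over every DAG pair on $n = 3$ in the tests.

## The exact oracle

`enumerateDags()` produces every DAG on $n \le 6$ nodes exactly once
(order-recursive generation with canonical-key deduplication; the guard
refuses larger $n$ where enumeration is prohibitive), and
`exactPosterior()` normalises the scores by log-sum-exp. All sampler
correctness claims in the package are adjudicated against this module: on a
seeded 3-node dataset of 200 rows, chains of $2 \times 10^5$ retained
states under the mixtures $[1.0]$, $[0.5, 0.5]$ and $[0, 1.0]$ match the
exact edge posteriors to within 0.02 max-absolute error and the exact DAG
distribution to within 0.02 total variation — and a negative control that
replaces the Hastings ratio by 1 fails the same bound, demonstrating that
the endpoint correction is load-bearing, not cosmetic.

## What the synthetic generators emulate

The package generates its own study systems in place of external datasets:

* `randomDag(n, edgeDensity, maxFanin)` — uniform topological order with
  independent edge inclusion. Default density 0.3 gives sparse,
  biologically plausible graphs; density is configurable and nothing below
  depends on a particular value.
* `randomCpts(structure, arities, concentration)` — symmetric-Dirichlet
  CPTs. Default arity 3 mirrors the common low/medium/high discretization
  of signaling data; default concentration 0.5 gives moderately peaky
  conditionals, so edges carry signal without being deterministic. All
  entries are strictly positive, which is the positivity the ergodicity
  argument assumes.
* `interventionalSample(bn, n, fraction)` — a fraction of rows (default
  0.3, matching common interventional designs) clamp one uniformly chosen
  node to a uniformly chosen value; the mask records the clamp.
* `combinedDataset(bnA, bnB, nEach)` — rows pooled from two different
  networks with no provenance column. No single DAG generated such data,
  so the posterior is genuinely multimodal: this is the stand-in for real
  systems with feedback loops and hidden variables.

What passing tests on these generators shows — and does not show: they
demonstrate correctness of the sampler against its target distribution and
the *direction* of the convergence improvement on multimodal data. They do
not certify behaviour on real measurements, whose discretization artefacts,
measurement noise and non-multinomial effects the generators deliberately
do not model.

## Study protocols and problem sizes

The convergence-comparison experiment pools 3000 + 3000 rows from two
random 10-node networks, runs three independent random-start chains per
proposal (`[1.0]` vs `[0.8, 0.2]`, fan-in cap 5), computes the mean
pairwise SSD between the chains' edge-posterior matrices, and averages over
six replicates. We run each chain for 15000 burn-in and 15000 sampling
steps thinned by 15 — sizes chosen so the whole comparison completes in
about a minute while leaving the one-step chains visibly mode-bound (their
retained samples typically contain only a handful of distinct DAGs, so the
SSD between independent chains stays large). At these lengths the absolute
SSD values are far from their long-run limits; it is the ordering of the
two proposals that is the reproducible finding, and it is asserted
one-sidedly over the six replicates.

The oracle-agreement runs use $2\times10^5$ retained states (seconds of
compute); the Hastings check uses $10^6$ simulated proposals per direction
between a fixed asymmetric pair ($q = 6$ vs $q = 5$), compared within three
Monte-Carlo standard errors by the delta method.

## Numerical choices and degenerate inputs

* Scores are log-space throughout; no probability-space products occur.
  Family tables larger than $2^{22}$ cells are refused with a pointer to
  the fan-in cap rather than silently thrashing memory.
* A dataset with zero (unmasked) rows scores 0 for every family, making
  the posterior uniform — used as the flat-target case in tests.
* `chainConfig` validates before any compute; `runChain` always consumes
  the acceptance draw even for certain-accept proposals, keeping streams
  aligned across negative-control variants.
* Move enumeration is sorted (kind, parent, child), so uniform indexing
  with a fixed seed is reproducible across platforms.
* Ties in `mapDag()` go to the first retained state; `bestConvergedPair()`
  breaks SSD ties towards the lowest chain indices; `consensusGraph()`
  uses a strict `>` threshold and reports (rather than enforces)
  acyclicity, since thresholded posteriors need not be acyclic.
* The empty neighbourhood (a single-node graph) is an explicit error, not
  a silent no-op.

## Limitations

Only discrete (multinomial/BDeu) scoring is implemented; Gaussian scoring,
equivalence-class (CPDAG) moves, order-based and dynamic-programming
samplers are out of scope. Adaptive tuning of the mixture during burn-in is
deliberately not performed — the mixture is fixed configuration, and the
hook-shaped place it would occupy is documented rather than enabled. The
exact oracle stops at $n = 6$. Interventions model single-node clamps; soft
or multi-target interventions would need a generalised mask semantics
(the scorer itself would accept them — the mask is per-cell).
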