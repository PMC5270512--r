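# Metropolis-Hastings chain over DAG space.
#
# Acceptance probability: min{1, exp(delta log likelihood + delta log prior
# + log q(start)/q(end))}. With the uniform structure prior the prior term
# vanishes and only the likelihood ratio and the endpoint neighbourhood-size
# ratio remain. Rejected proposals repeat the current state in the retained
# sample (standard MH accounting).

#' Construct a chain configuration
#'
#' @param sampleSize post-burn-in steps (every `thin`-th is retained).
#' @param seed integer RNG seed; governs the random initial DAG and every
#'   proposal/acceptance draw, so equal seeds give identical chains.
#' @param initialDag a [DagStructure-class], `"empty"`, or `"random"` (a
#'   uniform topological order with independent edge inclusion at
#'   probability 0.5, subject to the fan-in cap).
#' @param burnIn discarded initial steps.
#' @param thin keep every `thin`-th post-burn-in state.
#' @param proposal a [ProposalSpec-class].
#' @param score a [ScoreSettings-class].
#' @return a [ChainConfig-class].
#' @export
chainConfig <- function(sampleSize, seed, initialDag = "random", burnIn = 0,
                        thin = 1, proposal = proposalSpec(),
                        score = scoreSettings()) {
  new("ChainConfig", initialDag = initialDag, burnIn = as.integer(burnIn),
      sampleSize = as.integer(sampleSize), thin = as.integer(thin),
      seed = as.integer(seed), proposal = proposal, score = score)
}

#' One Metropolis-Hastings step
#'
#' Proposes a multi-step transition with [sampleTransition()] and accepts it
#' with probability `min(1, exp(delta log score + delta log prior +
#' hastingsLogRatio(q(start), q(end))))`. A proposal that ends at the
#' current structure is always accepted (zero deltas, unit ratio). Honours
#' a `logPrior` hook in `settings`.
#'
#' @param dag current [DagStructure-class].
#' @param dataset a [DiscreteDataset-class].
#' @param spec a [ProposalSpec-class].
#' @param settings a [ScoreSettings-class].
#' @param logScore cached `graphLogScore(dag, ...)`; computed when `NULL`.
#' @return list with elements `dag`, `logScore`, `accepted`, `walk`.
#' @export
mhStep <- function(dag, dataset, spec, settings = scoreSettings(),
                   logScore = NULL) {
  if (is.null(logScore)) logScore <- graphLogScore(dag, dataset, settings)
  walk <- sampleTransition(dag, spec)
  qStart <- walk@qValues[1]
  qEnd <- neighborhoodSize(walk@end, spec@maxFanin)
  propScore <- graphLogScore(walk@end, dataset, settings)
  logAlpha <- propScore - logScore +
    .logPriorOf(settings, walk@end) - .logPriorOf(settings, dag) +
    hastingsLogRatio(qStart, qEnd)
  accepted <- log(runif(1)) < logAlpha
  if (accepted) list(dag = walk@end, logScore = propScore, accepted = TRUE,
                     walk = walk)
  else list(dag = dag, logScore = logScore, accepted = FALSE, walk = walk)
}

.resolveInitialDag <- function(config, n, labels) {
  init <- config@initialDag
  if (is(init, "DagStructure")) {
    if (nNodes(init) != n) stop("initial DAG node count mismatch")
    return(init)
  }
  if (identical(init, "empty")) return(emptyDag(n, labels))
  randomDag(n, edgeDensity = 0.5, maxFanin = config@proposal@maxFanin,
            labels = labels)
}

#' Run one MCMC chain
#'
#' Executes `burnIn` discarded steps followed by `sampleSize` steps of which
#' every `thin`-th state is retained. Fully deterministic given the
#' config's seed (which this function sets). The chain requires the uniform
#' structure prior; use [mhStep()] directly for a custom `logPrior` hook.
#'
#' @param config a [ChainConfig-class].
#' @param dataset a [DiscreteDataset-class].
#' @param useHastings internal negative-control switch: `FALSE` replaces
#'   the Hastings ratio with 1, deliberately biasing the chain. Leave
#'   `TRUE` for correct sampling.
#' @return a [ChainSample-class].
#' @export
runChain <- function(config, dataset, useHastings = TRUE) {
  validObject(config)
  if (!is.null(config@score@logPrior))
    stop("runChain supports the uniform structure prior only")
  n <- nVariables(dataset)
  labels <- colnames(dataset@values)
  if (is.null(labels)) labels <- .defaultLabels(n)
  set.seed(config@seed)
  init <- .resolveInitialDag(config, n, labels)
  res <- cppRunChain(init@adjacency, dataset@values, dataset@arities,
                     .maskOrNull(dataset), config@score@ess,
                     config@proposal@lengthProbs,
                     .faninInt(config@proposal@maxFanin),
                     config@burnIn, config@sampleSize, config@thin,
                     isTRUE(useHastings))
  new("ChainSample", states = res$states, nNodes = n, labels = labels,
      logScores = res$logScores,
      acceptCounts = as.integer(res$acceptCounts),
      proposalCounts = as.integer(res$proposalCounts), config = config)
}

#' Run an ensemble of independent chains
#'
#' @param configs list of [ChainConfig-class]; duplicate seeds trigger a
#'   warning since such chains are identical, not independent.
#' @param dataset a [DiscreteDataset-class].
#' @inheritParams runChain
#' @return list of [ChainSample-class], one per config.
#' @export
runChainEnsemble <- function(configs, dataset, useHastings = TRUE) {
  if (length(configs) < 1) stop("at least one config required")
  seeds <- vapply(configs, function(cf) cf@seed, integer(1))
  if (anyDuplicated(seeds))
    warning("duplicate chain seeds: chains will not be independent")
  lapply(configs, runChain, dataset = dataset, useHastings = useHastings)
}

#' Pool retained samples from several chains
#'
#' Concatenates the retained states (and scores) of the given chains into
#' one [ChainSample-class]; edge posteriors of the pooled sample equal the
#' sample-size-weighted average of the per-chain matrices.
#'
#' @param samples list of [ChainSample-class] on the same node set.
#' @export
poolChains <- function(samples) {
  if (length(samples) < 1) stop("no samples to pool")
  n <- nNodes(samples[[1]])
  if (!all(vapply(samples, nNodes, integer(1)) == n))
    stop("samples must share the node count")
  new("ChainSample",
      states = do.call(rbind, lapply(samples, function(s) s@states)),
      nNodes = n, labels = samples[[1]]@labels,
      logScores = unlist(lapply(samples, logScores)),
      acceptCounts = as.integer(Reduce(`+`, lapply(samples, function(s) s@acceptCounts))),
      proposalCounts = as.integer(Reduce(`+`, lapply(samples, function(s) s@proposalCounts))),
      config = lapply(samples, function(s) s@config))
}

#' Materialise one retained state of a chain sample
#'
#' @param sample a [ChainSample-class].
#' @param i state index (1-based, in retention order).
#' @return the i-th retained [DagStructure-class].
#' @export
chainDag <- function(sample, i) {
  i <- as.integer(i)
  if (i < 1 || i > sampleSize(sample)) stop("state index out of range")
  n <- nNodes(sample)
  a <- matrix(as.integer(sample@states[i, ]), n, n, byrow = TRUE)
  new("DagStructure", adjacency = a, labels = sample@labels)
}
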