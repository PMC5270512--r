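# S4 classes for the DAG sampler. All node indices at the R level are
# 1-based; adjacency matrices are 0/1 integer with rows = parents and
# columns = children, so adjacency(x)[u, v] == 1 means the edge u -> v.

#' Directed acyclic graph structure
#'
#' The structure component of a Bayesian network: a set of labelled nodes and
#' an acyclic set of directed edges, stored as a 0/1 adjacency matrix with
#' rows indexing parents and columns children. Two structures with identical
#' edge sets are equal (`==`), which is what unique-DAG counting and the
#' exact-enumeration oracle rely on.
#'
#' @slot adjacency integer 0/1 matrix, `adjacency[u, v] == 1` iff edge u -> v.
#' @slot labels character vector of node labels.
#' @export
setClass("DagStructure",
  representation(adjacency = "matrix", labels = "character"))

setValidity("DagStructure", function(object) {
  a <- object@adjacency
  n <- nrow(a)
  if (ncol(a) != n) return("adjacency matrix must be square")
  if (n > 0 && !all(a %in% c(0L, 1L))) return("adjacency entries must be 0/1")
  if (n > 0 && any(diag(a) != 0L)) return("self-edges are not allowed")
  if (length(object@labels) != n) return("labels length must equal node count")
  if (n > 0 && !cppIsAcyclic(a)) return("edge set contains a directed cycle")
  TRUE
})

#' Single-edge move
#'
#' One admissible modification of a DAG: the addition, deletion or reversal
#' of a single directed edge. The edge is always given in the orientation it
#' has before the move (so a reversal of `(u, v)` yields the edge `(v, u)`).
#'
#' @slot kind one of `"addition"`, `"deletion"`, `"reversal"`.
#' @slot parent,child 1-based node indices of the edge before the move.
#' @export
setClass("EdgeMove",
  representation(kind = "character", parent = "integer", child = "integer"))

setValidity("EdgeMove", function(object) {
  if (!object@kind %in% c("addition", "deletion", "reversal"))
    return("kind must be addition, deletion or reversal")
  if (object@parent == object@child) return("self-edges are not allowed")
  TRUE
})

#' Multi-step transition walk
#'
#' A sampled (or constructed) walk of t sequential single-edge modifications
#' through DAG space, together with the neighbourhood size q(.) of the
#' structure each step was taken from. Intermediate structures are acyclic by
#' construction; the walk may legally return to its starting structure.
#'
#' @slot start,end [DagStructure-class] endpoints.
#' @slot moves data.frame with columns kind, parent, child (one row per step).
#' @slot qValues integer neighbourhood sizes before each step.
#' @slot maxFanin fan-in cap under which the walk was generated.
#' @export
setClass("TransitionWalk",
  representation(start = "DagStructure", end = "DagStructure",
                 moves = "data.frame", qValues = "integer",
                 maxFanin = "numeric"))

setValidity("TransitionWalk", function(object) {
  if (nrow(object@moves) != length(object@qValues))
    return("qValues length must equal the number of moves")
  TRUE
})

#' Discrete multivariate dataset
#'
#' Integer-coded observations (codes `0 ... arity - 1` per variable) with an
#' optional same-shape logical intervention mask; a `TRUE` mask entry marks a
#' value that was clamped by a perturbation rather than observed, and such a
#' value is excluded from its own family's likelihood counts while still
#' conditioning its children.
#'
#' @slot values samples x variables integer matrix.
#' @slot arities per-variable category counts (all >= 2).
#' @slot mask logical matrix of the same shape, or a 0x0 matrix when absent.
#' @export
setClass("DiscreteDataset",
  representation(values = "matrix", arities = "integer", mask = "matrix"))

setValidity("DiscreteDataset", function(object) {
  v <- object@values
  if (length(object@arities) != ncol(v))
    return("arities length must equal the number of variables")
  if (any(object@arities < 2L)) return("all arities must be >= 2")
  if (nrow(v) > 0) {
    if (any(is.na(v)) || any(v < 0L)) return("values must be non-negative integers")
    if (any(v >= rep(object@arities, each = nrow(v))))
      return("every value must be < its variable's arity")
  }
  m <- object@mask
  if (length(m) > 0 && !identical(dim(m), dim(v)))
    return("intervention mask shape must match values")
  TRUE
})

#' Scoring settings
#'
#' BDeu hyperparameters and the structure prior. The equivalent sample size
#' spreads a total Dirichlet pseudo-count of `ess` uniformly over the cells
#' of each family's conditional table. The structure prior is uniform unless
#' a `logPrior` hook (a function mapping a [DagStructure-class] to a log
#' prior value) is supplied; the hook is honoured by [exactPosterior()] and
#' [mhStep()] but [runChain()] requires the uniform prior.
#'
#' @slot ess equivalent sample size, positive.
#' @slot logPrior `NULL` (uniform) or a function(dag) -> log prior.
#' @export
setClass("ScoreSettings",
  representation(ess = "numeric", logPrior = "ANY"))

setValidity("ScoreSettings", function(object) {
  if (length(object@ess) != 1L || !is.finite(object@ess) || object@ess <= 0)
    return("ess must be a single positive number")
  if (!is.null(object@logPrior) && !is.function(object@logPrior))
    return("logPrior must be NULL or a function")
  TRUE
})

#' Proposal specification
#'
#' The mixture proposal: at each iteration a transition length t is drawn
#' with probability `lengthProbs[t]` and t sequential uniform single-edge
#' modifications are applied. `lengthProbs = c(1)` is the classical one-step
#' proposal; `c(0.8, 0.2)` proposes two-step jumps 20% of the time.
#'
#' @slot lengthProbs non-negative vector (p_1, ..., p_max) summing to 1.
#' @slot maxFanin fan-in cap (maximum parents per node), `Inf` for unlimited.
#' @export
setClass("ProposalSpec",
  representation(lengthProbs = "numeric", maxFanin = "numeric"))

setValidity("ProposalSpec", function(object) {
  p <- object@lengthProbs
  if (length(p) < 1L) return("lengthProbs must have at least one entry")
  if (any(p < 0)) return("lengthProbs must be non-negative")
  if (abs(sum(p) - 1) > 1e-12) return("lengthProbs must sum to 1")
  if (object@maxFanin < 1) return("maxFanin must be >= 1")
  TRUE
})

#' Chain run configuration
#'
#' @slot initialDag a [DagStructure-class], or `"empty"` / `"random"`.
#' @slot burnIn discarded initial steps (>= 0).
#' @slot sampleSize post-burn-in steps (>= 1).
#' @slot thin keep every `thin`-th post-burn-in state (>= 1).
#' @slot seed integer RNG seed for the chain.
#' @slot proposal [ProposalSpec-class].
#' @slot score [ScoreSettings-class].
#' @export
setClass("ChainConfig",
  representation(initialDag = "ANY", burnIn = "integer", sampleSize = "integer",
                 thin = "integer", seed = "integer", proposal = "ProposalSpec",
                 score = "ScoreSettings"))

setValidity("ChainConfig", function(object) {
  if (object@burnIn < 0L) return("burnIn must be >= 0")
  if (object@sampleSize < 1L) return("sampleSize must be >= 1")
  if (object@thin < 1L) return("thin must be >= 1")
  ok <- is(object@initialDag, "DagStructure") ||
    (is.character(object@initialDag) &&
       object@initialDag %in% c("empty", "random"))
  if (!ok) return("initialDag must be a DagStructure, \"empty\" or \"random\"")
  TRUE
})

#' Retained sample from one MCMC chain
#'
#' The ordered retained DAGs of a chain run, stored compactly (one raw byte
#' per adjacency cell per state), their log scores, and acceptance
#' bookkeeping per transition length. Use [chainDag()] to materialise single
#' states and [edgePosteriors()], [uniqueDagCount()], [mapDag()],
#' [scoreTrace()] for summaries.
#'
#' @slot states raw matrix, one retained state per row (flattened adjacency).
#' @slot nNodes node count.
#' @slot labels node labels.
#' @slot logScores log marginal likelihood of each retained state.
#' @slot acceptCounts,proposalCounts accepted / proposed moves per length t.
#' @slot config the [ChainConfig-class] that produced the sample.
#' @export
setClass("ChainSample",
  representation(states = "matrix", nNodes = "integer", labels = "character",
                 logScores = "numeric", acceptCounts = "integer",
                 proposalCounts = "integer", config = "ANY"))

setValidity("ChainSample", function(object) {
  if (nrow(object@states) != length(object@logScores))
    return("logScores length must match the number of retained states")
  if (ncol(object@states) != object@nNodes^2)
    return("state width must equal nNodes^2")
  TRUE
})

#' Exact posterior over an enumerated DAG space
#'
#' The complete list of DAGs on n nodes (within a fan-in cap), each with its
#' unnormalised log posterior weight. Normalised probabilities are computed
#' on demand via log-sum-exp ([probabilities()]).
#'
#' @slot states raw matrix of flattened adjacencies, one DAG per row.
#' @slot nNodes node count.
#' @slot labels node labels.
#' @slot logWeights unnormalised log posterior per DAG.
#' @export
setClass("DagDistribution",
  representation(states = "matrix", nNodes = "integer", labels = "character",
                 logWeights = "numeric"))

setValidity("DagDistribution", function(object) {
  if (nrow(object@states) != length(object@logWeights))
    return("logWeights length must match the number of DAGs")
  TRUE
})

#' Edge posterior probability matrix
#'
#' Per-ordered-pair posterior probabilities that each directed edge is
#' present, estimated as the fraction of sampled DAGs containing the edge
#' (or computed exactly from a [DagDistribution-class]). Entries lie in
#' [0, 1] with a zero diagonal.
#'
#' @slot probs n x n numeric matrix.
#' @slot provenance list describing the producing sample (chains, sizes).
#' @export
setClass("EdgePosteriorMatrix",
  representation(probs = "matrix", provenance = "list"))

setValidity("EdgePosteriorMatrix", function(object) {
  p <- object@probs
  if (nrow(p) != ncol(p)) return("matrix must be square")
  if (any(p < -1e-12 | p > 1 + 1e-12)) return("entries must lie in [0, 1]")
  if (nrow(p) > 0 && any(abs(diag(p)) > 1e-12)) return("diagonal must be zero")
  TRUE
})

#' Ground-truth discrete Bayesian network
#'
#' A DAG together with explicit conditional probability tables, used by the
#' synthetic-data generators. For node v with parents (p1 < p2 < ...), row j
#' of `cpts[[v]]` is the categorical distribution of v given the parent
#' configuration with mixed-radix index j (first parent most significant).
#'
#' @slot structure [DagStructure-class].
#' @slot arities per-node category counts.
#' @slot cpts list of numeric matrices, one per node (configs x arity).
#' @export
setClass("GroundTruthBN",
  representation(structure = "DagStructure", arities = "integer",
                 cpts = "list"))

setValidity("GroundTruthBN", function(object) {
  n <- nrow(object@structure@adjacency)
  if (length(object@arities) != n) return("arities length must equal node count")
  if (length(object@cpts) != n) return("one CPT per node required")
  for (v in seq_len(n)) {
    pa <- which(object@structure@adjacency[, v] == 1L)
    q <- prod(object@arities[pa])
    tab <- object@cpts[[v]]
    if (!is.matrix(tab) || nrow(tab) != q || ncol(tab) != object@arities[v])
      return(sprintf("CPT of node %d must be %d x %d", v, q, object@arities[v]))
    if (any(tab < 0)) return("CPT entries must be non-negative")
    if (any(abs(rowSums(tab) - 1) > 1e-12))
      return(sprintf("CPT rows of node %d must sum to 1", v))
  }
  TRUE
})
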