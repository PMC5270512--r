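# Convergence and sample-characterisation diagnostics.

#' Edge posterior probabilities of a sample
#'
#' Entry (u, v) is the fraction of retained DAGs containing the edge
#' u -> v — the Monte-Carlo estimate of the posterior probability of that
#' edge. Pooling chains first (see [poolChains()]) gives the sample-size
#' weighted average of the per-chain matrices.
#'
#' @param sample a non-empty [ChainSample-class].
#' @return an [EdgePosteriorMatrix-class].
#' @export
edgePosteriors <- function(sample) {
  m <- sampleSize(sample)
  if (m == 0) stop("empty sample")
  n <- nNodes(sample)
  s01 <- matrix(as.integer(sample@states != as.raw(0)), m, n * n)
  probs <- matrix(colMeans(s01), n, n, byrow = TRUE)
  dimnames(probs) <- list(sample@labels, sample@labels)
  new("EdgePosteriorMatrix", probs = probs,
      provenance = list(source = "chain", sampleSize = m))
}

#' Sum of squared differences between edge posterior matrices
#'
#' The pairwise convergence metric: sum over all ordered node pairs of the
#' squared difference of the two estimates. Symmetric, non-negative, zero
#' iff the matrices are equal.
#'
#' @param a,b [EdgePosteriorMatrix-class] (or plain matrices) of equal shape.
#' @export
edgePosteriorSSD <- function(a, b) {
  ma <- if (is(a, "EdgePosteriorMatrix")) a@probs else as.matrix(a)
  mb <- if (is(b, "EdgePosteriorMatrix")) b@probs else as.matrix(b)
  if (!identical(dim(ma), dim(mb))) stop("shape mismatch")
  sum((ma - mb)^2)
}

#' Best-converged chain pair
#'
#' Scans all unordered pairs of chains and returns the pair whose edge
#' posterior matrices have the lowest sum of squared differences — the
#' pair that agrees best, used as the convergence indicator. Ties are
#' broken towards the lowest chain indices.
#'
#' @param samples list of at least two [ChainSample-class].
#' @return list with `pair` (indices), `ssd`, and `ssdTable` (all pairs).
#' @export
bestConvergedPair <- function(samples) {
  if (length(samples) < 2) stop("at least two samples required")
  eps <- lapply(samples, edgePosteriors)
  pairs <- utils::combn(length(samples), 2)
  ssd <- apply(pairs, 2, function(p) edgePosteriorSSD(eps[[p[1]]], eps[[p[2]]]))
  best <- which.min(ssd)  # which.min returns the first minimum: lowest indices
  list(pair = pairs[, best], ssd = ssd[best],
       ssdTable = data.frame(i = pairs[1, ], j = pairs[2, ], ssd = ssd))
}

#' Number of distinct DAGs in a sample
#'
#' Counts distinct structures among the retained (post-thinning) states;
#' a chain oscillating between two structures reports 2.
#'
#' @param sample a [ChainSample-class].
#' @export
uniqueDagCount <- function(sample) {
  idx <- cppMatchRows(sample@states, sample@states)
  length(unique(idx))
}

#' Maximum a posteriori DAG of a sample
#'
#' The retained structure with the highest log score; ties go to the first
#' one encountered.
#'
#' @param sample a (possibly pooled) [ChainSample-class].
#' @return list with `dag` ([DagStructure-class]), `logScore`, `index`.
#' @export
mapDag <- function(sample) {
  if (sampleSize(sample) == 0) stop("empty sample")
  i <- which.max(logScores(sample))
  list(dag = chainDag(sample, i), logScore = logScores(sample)[i], index = i)
}

#' Consensus (average) graph from edge posteriors
#'
#' Keeps the edges whose posterior strictly exceeds `threshold`. The result
#' of thresholding need not be acyclic, so the graph is returned as an
#' adjacency matrix plus edge list with an `acyclic` flag, not as a
#' [DagStructure-class].
#'
#' @param posteriors an [EdgePosteriorMatrix-class].
#' @param threshold inclusion threshold in [0, 1] (default 0.85).
#' @return list with `adjacency`, `edges` (data.frame), `acyclic`.
#' @export
consensusGraph <- function(posteriors, threshold = 0.85) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  p <- posteriors@probs
  a <- matrix(as.integer(p > threshold), nrow(p), ncol(p))
  dimnames(a) <- dimnames(p)
  idx <- which(a == 1L, arr.ind = TRUE)
  edges <- data.frame(parent = as.integer(idx[, 1]),
                      child = as.integer(idx[, 2]),
                      posterior = p[idx])
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  list(adjacency = a, edges = edges, acyclic = cppIsAcyclic(a))
}

#' Acceptance probabilities over a one-step neighbourhood
#'
#' For each one-step neighbour G' of `dag`, the probability
#' `min(1, exp(delta log score + log q(G)/q(G')))` of accepting the move to
#' G' if it were proposed — the local-maximum picture: a structure whose
#' every exit has near-zero acceptance traps a one-step chain.
#'
#' @param dag a [DagStructure-class].
#' @param dataset a [DiscreteDataset-class].
#' @param settings a [ScoreSettings-class].
#' @param spec a [ProposalSpec-class] (supplies the fan-in cap).
#' @param cutoff report only moves with acceptance probability >= cutoff
#'   (default 0: report all).
#' @return data.frame with kind, parent, child, deltaLogScore, acceptProb.
#' @export
neighborhoodAcceptanceMap <- function(dag, dataset,
                                      settings = scoreSettings(),
                                      spec = proposalSpec(), cutoff = 0) {
  moves <- enumerateNeighborhood(dag, spec@maxFanin)
  qG <- nrow(moves)
  delta <- numeric(qG)
  acc <- numeric(qG)
  for (i in seq_len(qG)) {
    d <- deltaLogScore(dag, moves[i, ], dataset, settings)
    nb <- applyMove(dag, moves[i, ])
    qN <- neighborhoodSize(nb, spec@maxFanin)
    delta[i] <- d
    acc[i] <- min(1, exp(d + hastingsLogRatio(qG, qN)))
  }
  out <- cbind(moves, deltaLogScore = delta, acceptProb = acc)
  out[out$acceptProb >= cutoff, , drop = FALSE]
}

#' Score trace of a chain
#'
#' The tail of the retained log-score sequence, for trace plots. `lastK`
#' larger than the sample is clipped with a warning.
#'
#' @param sample a [ChainSample-class].
#' @param lastK number of trailing states (default: all).
#' @return data.frame with columns `index`, `logScore`.
#' @export
scoreTrace <- function(sample, lastK = NULL) {
  m <- sampleSize(sample)
  if (is.null(lastK)) lastK <- m
  if (lastK > m) {
    warning("lastK exceeds the sample size; returning the full trace")
    lastK <- m
  }
  idx <- seq.int(m - lastK + 1L, m)
  data.frame(index = idx, logScore = logScores(sample)[idx])
}
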