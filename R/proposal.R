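# The multi-step mixture proposal over DAG space.
#
# A proposal draws a transition length t with probability p_t, then takes t
# sequential single-edge modifications, each uniform over the current
# structure's neighbourhood. Summing the route probabilities over all walks
# between two endpoints shows that every interior neighbourhood size cancels
# between the forward and reverse directions, so the Hastings ratio is
# simply q(start) / q(end) — the proposal needs only the two endpoint
# neighbourhood sizes regardless of t or of the mixture.

#' Construct a proposal specification
#'
#' @param lengthProbs mixture vector `(p_1, ..., p_max)`: `p_t` is the
#'   probability of proposing a transition of t single-edge steps. Must be
#'   non-negative and sum to 1. A vector longer than 5 is allowed but
#'   warned against: very long jumps essentially sample the structure space
#'   at random and make for an inefficient chain.
#' @param maxFanin fan-in cap applied to every intermediate structure
#'   (`Inf` = unlimited).
#' @return a [ProposalSpec-class].
#' @examples
#' proposalSpec(c(0.8, 0.2))   # one step 80%, two steps 20%
#' @export
proposalSpec <- function(lengthProbs = 1, maxFanin = Inf) {
  if (length(lengthProbs) > 5)
    warning("transition lengths above 5 rarely help: long jumps approach ",
            "random sampling of the structure space")
  new("ProposalSpec", lengthProbs = as.numeric(lengthProbs),
      maxFanin = as.numeric(maxFanin))
}

#' Build a transition walk from explicit moves
#'
#' Replays `moves` from `start`, recording the neighbourhood size before
#' each step and validating that every step is admissible (acyclic result,
#' fan-in respected).
#'
#' @param start a [DagStructure-class].
#' @param moves data.frame with columns kind, parent, child.
#' @param maxFanin fan-in cap used for the q values.
#' @return a [TransitionWalk-class].
#' @export
transitionWalk <- function(start, moves, maxFanin = Inf) {
  cur <- start
  q <- integer(nrow(moves))
  for (i in seq_len(nrow(moves))) {
    q[i] <- neighborhoodSize(cur, maxFanin)
    cur <- applyMove(cur, moves[i, , drop = FALSE])
    if (is.finite(maxFanin) && max(colSums(cur@adjacency)) > maxFanin)
      stop("walk violates the fan-in cap")
  }
  new("TransitionWalk", start = start, end = cur, moves = moves,
      qValues = q, maxFanin = as.numeric(maxFanin))
}

#' Sample one multi-step transition
#'
#' Draws t from the mixture, then t uniform single-edge moves. The walk may
#' end at the starting structure or at a structure reachable in fewer
#' steps; such "inefficient" transitions are legal and preserve
#' correctness. RNG consumption order: length draw, then one draw per step.
#'
#' @param dag a [DagStructure-class] with a non-empty neighbourhood.
#' @param spec a [ProposalSpec-class].
#' @return a [TransitionWalk-class]; `walk@qValues[1]` is q(start).
#' @export
sampleTransition <- function(dag, spec) {
  res <- cppSampleTransition(dag@adjacency, spec@lengthProbs,
                             .faninInt(spec@maxFanin))
  moves <- data.frame(kind = .kindNames[res$moves[, 1]],
                      parent = res$moves[, 2] + 1L,
                      child = res$moves[, 3] + 1L, stringsAsFactors = FALSE)
  end <- new("DagStructure", adjacency = res$end, labels = dag@labels)
  new("TransitionWalk", start = dag, end = end, moves = moves,
      qValues = as.integer(res$qValues), maxFanin = spec@maxFanin)
}

#' Hastings log ratio of the multi-step proposal
#'
#' `log(qStart) - log(qEnd)`: for the uniform multi-step proposal the ratio
#' Q(start | end) / Q(end | start) telescopes to the ratio of the endpoint
#' neighbourhood sizes, for any transition length and any mixture.
#'
#' @param qStart,qEnd positive neighbourhood sizes of the two endpoints.
#' @export
hastingsLogRatio <- function(qStart, qEnd) {
  if (any(c(qStart, qEnd) <= 0)) stop("neighbourhood sizes must be positive")
  log(qStart) - log(qEnd)
}

#' Log probability of one specific route
#'
#' `log(p_t) - sum(log q_j)` over the structures the walk's steps were taken
#' from: the probability that the proposal draws exactly this walk. Summing
#' `exp()` of this over all routes between two endpoints gives the full
#' proposal probability Q^t(end | start).
#'
#' @param walk a [TransitionWalk-class].
#' @param spec the [ProposalSpec-class] the walk was sampled under.
#' @export
transitionLogProbability <- function(walk, spec) {
  t <- nrow(walk@moves)
  if (t < 1 || t > length(spec@lengthProbs) || spec@lengthProbs[t] == 0)
    stop("walk length has zero probability under this spec")
  log(spec@lengthProbs[t]) - sum(log(walk@qValues))
}

# ---------------------------------------------------------------------------
# Constructive reachability (the ergodicity argument, made executable)
# ---------------------------------------------------------------------------

.deletionMoves <- function(dag, k) {
  e <- dagEdges(dag)
  e <- e[seq_len(k), , drop = FALSE]
  data.frame(kind = rep("deletion", k), parent = e$parent, child = e$child,
             stringsAsFactors = FALSE)
}

#' Connect two DAGs with whole t-transitions
#'
#' Realises the irreducibility construction: any DAG can be turned into any
#' other using only complete transitions of length t. Edges of `gFrom` are
#' deleted in full t-transitions; residual steps are spent deleting down to
#' a single edge, reversing it, and removing it; `gTo` is then built up from
#' the empty graph, using a parity-correcting single edge (added in the
#' same direction as in `gTo` if the number of spare steps is even, the
#' opposite direction if odd) to absorb spare steps as reversals. Every
#' intermediate structure is acyclic.
#'
#' @param gFrom,gTo [DagStructure-class] objects on the same nodes (n >= 2
#'   unless both graphs are empty).
#' @param t transition length (>= 1).
#' @return list of [TransitionWalk-class], each of exactly t moves, whose
#'   concatenated application maps `gFrom` to `gTo`.
#' @export
reachabilityWalk <- function(gFrom, gTo, t) {
  t <- as.integer(t)
  if (t < 1) stop("t must be >= 1")
  n <- nNodes(gFrom)
  if (nNodes(gTo) != n) stop("endpoint DAGs must share the node set")
  e <- edgeCount(gFrom); e2 <- edgeCount(gTo)
  if (n < 2 && (e > 0 || e2 > 0)) stop("n = 1 admits no moves")
  walks <- list()
  cur <- gFrom

  addWalk <- function(moves) {
    stopifnot(nrow(moves) == t)
    w <- transitionWalk(cur, moves, maxFanin = Inf)
    walks[[length(walks) + 1L]] <<- w
    cur <<- w@end
  }

  # tear gFrom down to the empty graph
  dt <- e %/% t
  for (i in seq_len(dt)) addWalk(.deletionMoves(cur, t))
  e1 <- e - t * dt
  if (e1 > 0) {
    d1 <- e1 - 1L
    moves <- if (d1 > 0) .deletionMoves(cur, d1) else
      data.frame(kind = character(0), parent = integer(0), child = integer(0))
    edge <- dagEdges(cur)[d1 + 1L, ]
    p <- edge$parent; k <- edge$child
    for (i in seq_len(t - d1 - 1L)) {  # reversals of the single leftover edge
      moves <- rbind(moves, data.frame(kind = "reversal", parent = p, child = k))
      tmp <- p; p <- k; k <- tmp
    }
    moves <- rbind(moves, data.frame(kind = "deletion", parent = p, child = k))
    addWalk(moves)
  }

  # build gTo up from the empty graph
  if (e2 > 0) {
    eTo <- dagEdges(gTo)
    a <- e2 %/% t
    resid <- e2 - a * t
    if (resid > 0) {
      E <- t - resid  # spare steps in the partial transition
      first <- eTo[1L, ]
      if (E %% 2 == 0) {
        p <- first$parent; k <- first$child
      } else {
        p <- first$child; k <- first$parent
      }
      moves <- data.frame(kind = "addition", parent = p, child = k,
                          stringsAsFactors = FALSE)
      for (i in seq_len(E)) {  # E - 1 reversals, then the correcting one
        moves <- rbind(moves, data.frame(kind = "reversal", parent = p, child = k))
        tmp <- p; p <- k; k <- tmp
      }
      rest <- eTo[seq.int(2L, length.out = t - E - 1L), , drop = FALSE]
      if (nrow(rest) > 0)
        moves <- rbind(moves, data.frame(kind = "addition",
                                         parent = rest$parent,
                                         child = rest$child))
      addWalk(moves)
      done <- 1L + (t - E - 1L)
    } else done <- 0L
    remaining <- eTo[seq.int(done + 1L, length.out = e2 - done), , drop = FALSE]
    while (nrow(remaining) > 0) {
      chunk <- remaining[seq_len(t), , drop = FALSE]
      addWalk(data.frame(kind = "addition", parent = chunk$parent,
                         child = chunk$child, stringsAsFactors = FALSE))
      remaining <- remaining[-seq_len(t), , drop = FALSE]
    }
  }
  walks
}

#' Aperiodicity witness: self-returning walk pairs
#'
#' Constructs two sequences of whole t-transitions from `dag` back to
#' itself, of s and s+1 transitions respectively: the route through the
#' empty graph, and the same route with one filler transition inserted at
#' the empty graph (add an edge, reverse it t-2 times, delete it). The
#' existence of both lengths forces the chain's period to be 1.
#'
#' @param dag a [DagStructure-class] with at least 2 nodes.
#' @param t transition length, t >= 2.
#' @return list with elements `s` and `sPlus1`, each a list of
#'   [TransitionWalk-class] starting and ending at `dag`.
#' @export
selfReturnWalks <- function(dag, t) {
  t <- as.integer(t)
  if (t < 2) stop("the filler transition needs t >= 2")
  if (nNodes(dag) < 2) stop("n >= 2 required")
  empty <- emptyDag(nNodes(dag), dag@labels)
  down <- reachabilityWalk(dag, empty, t)
  up <- reachabilityWalk(empty, dag, t)
  p <- 1L; k <- 2L
  moves <- data.frame(kind = "addition", parent = p, child = k,
                      stringsAsFactors = FALSE)
  for (i in seq_len(t - 2L)) {
    moves <- rbind(moves, data.frame(kind = "reversal", parent = p, child = k))
    tmp <- p; p <- k; k <- tmp
  }
  moves <- rbind(moves, data.frame(kind = "deletion", parent = p, child = k))
  filler <- transitionWalk(empty, moves, maxFanin = Inf)
  list(s = c(down, up), sPlus1 = c(down, list(filler), up))
}
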