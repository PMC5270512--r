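# Generics and small accessors / show methods.

#' Number of nodes
#' @param x a DagStructure, GroundTruthBN, ChainSample or DagDistribution.
#' @return integer node count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @describeIn nNodes node count of a DAG.
#' @export
setMethod("nNodes", "DagStructure", function(x) nrow(x@adjacency))
#' @describeIn nNodes node count of a ground-truth network.
setMethod("nNodes", "GroundTruthBN", function(x) nNodes(x@structure))
#' @describeIn nNodes node count underlying a chain sample.
setMethod("nNodes", "ChainSample", function(x) x@nNodes)
#' @describeIn nNodes node count of an enumerated DAG space.
setMethod("nNodes", "DagDistribution", function(x) x@nNodes)

#' Node labels
#' @param x a DagStructure or ChainSample.
#' @return character vector of labels.
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))
#' @describeIn nodeLabels labels of a DAG.
setMethod("nodeLabels", "DagStructure", function(x) x@labels)
#' @describeIn nodeLabels labels of a chain sample.
setMethod("nodeLabels", "ChainSample", function(x) x@labels)

#' Adjacency matrix of a DAG
#' @param x a [DagStructure-class].
#' @return 0/1 integer matrix, rows = parents, columns = children.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @describeIn adjacency adjacency of a DagStructure.
setMethod("adjacency", "DagStructure", function(x) {
  a <- x@adjacency
  dimnames(a) <- list(x@labels, x@labels)
  a
})

#' Edge list of a DAG
#' @param x a [DagStructure-class].
#' @return data.frame with integer columns `parent`, `child` (1-based).
#' @export
setGeneric("dagEdges", function(x) standardGeneric("dagEdges"))
#' @describeIn dagEdges edges of a DagStructure, sorted by parent then child.
setMethod("dagEdges", "DagStructure", function(x) {
  idx <- which(x@adjacency == 1L, arr.ind = TRUE)
  df <- data.frame(parent = as.integer(idx[, 1]), child = as.integer(idx[, 2]))
  df[order(df$parent, df$child), , drop = FALSE]
})

#' Number of edges
#' @param x a [DagStructure-class].
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
#' @describeIn edgeCount edge count of a DagStructure.
setMethod("edgeCount", "DagStructure", function(x) sum(x@adjacency))

#' Retained log scores of a chain sample
#' @param x a [ChainSample-class].
#' @export
setGeneric("logScores", function(x) standardGeneric("logScores"))
#' @describeIn logScores retained log scores.
setMethod("logScores", "ChainSample", function(x) x@logScores)

#' Number of retained states / enumerated DAGs
#' @param x a [ChainSample-class] or [DagDistribution-class].
#' @export
setGeneric("sampleSize", function(x) standardGeneric("sampleSize"))
#' @describeIn sampleSize retained states in a chain sample.
setMethod("sampleSize", "ChainSample", function(x) nrow(x@states))
#' @describeIn sampleSize number of enumerated DAGs.
setMethod("sampleSize", "DagDistribution", function(x) nrow(x@states))

#' Normalised probabilities of an exact posterior
#' @param x a [DagDistribution-class].
#' @return numeric vector summing to 1 (log-sum-exp normalisation).
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))
#' @describeIn probabilities normalised DAG probabilities.
setMethod("probabilities", "DagDistribution", function(x) {
  w <- x@logWeights
  m <- max(w)
  e <- exp(w - m)
  e / sum(e)
})

#' Unnormalised log posterior weights
#' @param x a [DagDistribution-class].
#' @export
setGeneric("logWeights", function(x) standardGeneric("logWeights"))
#' @describeIn logWeights log weights of the enumerated DAGs.
setMethod("logWeights", "DagDistribution", function(x) x@logWeights)

#' Per-length acceptance rates of a chain
#' @param x a [ChainSample-class].
#' @return data.frame with columns t, proposed, accepted, rate.
#' @export
setGeneric("acceptanceRates", function(x) standardGeneric("acceptanceRates"))
#' @describeIn acceptanceRates acceptance bookkeeping per transition length.
setMethod("acceptanceRates", "ChainSample", function(x) {
  data.frame(t = seq_along(x@proposalCounts),
             proposed = x@proposalCounts, accepted = x@acceptCounts,
             rate = ifelse(x@proposalCounts > 0,
                           x@acceptCounts / x@proposalCounts, NA_real_))
})

#' @export
setMethod("as.matrix", "EdgePosteriorMatrix", function(x, ...) x@probs)

#' Provenance of an edge posterior matrix
#' @param x an [EdgePosteriorMatrix-class].
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @describeIn provenance provenance list (chains, sample sizes).
setMethod("provenance", "EdgePosteriorMatrix", function(x) x@provenance)

#' DAG equality (identical edge sets)
#' @param e1,e2 [DagStructure-class] objects.
#' @export
setMethod("==", signature("DagStructure", "DagStructure"), function(e1, e2) {
  identical(dim(e1@adjacency), dim(e2@adjacency)) &&
    all(e1@adjacency == e2@adjacency)
})

#' @export
setMethod("!=", signature("DagStructure", "DagStructure"), function(e1, e2) {
  !(e1 == e2)
})

setMethod("show", "DagStructure", function(object) {
  cat(sprintf("DagStructure: %d nodes, %d edges\n", nNodes(object),
              edgeCount(object)))
  e <- dagEdges(object)
  if (nrow(e) > 0) {
    lab <- object@labels
    txt <- paste0(lab[e$parent], " -> ", lab[e$child])
    cat("  ", paste(head(txt, 12), collapse = ", "),
        if (nrow(e) > 12) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "EdgeMove", function(object) {
  cat(sprintf("EdgeMove: %s (%d, %d)\n", object@kind, object@parent,
              object@child))
})

setMethod("show", "TransitionWalk", function(object) {
  cat(sprintf("TransitionWalk: %d step(s), q(start) = %d\n",
              nrow(object@moves),
              if (length(object@qValues)) object@qValues[1] else NA_integer_))
})

setMethod("show", "DiscreteDataset", function(object) {
  cat(sprintf("DiscreteDataset: %d samples x %d variables (arities %s)%s\n",
              nrow(object@values), ncol(object@values),
              paste(object@arities, collapse = ","),
              if (hasInterventions(object))
                sprintf(", %d intervened cells", sum(object@mask)) else ""))
})

setMethod("show", "ProposalSpec", function(object) {
  cat(sprintf("ProposalSpec: [%s], max fan-in %s\n",
              paste(format(object@lengthProbs), collapse = ", "),
              if (is.finite(object@maxFanin)) object@maxFanin else "unlimited"))
})

setMethod("show", "ChainSample", function(object) {
  cat(sprintf("ChainSample: %d retained states on %d nodes\n",
              sampleSize(object), nNodes(object)))
  cat(sprintf("  log score range: [%.4f, %.4f]\n",
              min(object@logScores), max(object@logScores)))
  ar <- acceptanceRates(object)
  cat(sprintf("  acceptance: %s\n",
              paste(sprintf("t=%d %.3f", ar$t, ar$rate), collapse = ", ")))
})

setMethod("show", "DagDistribution", function(object) {
  cat(sprintf("DagDistribution: %d DAGs on %d nodes\n", sampleSize(object),
              nNodes(object)))
})

setMethod("show", "EdgePosteriorMatrix", function(object) {
  cat(sprintf("EdgePosteriorMatrix: %d x %d\n", nrow(object@probs),
              ncol(object@probs)))
  print(round(object@probs, 3))
})

setMethod("show", "GroundTruthBN", function(object) {
  cat(sprintf("GroundTruthBN: %d nodes, %d edges, arities %s\n",
              nNodes(object), edgeCount(object@structure),
              paste(object@arities, collapse = ",")))
})
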