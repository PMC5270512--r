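# Ground-truth network and data generators. These emulate the study designs
# the sampler is exercised on: random discrete networks, ancestral
# (observational) sampling, single-node interventions, and pooled data from
# two different networks (the deliberately misspecified, multimodal case).

#' Random DAG
#'
#' Draws a uniform topological order, then includes each order-compatible
#' edge independently with probability `edgeDensity`, skipping edges that
#' would push a child past the fan-in cap (children are scanned in order,
#' parents in order within each child).
#'
#' @param n node count.
#' @param edgeDensity inclusion probability in [0, 1] (default 0.3).
#' @param maxFanin fan-in cap, `Inf` for unlimited.
#' @param labels optional node labels.
#' @return a [DagStructure-class].
#' @export
randomDag <- function(n, edgeDensity = 0.3, maxFanin = Inf, labels = NULL) {
  if (edgeDensity < 0 || edgeDensity > 1) stop("edgeDensity must be in [0, 1]")
  ord <- sample.int(n)
  a <- matrix(0L, n, n)
  for (k in seq_len(n)[-1]) {
    child <- ord[k]
    nPar <- 0L
    for (j in seq_len(k - 1L)) {
      if (nPar >= maxFanin) break
      if (runif(1) < edgeDensity) {
        a[ord[j], child] <- 1L
        nPar <- nPar + 1L
      }
    }
  }
  if (is.null(labels)) labels <- .defaultLabels(n)
  new("DagStructure", adjacency = a, labels = as.character(labels))
}

.parentConfigIndex <- function(values, parents, arities) {
  # mixed-radix index over ascending parents, first parent most significant;
  # matches the C++ scorer and the CPT row convention. 1-based.
  idx <- rep(0, nrow(values))
  for (p in parents) idx <- idx * arities[p] + values[, p]
  idx + 1
}

#' Random conditional probability tables
#'
#' Each conditional distribution (one CPT row per parent configuration) is
#' drawn from a symmetric Dirichlet with the given concentration; small
#' concentrations give peaky (near-deterministic) tables, large ones give
#' near-uniform tables. Entries are strictly positive, so every DAG has
#' positive marginal likelihood — the positivity the ergodicity argument
#' assumes.
#'
#' @param structure a [DagStructure-class].
#' @param arities per-node category counts (>= 2); a single value is
#'   recycled. Default 3 throughout the package.
#' @param concentration positive Dirichlet concentration (default 0.5).
#' @return a [GroundTruthBN-class].
#' @export
randomCpts <- function(structure, arities = 3, concentration = 0.5) {
  if (concentration <= 0) stop("concentration must be positive")
  n <- nNodes(structure)
  arities <- as.integer(rep(arities, length.out = n))
  if (any(arities < 2)) stop("arities must be >= 2")
  cpts <- vector("list", n)
  for (v in seq_len(n)) {
    pa <- which(structure@adjacency[, v] == 1L)
    q <- prod(arities[pa])
    g <- matrix(rgamma(q * arities[v], shape = concentration), q, arities[v])
    g[g < .Machine$double.xmin] <- .Machine$double.xmin
    cpts[[v]] <- g / rowSums(g)
  }
  new("GroundTruthBN", structure = structure, arities = arities, cpts = cpts)
}

#' @rdname randomCpts
#' @param cpts explicit list of CPT matrices (configs x arity per node).
#' @export
groundTruthBN <- function(structure, arities, cpts) {
  new("GroundTruthBN", structure = structure,
      arities = as.integer(rep(arities, length.out = nNodes(structure))),
      cpts = cpts)
}

.topoOrder <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  ord <- integer(0)
  avail <- which(indeg == 0)
  indeg[avail] <- NA
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    ord <- c(ord, v)
    for (w in which(adj[v, ] == 1L)) {
      indeg[w] <- indeg[w] - 1L
      if (!is.na(indeg[w]) && indeg[w] == 0L) { avail <- c(avail, w); indeg[w] <- NA }
    }
  }
  ord
}

.sampleNodeValues <- function(bn, values, v, rows) {
  # draw node v for the given rows, conditional on already-filled parents
  pa <- which(bn@structure@adjacency[, v] == 1L)
  tab <- bn@cpts[[v]]
  if (length(pa) == 0) {
    cfg <- rep(1L, length(rows))
  } else {
    cfg <- .parentConfigIndex(values[rows, , drop = FALSE], pa, bn@arities)
  }
  out <- integer(length(rows))
  for (c in unique(cfg)) {
    sel <- which(cfg == c)
    out[sel] <- sample.int(bn@arities[v], length(sel), replace = TRUE,
                           prob = tab[c, ]) - 1L
  }
  out
}

#' Forward (ancestral) sampling
#'
#' Draws rows in topological order from the CPTs; the intervention mask of
#' the result is all-`FALSE`.
#'
#' @param bn a [GroundTruthBN-class].
#' @param nSamples number of rows.
#' @return a [DiscreteDataset-class].
#' @export
forwardSample <- function(bn, nSamples) {
  n <- nNodes(bn)
  values <- matrix(0L, nSamples, n)
  colnames(values) <- bn@structure@labels
  if (nSamples > 0)
    for (v in .topoOrder(bn@structure@adjacency))
      values[, v] <- .sampleNodeValues(bn, values, v, seq_len(nSamples))
  discreteDataset(values, arities = bn@arities)
}

#' Interventional sampling
#'
#' A fraction of rows are perturbation experiments: in each such row one
#' node (uniformly chosen, or drawn from `targets`) is clamped to a value
#' (uniform, or `fixedValue`) and marked in the intervention mask; its
#' descendants are sampled conditional on the clamp and ancestors sample as
#' usual. With `interventionFraction = 0` this is [forwardSample()] in law.
#'
#' @param bn a [GroundTruthBN-class].
#' @param nSamples number of rows.
#' @param interventionFraction fraction of intervened rows in [0, 1].
#' @param targets optional node indices eligible for clamping.
#' @param fixedValue optional fixed clamp value (0-based code).
#' @return a [DiscreteDataset-class] with mask set on clamped cells.
#' @export
interventionalSample <- function(bn, nSamples, interventionFraction = 0.3,
                                 targets = NULL, fixedValue = NULL) {
  if (interventionFraction < 0 || interventionFraction > 1)
    stop("interventionFraction must be in [0, 1]")
  n <- nNodes(bn)
  if (is.null(targets)) targets <- seq_len(n)
  nInt <- round(interventionFraction * nSamples)
  intRows <- if (nInt > 0) sample.int(nSamples, nInt) else integer(0)
  intNode <- if (nInt > 0) targets[sample.int(length(targets), nInt,
                                              replace = TRUE)] else integer(0)
  intValue <- if (is.null(fixedValue)) {
    vapply(intNode, function(v) sample.int(bn@arities[v], 1) - 1L, integer(1))
  } else rep(as.integer(fixedValue), nInt)

  values <- matrix(0L, nSamples, n)
  colnames(values) <- bn@structure@labels
  mask <- matrix(FALSE, nSamples, n)
  if (nSamples > 0) {
    for (v in .topoOrder(bn@structure@adjacency)) {
      vals <- .sampleNodeValues(bn, values, v, seq_len(nSamples))
      clamped <- intRows[intNode == v]
      vals[clamped] <- intValue[intNode == v]
      mask[clamped, v] <- TRUE
      values[, v] <- vals
    }
  }
  discreteDataset(values, arities = bn@arities, mask = mask)
}

#' Pooled dataset from two networks
#'
#' Row-concatenates `nEach` forward samples from each of two ground-truth
#' networks over the same nodes, with no provenance column: the learner is
#' deliberately shown data no single DAG generated, which makes the
#' posterior multimodal. This is the misspecified-system scenario used to
#' compare proposal mixtures.
#'
#' @param bnA,bnB [GroundTruthBN-class] with equal node counts and arities.
#' @param nEach rows drawn from each network.
#' @return a [DiscreteDataset-class] with `2 * nEach` rows.
#' @export
combinedDataset <- function(bnA, bnB, nEach) {
  if (nNodes(bnA) != nNodes(bnB) || !all(bnA@arities == bnB@arities))
    stop("the two networks must share node count and arities")
  da <- forwardSample(bnA, nEach)
  db <- forwardSample(bnB, nEach)
  discreteDataset(rbind(da@values, db@values), arities = bnA@arities)
}

# ---------------------------------------------------------------------------
# Ground-truth BN JSON I/O
# ---------------------------------------------------------------------------

#' Read / write a ground-truth network as JSON
#'
#' The JSON object stores node labels, arities, the edge list (labels,
#' parent -> child) and per-node CPT matrices (rows = parent configurations
#' in mixed-radix order over ascending parents). Any externally published
#' network in this format (e.g. an Alarm-style benchmark) can be used in
#' place of the random generators.
#'
#' @param bn a [GroundTruthBN-class].
#' @param path file path.
#' @name bnIO
#' @export
writeGroundTruthBN <- function(bn, path) {
  e <- dagEdges(bn@structure)
  lab <- bn@structure@labels
  obj <- list(nodes = lab, arities = bn@arities,
              edges = data.frame(parent = lab[e$parent], child = lab[e$child]),
              cpts = lapply(bn@cpts, function(m) unclass(m)))
  jsonlite::write_json(obj, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname bnIO
#' @export
readGroundTruthBN <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- as.character(obj$nodes)
  n <- length(labels)
  edges <- if (!is.null(obj$edges) && NROW(obj$edges) > 0)
    cbind(obj$edges$parent, obj$edges$child) else NULL
  structure <- dagStructure(n, edges, labels = labels)
  cpts <- lapply(seq_len(n), function(v) {
    m <- obj$cpts[[v]]
    if (!is.matrix(m)) m <- matrix(m, nrow = 1)
    m
  })
  groundTruthBN(structure, as.integer(obj$arities), cpts)
}
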