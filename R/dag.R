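# DAG construction, single-edge moves and neighbourhood enumeration.

.defaultLabels <- function(n) paste0("V", seq_len(n))

#' Construct a DAG structure
#'
#' @param nNodes number of nodes.
#' @param edges optional edge set: a 2-column matrix or data.frame of
#'   (parent, child) pairs, 1-based indices or label strings.
#' @param labels optional node labels (defaults to `V1 ... Vn`).
#' @return a validated [DagStructure-class]; errors on self-edges, duplicate
#'   edges or cycles.
#' @examples
#' dagStructure(3, rbind(c(1, 2), c(2, 3)))
#' @export
dagStructure <- function(nNodes, edges = NULL, labels = NULL) {
  nNodes <- as.integer(nNodes)
  if (is.null(labels)) labels <- .defaultLabels(nNodes)
  if (length(labels) != nNodes) stop("labels length must equal nNodes")
  a <- matrix(0L, nNodes, nNodes)
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2) stop("edges must have two columns (parent, child)")
    if (is.character(edges)) {
      p <- match(edges[, 1], labels)
      k <- match(edges[, 2], labels)
      if (anyNA(p) || anyNA(k)) stop("edge labels not found among node labels")
    } else {
      p <- as.integer(edges[, 1])
      k <- as.integer(edges[, 2])
      if (anyNA(p) || anyNA(k) || any(p < 1) || any(k < 1) ||
          any(p > nNodes) || any(k > nNodes))
        stop("edge indices out of range")
    }
    if (any(p == k)) stop("self-edges are not allowed")
    if (anyDuplicated(cbind(p, k))) stop("duplicate edges")
    a[cbind(p, k)] <- 1L
  }
  new("DagStructure", adjacency = a, labels = as.character(labels))
}

#' @rdname dagStructure
#' @export
emptyDag <- function(nNodes, labels = NULL) dagStructure(nNodes, NULL, labels)

#' Build a DagStructure directly from an adjacency matrix
#' @param adjacency square 0/1 matrix (rows = parents).
#' @param labels optional node labels.
#' @export
dagFromAdjacency <- function(adjacency, labels = NULL) {
  a <- as.matrix(adjacency)
  storage.mode(a) <- "integer"
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(a))) rownames(a) else .defaultLabels(nrow(a))
  }
  dimnames(a) <- NULL
  new("DagStructure", adjacency = a, labels = as.character(labels))
}

#' Test acyclicity of a candidate edge set
#'
#' @param edges 2-column matrix/data.frame of 1-based (parent, child) pairs,
#'   or a [DagStructure-class] (trivially acyclic), or a square 0/1
#'   adjacency matrix.
#' @param nNodes required when `edges` is an edge list.
#' @return `TRUE` iff a topological order exists. Self-edges are an error.
#' @export
isAcyclic <- function(edges, nNodes = NULL) {
  if (is(edges, "DagStructure")) return(cppIsAcyclic(edges@adjacency))
  edges <- as.matrix(edges)
  if (nrow(edges) == ncol(edges) && nrow(edges) > 2 &&
      all(edges %in% c(0, 1)) && is.null(nNodes)) {
    a <- edges
  } else if (!is.null(nNodes) &&
             (NROW(edges) == 0 || ncol(edges) == 2)) {
    a <- matrix(0L, nNodes, nNodes)
    if (NROW(edges) > 0) {
      p <- as.integer(edges[, 1]); k <- as.integer(edges[, 2])
      if (any(p == k)) stop("self-edges are not allowed")
      a[cbind(p, k)] <- 1L
    }
  } else if (is.null(nNodes)) {
    a <- edges  # small square matrix
  } else {
    a <- edges
  }
  storage.mode(a) <- "integer"
  cppIsAcyclic(a)
}

#' Construct a single-edge move
#' @param kind `"addition"`, `"deletion"` or `"reversal"`.
#' @param parent,child 1-based node indices of the edge (pre-move
#'   orientation).
#' @export
edgeMove <- function(kind, parent, child) {
  new("EdgeMove", kind = as.character(kind), parent = as.integer(parent),
      child = as.integer(child))
}

.moveFields <- function(move) {
  if (is(move, "EdgeMove"))
    return(list(kind = move@kind, parent = move@parent, child = move@child))
  if (is.data.frame(move) && nrow(move) == 1)
    return(list(kind = as.character(move$kind),
                parent = as.integer(move$parent),
                child = as.integer(move$child)))
  stop("move must be an EdgeMove or a one-row data.frame(kind, parent, child)")
}

#' Apply a single-edge move to a DAG
#'
#' Returns the modified structure, leaving the input unchanged. Adding an
#' existing edge, deleting or reversing a missing one, or producing a cycle
#' is an error.
#'
#' @param dag a [DagStructure-class].
#' @param move an [EdgeMove-class] or one-row data.frame as produced by
#'   [enumerateNeighborhood()].
#' @return the new [DagStructure-class].
#' @export
applyMove <- function(dag, move) {
  m <- .moveFields(move)
  a <- dag@adjacency
  u <- m$parent; v <- m$child
  if (m$kind == "addition") {
    if (a[u, v] == 1L) stop("cannot add an existing edge")
    if (a[v, u] == 1L) stop("cannot add the reverse of an existing edge")
    a[u, v] <- 1L
  } else if (m$kind == "deletion") {
    if (a[u, v] == 0L) stop("cannot delete a missing edge")
    a[u, v] <- 0L
  } else if (m$kind == "reversal") {
    if (a[u, v] == 0L) stop("cannot reverse a missing edge")
    a[u, v] <- 0L
    a[v, u] <- 1L
  } else stop("unknown move kind")
  if (!cppIsAcyclic(a)) stop("move would create a directed cycle")
  new("DagStructure", adjacency = a, labels = dag@labels)
}

.kindNames <- c("addition", "deletion", "reversal")

#' Enumerate the one-step neighbourhood of a DAG
#'
#' All single-edge modifications (addition, deletion, reversal) whose result
#' is acyclic and whose child gaining a parent stays within the fan-in cap.
#' Deletions are always admissible, which keeps the neighbourhood relation
#' symmetric. Moves are returned in a deterministic order (kind, then
#' parent, then child) so that uniform sampling is reproducible.
#'
#' @param dag a [DagStructure-class].
#' @param maxFanin fan-in cap, `Inf` for unlimited.
#' @return data.frame with columns `kind`, `parent`, `child`.
#' @examples
#' enumerateNeighborhood(emptyDag(3))  # 6 additions
#' @export
enumerateNeighborhood <- function(dag, maxFanin = Inf) {
  m <- cppEnumerateMoves(dag@adjacency, .faninInt(maxFanin))
  data.frame(kind = .kindNames[m[, 1]], parent = m[, 2] + 1L,
             child = m[, 3] + 1L, stringsAsFactors = FALSE)
}

#' Neighbourhood size q(G)
#'
#' The number of DAGs reachable from `dag` by one admissible single-edge
#' modification — the quantity whose endpoint ratio forms the Hastings
#' correction of the multi-step proposal.
#'
#' @inheritParams enumerateNeighborhood
#' @return integer count, equal to `nrow(enumerateNeighborhood(dag, maxFanin))`.
#' @export
neighborhoodSize <- function(dag, maxFanin = Inf) {
  cppNeighborhoodSize(dag@adjacency, .faninInt(maxFanin))
}

#' Canonical key of a DAG
#'
#' A string identifying the edge set; two DAGs are equal iff their keys are
#' equal. Used for unique-DAG counting and route identification.
#' @param dag a [DagStructure-class].
#' @export
dagKey <- function(dag) paste(dag@adjacency, collapse = "")

# ---------------------------------------------------------------------------
# DAG file I/O
# ---------------------------------------------------------------------------

#' Read / write DAG files
#'
#' Edge-list files are tab-separated `parent<TAB>child` pairs (header
#' optional; labels or 1-based indices). Adjacency files are square 0/1 CSV
#' with rows = parents. `writeDot()` emits Graphviz DOT for visualisation.
#'
#' @param path file path.
#' @param nNodes,labels node count / labels when the edge list alone does
#'   not determine them.
#' @param dag a [DagStructure-class].
#' @return the read [DagStructure-class], or (invisibly) `path` for writers.
#' @name dagIO
NULL

#' @rdname dagIO
#' @export
readDagEdgeList <- function(path, nNodes = NULL, labels = NULL) {
  first <- readLines(path, n = 1L)
  hasHeader <- length(first) == 1L &&
    identical(strsplit(first, "\t")[[1]], c("parent", "child"))
  tab <- read.table(path, sep = "\t", header = hasHeader,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("edge list must have two columns")
  ints <- suppressWarnings(!anyNA(as.integer(tab[[1]])) &&
                             !anyNA(as.integer(tab[[2]])))
  if (ints) {
    p <- as.integer(tab[[1]]); k <- as.integer(tab[[2]])
    if (is.null(nNodes))
      nNodes <- if (!is.null(labels)) length(labels) else max(p, k)
    dagStructure(nNodes, cbind(p, k), labels = labels)
  } else {
    if (is.null(labels)) labels <- sort(unique(c(tab[[1]], tab[[2]])))
    dagStructure(length(labels), cbind(tab[[1]], tab[[2]]), labels = labels)
  }
}

#' @rdname dagIO
#' @export
writeDagEdgeList <- function(dag, path) {
  e <- dagEdges(dag)
  lab <- dag@labels
  write.table(data.frame(parent = lab[e$parent], child = lab[e$child]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dagIO
#' @export
readDagAdjacency <- function(path) {
  a <- as.matrix(read.table(path, sep = ",", header = FALSE))
  if (nrow(a) != ncol(a)) stop("adjacency file must be square")
  dagFromAdjacency(a)
}

#' @rdname dagIO
#' @export
writeDagAdjacency <- function(dag, path) {
  write.table(dag@adjacency, path, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname dagIO
#' @export
writeDot <- function(dag, path) {
  e <- dagEdges(dag)
  lab <- gsub('"', "'", dag@labels)
  lines <- c("digraph G {",
             paste0('  "', lab, '";'),
             if (nrow(e) > 0)
               paste0('  "', lab[e$parent], '" -> "', lab[e$child], '";'),
             "}")
  writeLines(lines, path)
  invisible(path)
}
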