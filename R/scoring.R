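# BDeu (Dirichlet-multinomial) marginal likelihood with intervention-aware
# counts. All computation is in log space via lgamma; the per-(child,
# parent-set) cache lives inside the C++ scorer for chain runs, and the
# R-level functions below rescore directly (they are cheap at API scale).

#' Construct a discrete dataset
#'
#' @param values samples x variables matrix (or data.frame) of non-negative
#'   integer codes `0 ... arity - 1`.
#' @param arities optional per-variable category counts; inferred as
#'   `max(code) + 1` (at least 2) when missing.
#' @param mask optional same-shape logical/0-1 matrix; `TRUE` marks a value
#'   clamped by an intervention.
#' @return a [DiscreteDataset-class].
#' @export
discreteDataset <- function(values, arities = NULL, mask = NULL) {
  v <- as.matrix(values)
  storage.mode(v) <- "integer"
  if (is.null(arities)) {
    arities <- if (nrow(v) > 0)
      pmax(apply(v, 2, max) + 1L, 2L)
    else rep(2L, ncol(v))
  }
  if (is.null(mask)) {
    m <- matrix(logical(0), 0, 0)
  } else {
    m <- as.matrix(mask)
    storage.mode(m) <- "logical"
  }
  new("DiscreteDataset", values = v, arities = as.integer(arities), mask = m)
}

#' @rdname discreteDataset
#' @param x a [DiscreteDataset-class].
#' @export
nVariables <- function(x) ncol(x@values)

#' @rdname discreteDataset
#' @export
nSamples <- function(x) nrow(x@values)

#' @rdname discreteDataset
#' @export
arities <- function(x) x@arities

#' @rdname discreteDataset
#' @export
hasInterventions <- function(x) length(x@mask) > 0 && any(x@mask)

#' @rdname discreteDataset
#' @export
interventionMask <- function(x) {
  if (length(x@mask) > 0) x@mask
  else matrix(FALSE, nrow(x@values), ncol(x@values))
}

#' Scoring settings
#'
#' @param ess equivalent sample size of the BDeu prior: the Dirichlet
#'   hyperparameter for each cell of a family table is
#'   `ess / (arity(child) * #parent configurations)`. Default 1.
#' @param logPrior optional structure-prior hook, a function mapping a
#'   [DagStructure-class] to a log prior value; `NULL` means the uniform
#'   prior over DAGs passing the fan-in cap.
#' @return a [ScoreSettings-class].
#' @export
scoreSettings <- function(ess = 1, logPrior = NULL) {
  new("ScoreSettings", ess = as.numeric(ess), logPrior = logPrior)
}

.checkNodes <- function(nodes, n) {
  nodes <- as.integer(nodes)
  if (anyNA(nodes) || any(nodes < 1L) || any(nodes > n))
    stop("node index out of range")
  nodes
}

#' Family log marginal likelihood
#'
#' Log of the Dirichlet-multinomial marginal of `child`'s column given the
#' configurations of `parents`, under BDeu hyperparameters. Samples whose
#' child value is intervention-masked are excluded from this family's
#' counts. A family with no unmasked samples scores 0 (the empty product).
#'
#' @param child child node index (1-based).
#' @param parents integer vector of parent indices (may be empty).
#' @param dataset a [DiscreteDataset-class].
#' @param settings a [ScoreSettings-class].
#' @return finite log probability.
#' @export
familyLogScore <- function(child, parents, dataset,
                           settings = scoreSettings()) {
  n <- nVariables(dataset)
  child <- .checkNodes(child, n)
  parents <- if (length(parents)) .checkNodes(parents, n) else integer(0)
  if (child %in% parents) stop("parents must exclude the child")
  cppFamilyLogScore(child - 1L, parents - 1L, dataset@values,
                    dataset@arities, .maskOrNull(dataset), settings@ess)
}

#' Graph log marginal likelihood
#'
#' Sum of [familyLogScore()] over all nodes (score decomposability).
#'
#' @param dag a [DagStructure-class] whose nodes match the dataset columns.
#' @inheritParams familyLogScore
#' @export
graphLogScore <- function(dag, dataset, settings = scoreSettings()) {
  if (nNodes(dag) != nVariables(dataset))
    stop("DAG node count does not match dataset variable count")
  cppGraphLogScore(dag@adjacency, dataset@values, dataset@arities,
                   .maskOrNull(dataset), settings@ess)
}

#' Log-score difference of a single-edge move
#'
#' Equals `graphLogScore(applyMove(dag, move)) - graphLogScore(dag)` but
#' rescores only the affected families: the child family for an addition or
#' deletion, both endpoint families for a reversal.
#'
#' @param dag a [DagStructure-class].
#' @param move an [EdgeMove-class] or one-row data.frame.
#' @inheritParams familyLogScore
#' @export
deltaLogScore <- function(dag, move, dataset, settings = scoreSettings()) {
  m <- .moveFields(move)
  a <- dag@adjacency
  kind <- match(m$kind, .kindNames)
  if (kind == 1 && a[m$parent, m$child] == 1L) stop("edge already present")
  if (kind != 1 && a[m$parent, m$child] == 0L) stop("edge not present")
  cppDeltaLogScore(dag@adjacency, kind, m$parent - 1L, m$child - 1L,
                   dataset@values, dataset@arities, .maskOrNull(dataset),
                   settings@ess)
}

.logPriorOf <- function(settings, dag) {
  if (is.null(settings@logPrior)) 0 else settings@logPrior(dag)
}
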