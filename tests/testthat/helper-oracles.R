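# Independent oracles used across the suite. These deliberately avoid the
# package's own acyclicity / neighbourhood code paths: acyclicity goes
# through igraph, counts through brute-force apply-and-check or closed-form
# recurrences.

oracleAcyclic <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  igraph::is_dag(g)
}

# Brute-force one-step neighbourhood: try every candidate single-edge
# modification, keep those whose result is acyclic (per igraph) and whose
# fan-in constraint holds for the child gaining a parent.
oracleNeighborhood <- function(dag, maxFanin = Inf) {
  a <- adjacency(dag)
  dimnames(a) <- NULL
  n <- nrow(a)
  keep <- list()
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u == v) next
    if (a[u, v] == 0 && a[v, u] == 0) {           # addition
      b <- a; b[u, v] <- 1L
      if (sum(b[, v]) <= maxFanin && oracleAcyclic(b))
        keep[[length(keep) + 1]] <- c("addition", u, v)
    }
    if (a[u, v] == 1) {                            # deletion
      keep[[length(keep) + 1]] <- c("deletion", u, v)
      b <- a; b[u, v] <- 0L; b[v, u] <- 1L         # reversal
      if (sum(b[, u]) <= maxFanin && oracleAcyclic(b))
        keep[[length(keep) + 1]] <- c("reversal", u, v)
    }
  }
  df <- as.data.frame(do.call(rbind, c(keep, list(c("x", 0, 0)))),
                      stringsAsFactors = FALSE)[seq_along(keep), , drop = FALSE]
  names(df) <- c("kind", "parent", "child")
  df$parent <- as.integer(df$parent); df$child <- as.integer(df$child)
  df[order(df$kind, df$parent, df$child), , drop = FALSE]
}

# Robinson's recurrence for the number of labelled DAGs on n nodes:
# a_n = sum_{k=1..n} (-1)^(k+1) C(n,k) 2^{k(n-k)} a_{n-k}, a_0 = 1.
oracleDagCount <- function(n) {
  a <- c(1, rep(NA_real_, n))
  for (m in seq_len(n)) {
    s <- 0
    for (k in seq_len(m))
      s <- s + (-1)^(k + 1) * choose(m, k) * 2^(k * (m - k)) * a[m - k + 1]
    a[m + 1] <- s
  }
  a[n + 1]
}

# All DAGs on n nodes by filtering every subset of ordered pairs (test-time
# cross-check of the production enumerator; n <= 4 only).
oracleEnumerateDags <- function(n, maxFanin = Inf) {
  pairs <- which(diag(n) == 0, arr.ind = TRUE)
  m <- nrow(pairs)  # n(n-1) ordered pairs
  count <- 0L
  for (code in 0:(2^m - 1)) {
    sel <- which(bitwAnd(code, 2^(seq_len(m) - 1)) > 0)
    a <- matrix(0L, n, n)
    a[pairs[sel, , drop = FALSE]] <- 1L
    if (any(colSums(a) > maxFanin)) next
    if (oracleAcyclic(a)) count <- count + 1L
  }
  count
}

# Exhaustive enumeration of all length-t routes between two DAGs, with the
# per-route probability 1/(q1 * ... * qt); returns total Q^t(to | from)
# given p_t = 1 for this t. Used to check the telescoping Hastings ratio.
oracleRouteProbability <- function(from, to, t, maxFanin = Inf) {
  rec <- function(cur, depth, logp) {
    moves <- enumerateNeighborhood(cur, maxFanin)
    q <- nrow(moves)
    if (depth == t) {
      tot <- 0
      for (i in seq_len(q)) {
        nxt <- applyMove(cur, moves[i, ])
        if (nxt == to) tot <- tot + exp(logp - log(q))
      }
      return(tot)
    }
    tot <- 0
    for (i in seq_len(q))
      tot <- tot + rec(applyMove(cur, moves[i, ]), depth + 1, logp - log(q))
    tot
  }
  rec(from, 1, 0)
}

# skeleton + v-structures: the Markov equivalence class fingerprint
oracleEquivalenceKey <- function(dag) {
  a <- adjacency(dag)
  dimnames(a) <- NULL
  n <- nrow(a)
  skel <- (a + t(a)) > 0
  vkeys <- character(0)
  for (v in seq_len(n)) {
    pa <- which(a[, v] == 1)
    if (length(pa) >= 2) {
      cmb <- combn(pa, 2)
      for (j in seq_len(ncol(cmb))) {
        x <- cmb[1, j]; y <- cmb[2, j]
        if (!skel[x, y]) vkeys <- c(vkeys, paste(x, v, y, sep = "-"))
      }
    }
  }
  paste(paste(which(skel & upper.tri(skel)), collapse = ","),
        paste(sort(vkeys), collapse = ";"), sep = "|")
}

meanPairwiseSSD <- function(samples) {
  ep <- lapply(samples, edgePosteriors)
  pr <- combn(length(ep), 2)
  mean(apply(pr, 2, function(p) edgePosteriorSSD(ep[[p[1]]], ep[[p[2]]])))
}

# a small fixed 3-node binary ground truth used by several files
toyBn3 <- function(seed = 1) {
  set.seed(seed)
  dag <- dagStructure(3, rbind(c(1, 2), c(2, 3)))
  randomCpts(dag, arities = 2, concentration = 0.5)
}
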