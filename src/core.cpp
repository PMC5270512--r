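#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <array>
#include <string>
#include <cmath>

using namespace Rcpp;

// Adjacency is held as a flat row-major 0/1 vector: adj[u * n + v] == 1 iff
// there is an edge u -> v (u = parent, v = child). Node indices are 0-based
// inside this file; the R layer is 1-based and converts at the boundary.

typedef std::vector<int> Adj;

static Adj asAdj(const IntegerMatrix& m) {
  int n = m.nrow();
  Adj a((size_t)n * n, 0);
  for (int u = 0; u < n; ++u)
    for (int v = 0; v < n; ++v)
      a[(size_t)u * n + v] = m(u, v) != 0;
  return a;
}

static IntegerMatrix asMatrix(const Adj& a, int n) {
  IntegerMatrix m(n, n);
  for (int u = 0; u < n; ++u)
    for (int v = 0; v < n; ++v)
      m(u, v) = a[(size_t)u * n + v];
  return m;
}

// DFS reachability from -> to, optionally ignoring the single edge
// (skipU, skipV). Used for incremental acyclicity: adding u->v creates a
// cycle iff v already reaches u; reversing u->v creates one iff u reaches v
// through some path other than the edge itself.
static bool reaches(const Adj& adj, int n, int from, int to,
                    int skipU = -1, int skipV = -1) {
  if (from == to) return true;
  std::vector<char> vis((size_t)n, 0);
  std::vector<int> stack;
  stack.push_back(from);
  vis[from] = 1;
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    const int* row = adj.data() + (size_t)u * n;
    for (int v = 0; v < n; ++v) {
      if (!row[v]) continue;
      if (u == skipU && v == skipV) continue;
      if (v == to) return true;
      if (!vis[v]) { vis[v] = 1; stack.push_back(v); }
    }
  }
  return false;
}

static bool acyclicKahn(const Adj& adj, int n) {
  std::vector<int> indeg(n, 0);
  for (int u = 0; u < n; ++u)
    for (int v = 0; v < n; ++v)
      indeg[v] += adj[(size_t)u * n + v];
  std::vector<int> stack;
  for (int v = 0; v < n; ++v) if (indeg[v] == 0) stack.push_back(v);
  int removed = 0;
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    ++removed;
    for (int v = 0; v < n; ++v) {
      if (adj[(size_t)u * n + v] && --indeg[v] == 0) stack.push_back(v);
    }
  }
  return removed == n;
}

// Move kinds: 1 = addition, 2 = deletion, 3 = reversal.
struct Move { int kind, u, v; };

// Enumerate the one-step neighbourhood in a fixed deterministic order
// (kind, then parent, then child, all ascending). A move is admissible iff
// the result is acyclic and the child gaining a parent stays within the
// fan-in cap; deletions are always admissible. This keeps the neighbourhood
// relation symmetric, which the endpoint-ratio Hastings correction requires.
static void enumMoves(const Adj& adj, int n, int fanin,
                      std::vector<Move>& out) {
  out.clear();
  std::vector<int> indeg(n, 0);
  for (int u = 0; u < n; ++u)
    for (int v = 0; v < n; ++v)
      indeg[v] += adj[(size_t)u * n + v];
  for (int u = 0; u < n; ++u) {
    for (int v = 0; v < n; ++v) {
      if (u == v) continue;
      if (adj[(size_t)u * n + v] || adj[(size_t)v * n + u]) continue;
      if (indeg[v] + 1 > fanin) continue;
      if (reaches(adj, n, v, u)) continue;
      out.push_back({1, u, v});
    }
  }
  for (int u = 0; u < n; ++u)
    for (int v = 0; v < n; ++v)
      if (adj[(size_t)u * n + v]) out.push_back({2, u, v});
  for (int u = 0; u < n; ++u) {
    for (int v = 0; v < n; ++v) {
      if (!adj[(size_t)u * n + v]) continue;
      if (indeg[u] + 1 > fanin) continue;
      if (reaches(adj, n, u, v, u, v)) continue;
      out.push_back({3, u, v});
    }
  }
}

static void applyMoveInPlace(Adj& adj, int n, const Move& m) {
  if (m.kind == 1) {
    adj[(size_t)m.u * n + m.v] = 1;
  } else if (m.kind == 2) {
    adj[(size_t)m.u * n + m.v] = 0;
  } else {
    adj[(size_t)m.u * n + m.v] = 0;
    adj[(size_t)m.v * n + m.u] = 1;
  }
}

// ---------------------------------------------------------------------------
// BDeu scoring
// ---------------------------------------------------------------------------

// Dirichlet-multinomial (BDeu) family scorer over integer-coded data with an
// optional intervention mask: a sample whose child value was clamped is
// excluded from that child's own family counts (it still conditions its
// children through their parent configurations). Scores are cached per
// (child, parent set).
struct Scorer {
  const int* data;   // N x n, column-major (column = variable)
  const int* mask;   // same shape, 0/1, or NULL
  int N, n;
  std::vector<int> arity;
  double ess;
  std::unordered_map<std::string, double> cache;

  double familyCached(int child, const std::vector<int>& parents) {
    std::string key(1, (char)child);
    for (size_t i = 0; i < parents.size(); ++i)
      key.push_back((char)parents[i]);
    std::unordered_map<std::string, double>::iterator it = cache.find(key);
    if (it != cache.end()) return it->second;
    double s = familyRaw(child, parents);
    cache.emplace(std::move(key), s);
    return s;
  }

  double familyRaw(int child, const std::vector<int>& parents) const {
    long long q = 1;
    for (size_t i = 0; i < parents.size(); ++i) {
      q *= arity[parents[i]];
      if (q > (1LL << 22))
        stop("parent configuration table too large; use a fan-in cap");
    }
    int r = arity[child];
    long long cells = q * r;
    std::vector<double> cnt((size_t)cells, 0.0);
    const int* dc = data + (long long)N * child;
    const int* mc = mask ? mask + (long long)N * child : (const int*)0;
    for (int i = 0; i < N; ++i) {
      if (mc && mc[i]) continue;
      long long idx = 0;
      for (size_t j = 0; j < parents.size(); ++j) {
        int p = parents[j];
        idx = idx * arity[p] + data[(long long)N * p + i];
      }
      cnt[(size_t)(idx * r + dc[i])] += 1.0;
    }
    double aij = ess / (double)q;
    double aijk = ess / (double)cells;
    double lgAij = std::lgamma(aij), lgAijk = std::lgamma(aijk);
    double s = 0.0;
    for (long long j = 0; j < q; ++j) {
      double Nij = 0.0;
      for (int k = 0; k < r; ++k) Nij += cnt[(size_t)(j * r + k)];
      if (Nij == 0.0) continue;
      s += lgAij - std::lgamma(aij + Nij);
      for (int k = 0; k < r; ++k) {
        double c = cnt[(size_t)(j * r + k)];
        if (c > 0.0) s += std::lgamma(aijk + c) - lgAijk;
      }
    }
    return s;
  }

  std::vector<int> parentsOf(const Adj& adj, int v) const {
    std::vector<int> p;
    for (int u = 0; u < n; ++u)
      if (adj[(size_t)u * n + v]) p.push_back(u);
    return p;  // ascending: canonical cache key
  }

  double graph(const Adj& adj) {
    double s = 0.0;
    for (int v = 0; v < n; ++v) s += familyCached(v, parentsOf(adj, v));
    return s;
  }
};

static Scorer makeScorer(const IntegerMatrix& data,
                         const IntegerVector& arities,
                         const Nullable<IntegerMatrix>& mask,
                         double ess) {
  Scorer sc;
  sc.N = data.nrow();
  sc.n = data.ncol();
  sc.data = sc.N > 0 ? &data[0] : (const int*)0;
  sc.mask = (const int*)0;
  if (mask.isNotNull()) {
    IntegerMatrix m(mask);
    if (m.nrow() != sc.N || m.ncol() != sc.n)
      stop("intervention mask shape does not match data");
    sc.mask = sc.N > 0 ? &m[0] : (const int*)0;
  }
  sc.arity = std::vector<int>(arities.begin(), arities.end());
  sc.ess = ess;
  return sc;
}

// ---------------------------------------------------------------------------
// Exported primitives
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
bool cppIsAcyclic(IntegerMatrix adj) {
  int n = adj.nrow();
  for (int v = 0; v < n; ++v)
    if (adj(v, v) != 0) stop("self-edge present");
  Adj a = asAdj(adj);
  return acyclicKahn(a, n);
}

// [[Rcpp::export]]
IntegerMatrix cppEnumerateMoves(IntegerMatrix adj, int maxFanin) {
  int n = adj.nrow();
  Adj a = asAdj(adj);
  std::vector<Move> mv;
  enumMoves(a, n, maxFanin, mv);
  IntegerMatrix out((int)mv.size(), 3);
  for (size_t i = 0; i < mv.size(); ++i) {
    out(i, 0) = mv[i].kind;
    out(i, 1) = mv[i].u;
    out(i, 2) = mv[i].v;
  }
  return out;
}

// [[Rcpp::export]]
int cppNeighborhoodSize(IntegerMatrix adj, int maxFanin) {
  int n = adj.nrow();
  Adj a = asAdj(adj);
  std::vector<Move> mv;
  enumMoves(a, n, maxFanin, mv);
  return (int)mv.size();
}

// [[Rcpp::export]]
double cppFamilyLogScore(int child, IntegerVector parents, IntegerMatrix data,
                         IntegerVector arities, Nullable<IntegerMatrix> mask,
                         double ess) {
  Scorer sc = makeScorer(data, arities, mask, ess);
  std::vector<int> p(parents.begin(), parents.end());
  std::sort(p.begin(), p.end());
  return sc.familyRaw(child, p);
}

// [[Rcpp::export]]
double cppGraphLogScore(IntegerMatrix adj, IntegerMatrix data,
                        IntegerVector arities, Nullable<IntegerMatrix> mask,
                        double ess) {
  Scorer sc = makeScorer(data, arities, mask, ess);
  Adj a = asAdj(adj);
  return sc.graph(a);
}

// Rescores only the affected families: one for addition/deletion, the two
// endpoint families for reversal.
// [[Rcpp::export]]
double cppDeltaLogScore(IntegerMatrix adj, int kind, int u, int v,
                        IntegerMatrix data, IntegerVector arities,
                        Nullable<IntegerMatrix> mask, double ess) {
  Scorer sc = makeScorer(data, arities, mask, ess);
  int n = adj.nrow();
  Adj a = asAdj(adj);
  std::vector<int> pv = sc.parentsOf(a, v);
  double d = 0.0;
  if (kind == 1) {
    std::vector<int> pv2 = pv;
    pv2.insert(std::lower_bound(pv2.begin(), pv2.end(), u), u);
    d = sc.familyRaw(v, pv2) - sc.familyRaw(v, pv);
  } else if (kind == 2) {
    std::vector<int> pv2;
    for (size_t i = 0; i < pv.size(); ++i) if (pv[i] != u) pv2.push_back(pv[i]);
    d = sc.familyRaw(v, pv2) - sc.familyRaw(v, pv);
  } else {
    std::vector<int> pv2;
    for (size_t i = 0; i < pv.size(); ++i) if (pv[i] != u) pv2.push_back(pv[i]);
    std::vector<int> pu = sc.parentsOf(a, u);
    std::vector<int> pu2 = pu;
    pu2.insert(std::lower_bound(pu2.begin(), pu2.end(), v), v);
    d = sc.familyRaw(v, pv2) - sc.familyRaw(v, pv) +
        sc.familyRaw(u, pu2) - sc.familyRaw(u, pu);
  }
  return d;
}

// ---------------------------------------------------------------------------
// Proposal machinery
// ---------------------------------------------------------------------------

static int drawLength(const NumericVector& p) {
  double u = unif_rand(), acc = 0.0;
  for (int t = 0; t < p.size(); ++t) {
    acc += p[t];
    if (u < acc) return t + 1;
  }
  return (int)p.size();
}

// Sample one multi-step transition. RNG consumption order per call:
// the length draw, then one uniform draw per sub-step.
// [[Rcpp::export]]
List cppSampleTransition(IntegerMatrix adj, NumericVector lengthProbs,
                         int maxFanin) {
  int n = adj.nrow();
  Adj cur = asAdj(adj);
  int t = drawLength(lengthProbs);
  IntegerMatrix moves(t, 3);
  IntegerVector qvals(t);
  std::vector<Move> mv;
  for (int s = 0; s < t; ++s) {
    enumMoves(cur, n, maxFanin, mv);
    int q = (int)mv.size();
    if (q == 0) stop("empty neighbourhood: no admissible single-edge move");
    int pick = (int)(unif_rand() * q);
    if (pick >= q) pick = q - 1;
    const Move& m = mv[pick];
    moves(s, 0) = m.kind;
    moves(s, 1) = m.u;
    moves(s, 2) = m.v;
    qvals[s] = q;
    applyMoveInPlace(cur, n, m);
  }
  return List::create(_["t"] = t, _["moves"] = moves, _["qValues"] = qvals,
                      _["end"] = asMatrix(cur, n));
}

// Monte-Carlo estimate support for the proposal distribution: count how many
// of nsim sampled transitions from `adj` end exactly at `target`.
// [[Rcpp::export]]
int cppCountProposalsTo(IntegerMatrix adj, IntegerMatrix target,
                        NumericVector lengthProbs, int maxFanin, int nsim) {
  int n = adj.nrow();
  Adj start = asAdj(adj), tgt = asAdj(target);
  std::vector<Move> mv;
  int hits = 0;
  for (int i = 0; i < nsim; ++i) {
    Adj cur = start;
    int t = drawLength(lengthProbs);
    bool ok = true;
    for (int s = 0; s < t; ++s) {
      enumMoves(cur, n, maxFanin, mv);
      int q = (int)mv.size();
      if (q == 0) { ok = false; break; }
      int pick = (int)(unif_rand() * q);
      if (pick >= q) pick = q - 1;
      applyMoveInPlace(cur, n, mv[pick]);
    }
    if (ok && cur == tgt) ++hits;
  }
  return hits;
}

// ---------------------------------------------------------------------------
// Metropolis-Hastings chain
// ---------------------------------------------------------------------------

// One chain. RNG consumption order per iteration: length draw, one draw per
// sub-step, then the acceptance draw (always consumed, for replayability).
// Acceptance uses the endpoint neighbourhood-size ratio q(start)/q(end) as
// the Hastings correction; useHastings = FALSE is a negative-control switch
// that sets the correction to 1 and deliberately biases the chain.
// [[Rcpp::export]]
List cppRunChain(IntegerMatrix adj0, IntegerMatrix data, IntegerVector arities,
                 Nullable<IntegerMatrix> mask, double ess,
                 NumericVector lengthProbs, int maxFanin,
                 int burnIn, int sampleSize, int thin, bool useHastings) {
  int n = adj0.nrow();
  Scorer sc = makeScorer(data, arities, mask, ess);
  if (sc.n != n) stop("dataset variable count does not match DAG node count");
  Adj cur = asAdj(adj0);
  if (!acyclicKahn(cur, n)) stop("initial DAG is cyclic");
  double curScore = sc.graph(cur);

  int maxT = lengthProbs.size();
  IntegerVector acceptCounts(maxT), proposalCounts(maxT);
  int nKeep = sampleSize / thin;
  RawMatrix states(nKeep, n * n);
  NumericVector logScores(nKeep);
  std::vector<Move> mv;
  long long total = (long long)burnIn + sampleSize;
  int kept = 0;

  for (long long iter = 1; iter <= total; ++iter) {
    int t = drawLength(lengthProbs);
    Adj prop = cur;
    int qStart = -1;
    bool ok = true;
    for (int s = 0; s < t; ++s) {
      enumMoves(prop, n, maxFanin, mv);
      int q = (int)mv.size();
      if (s == 0) qStart = q;
      if (q == 0) { ok = false; break; }
      int pick = (int)(unif_rand() * q);
      if (pick >= q) pick = q - 1;
      applyMoveInPlace(prop, n, mv[pick]);
    }
    if (!ok) stop("empty neighbourhood encountered (single-node graph?)");
    enumMoves(prop, n, maxFanin, mv);
    int qEnd = (int)mv.size();
    double propScore = sc.graph(prop);
    double logAlpha = propScore - curScore;
    if (useHastings) logAlpha += std::log((double)qStart) - std::log((double)qEnd);
    double uAcc = unif_rand();
    proposalCounts[t - 1] += 1;
    if (std::log(uAcc) < logAlpha) {
      cur = prop;
      curScore = propScore;
      acceptCounts[t - 1] += 1;
    }
    if (iter > burnIn) {
      long long k = iter - burnIn;
      if (k % thin == 0 && kept < nKeep) {
        for (int j = 0; j < n * n; ++j)
          states(kept, j) = (Rbyte)cur[(size_t)j];
        logScores[kept] = curScore;
        ++kept;
      }
    }
    if (iter % 8192 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["states"] = states, _["logScores"] = logScores,
                      _["acceptCounts"] = acceptCounts,
                      _["proposalCounts"] = proposalCounts,
                      _["finalAdj"] = asMatrix(cur, n),
                      _["finalLogScore"] = curScore);
}

// ---------------------------------------------------------------------------
// Exhaustive DAG enumeration (small n)
// ---------------------------------------------------------------------------

static void enumRec(int n, int fanin, int k, std::vector<int>& ord,
                    std::vector<char>& placed, Adj& adj,
                    std::unordered_set<std::string>& seen,
                    std::vector<std::string>& out) {
  if (k == n) {
    std::string key((const char*)adj.data(), 0);
    key.resize((size_t)n * n);
    for (size_t i = 0; i < (size_t)n * n; ++i) key[i] = (char)adj[i];
    if (seen.insert(key).second) out.push_back(key);
    return;
  }
  for (int v = 0; v < n; ++v) {
    if (placed[v]) continue;
    placed[v] = 1;
    ord[k] = v;
    // all parent subsets of the already-placed nodes, within the fan-in cap
    int nSub = 1 << k;
    for (int sub = 0; sub < nSub; ++sub) {
      int sz = 0;
      for (int b = 0; b < k; ++b) if (sub & (1 << b)) ++sz;
      if (sz > fanin) continue;
      for (int b = 0; b < k; ++b)
        if (sub & (1 << b)) adj[(size_t)ord[b] * n + v] = 1;
      enumRec(n, fanin, k + 1, ord, placed, adj, seen, out);
      for (int b = 0; b < k; ++b)
        if (sub & (1 << b)) adj[(size_t)ord[b] * n + v] = 0;
    }
    placed[v] = 0;
  }
}

// All DAGs on n labelled nodes (n <= 6), one row per DAG, row = flattened
// row-major adjacency. Generation is order-recursive with canonical-key
// deduplication (each DAG is reached once per linear extension).
// [[Rcpp::export]]
RawMatrix cppEnumerateDags(int n, int maxFanin) {
  if (n < 1 || n > 6) stop("exhaustive enumeration is limited to 1 <= n <= 6");
  std::vector<int> ord(n, 0);
  std::vector<char> placed(n, 0);
  Adj adj((size_t)n * n, 0);
  std::unordered_set<std::string> seen;
  std::vector<std::string> out;
  enumRec(n, maxFanin, 0, ord, placed, adj, seen, out);
  RawMatrix m((int)out.size(), n * n);
  for (size_t i = 0; i < out.size(); ++i)
    for (int j = 0; j < n * n; ++j)
      m((int)i, j) = (Rbyte)out[i][(size_t)j];
  return m;
}

// Score every DAG in a row-packed set with a shared family cache.
// [[Rcpp::export]]
NumericVector cppScoreDagSet(RawMatrix states, int n, IntegerMatrix data,
                             IntegerVector arities, Nullable<IntegerMatrix> mask,
                             double ess) {
  Scorer sc = makeScorer(data, arities, mask, ess);
  if (sc.n != n) stop("dataset variable count does not match DAG node count");
  int m = states.nrow();
  NumericVector out(m);
  Adj adj((size_t)n * n, 0);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n * n; ++j) adj[(size_t)j] = states(i, j) != 0;
    out[i] = sc.graph(adj);
  }
  return out;
}

// Index of each row of x within the rows of `table` (1-based, NA if absent).
// [[Rcpp::export]]
IntegerVector cppMatchRows(RawMatrix x, RawMatrix table) {
  if (x.ncol() != table.ncol()) stop("row widths differ");
  int w = x.ncol();
  std::unordered_map<std::string, int> idx;
  idx.reserve((size_t)table.nrow() * 2);
  for (int i = 0; i < table.nrow(); ++i) {
    std::string key((size_t)w, '\0');
    for (int j = 0; j < w; ++j) key[(size_t)j] = (char)table(i, j);
    idx.emplace(std::move(key), i + 1);
  }
  IntegerVector out(x.nrow());
  for (int i = 0; i < x.nrow(); ++i) {
    std::string key((size_t)w, '\0');
    for (int j = 0; j < w; ++j) key[(size_t)j] = (char)x(i, j);
    std::unordered_map<std::string, int>::iterator it = idx.find(key);
    out[i] = it == idx.end() ? NA_INTEGER : it->second;
  }
  return out;
}
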