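#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Maximum-parsimony search over unrooted binary trees.
//
// Leaf character states are bitmasks over an unordered state alphabet
// (one bit per amino acid; gaps / missing data carry the all-ones mask).
// Sites are pre-compressed to unique patterns with multiplicity weights
// on the R side. Tree length is the weighted Fitch count of changes.
//
// Tree representation: nodes 0..2n-3 (tips 0..n-1, internals n..2n-3),
// adjacency lists with three slots per node (tips use slot 0 only).

typedef std::vector<std::array<int, 3> > Adj;

static inline void replace_nb(Adj &nb, int node, int from, int to) {
  for (int k = 0; k < 3; ++k)
    if (nb[node][k] == from) { nb[node][k] = to; return; }
  stop("internal error: neighbour not found");
}

// Weighted Fitch length of the tree rooted at tip `anchor`. Early exit
// once the length exceeds `bound`.
static double fitch_len(const Adj &nb, int nTip, int anchor,
                        const uint32_t *leaf, int nsite, const double *w,
                        std::vector<uint32_t> &buf,
                        std::vector<int> &parent, std::vector<int> &order,
                        double bound) {
  const int N = (int) nb.size();
  int root = nb[anchor][0];
  if (root < nTip) return 0.0; // two-taxon tree
  order.clear();
  std::vector<int> stack;
  stack.push_back(root);
  parent.assign(N, -2);
  parent[root] = anchor;
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    order.push_back(u);
    for (int k = 0; k < 3; ++k) {
      int v = nb[u][k];
      if (v >= nTip && v != parent[u] && v >= 0) {
        parent[v] = u;
        stack.push_back(v);
      } else if (v >= 0 && v < nTip && v != parent[u]) {
        parent[v] = u;
      }
    }
  }
  double len = 0.0;
  // Post-order: reverse DFS discovery order.
  for (int idx = (int) order.size() - 1; idx >= 0; --idx) {
    int u = order[idx];
    const uint32_t *c[2];
    int nc = 0;
    for (int k = 0; k < 3; ++k) {
      int v = nb[u][k];
      if (v < 0 || v == parent[u]) continue;
      c[nc++] = (v < nTip) ? (leaf + (size_t) v * nsite)
                           : (&buf[(size_t) v * nsite]);
    }
    if (nc != 2) stop("internal error: non-binary node in Fitch pass");
    uint32_t *out = &buf[(size_t) u * nsite];
    for (int s = 0; s < nsite; ++s) {
      uint32_t x = c[0][s] & c[1][s];
      if (!x) { x = c[0][s] | c[1][s]; len += w[s]; }
      out[s] = x;
    }
    if (len > bound) return len;
  }
  // Fold in the anchor tip.
  const uint32_t *a = leaf + (size_t) anchor * nsite;
  const uint32_t *r = &buf[(size_t) root * nsite];
  for (int s = 0; s < nsite; ++s)
    if (!(a[s] & r[s])) len += w[s];
  return len;
}

// Collect undirected edges (u, v) reachable from `start`, skipping any
// traversal through `avoid` (-1 for none).
static void collect_edges(const Adj &nb, int start, int avoid,
                          std::vector<std::pair<int, int> > &edges) {
  edges.clear();
  std::vector<int> stack, seen;
  seen.assign(nb.size(), 0);
  stack.push_back(start);
  seen[start] = 1;
  if (avoid >= 0) seen[avoid] = 1;
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    for (int k = 0; k < 3; ++k) {
      int v = nb[u][k];
      if (v < 0 || seen[v]) continue;
      edges.push_back(std::make_pair(u, v));
      seen[v] = 1;
      stack.push_back(v);
    }
  }
}

struct Workspace {
  std::vector<uint32_t> buf;
  std::vector<int> parent, order;
};

static double score(const Adj &nb, int nTip, int anchor,
                    const uint32_t *leaf, int nsite, const double *w,
                    Workspace &ws, double bound) {
  return fitch_len(nb, nTip, anchor, leaf, nsite, w, ws.buf, ws.parent,
                   ws.order, bound);
}

// Greedy random-addition starting tree: taxa joined in shuffled order,
// each at the placement minimising tree length.
static void random_addition(Adj &nb, int nTip, const uint32_t *leaf,
                            int nsite, const double *w, Workspace &ws,
                            std::vector<int> &addorder) {
  const int N = 2 * nTip - 2;
  nb.assign(N, std::array<int, 3>());
  for (int i = 0; i < N; ++i) nb[i][0] = nb[i][1] = nb[i][2] = -1;
  // Shuffled taxon order via R's RNG.
  addorder.resize(nTip);
  for (int i = 0; i < nTip; ++i) addorder[i] = i;
  for (int i = nTip - 1; i > 0; --i) {
    int j = (int) (unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(addorder[i], addorder[j]);
  }
  int t0 = addorder[0], t1 = addorder[1], t2 = addorder[2];
  int inode = nTip; // next free internal id
  nb[inode][0] = t0; nb[inode][1] = t1; nb[inode][2] = t2;
  nb[t0][0] = inode; nb[t1][0] = inode; nb[t2][0] = inode;
  ++inode;
  std::vector<std::pair<int, int> > edges;
  for (int k = 3; k < nTip; ++k) {
    int t = addorder[k];
    collect_edges(nb, t0, -1, edges);
    double best = R_PosInf;
    int bx = -1, by = -1;
    int m = inode;
    for (size_t e = 0; e < edges.size(); ++e) {
      int x = edges[e].first, y = edges[e].second;
      replace_nb(nb, x, y, m); replace_nb(nb, y, x, m);
      nb[m][0] = x; nb[m][1] = y; nb[m][2] = t;
      nb[t][0] = m;
      double len = score(nb, nTip, t0, leaf, nsite, w, ws, best);
      if (len < best - 1e-12) { best = len; bx = x; by = y; }
      // revert
      replace_nb(nb, x, m, y); replace_nb(nb, y, m, x);
      nb[m][0] = nb[m][1] = nb[m][2] = -1;
      nb[t][0] = -1;
    }
    replace_nb(nb, bx, by, m); replace_nb(nb, by, bx, m);
    nb[m][0] = bx; nb[m][1] = by; nb[m][2] = t;
    nb[t][0] = m;
    ++inode;
  }
}

// One full first-improvement SPR sweep; returns true if an improving
// move was applied (tree modified in place, len updated).
static bool spr_sweep(Adj &nb, int nTip, const uint32_t *leaf, int nsite,
                      const double *w, Workspace &ws, double &len) {
  std::vector<std::pair<int, int> > edges, mainEdges;
  collect_edges(nb, 0, -1, edges);
  for (size_t e = 0; e < edges.size(); ++e) {
    for (int dir = 0; dir < 2; ++dir) {
      int u = dir ? edges[e].second : edges[e].first;
      int v = dir ? edges[e].first : edges[e].second;
      if (v < nTip) continue; // handle node must be internal
      // v's other neighbours a, b get spliced together.
      int a = -1, b = -1;
      for (int k = 0; k < 3; ++k) {
        int x = nb[v][k];
        if (x == u) continue;
        if (a < 0) a = x; else b = x;
      }
      replace_nb(nb, a, v, b); replace_nb(nb, b, v, a);
      // main component = side of a/b; pruned unit = subtree u + handle v.
      collect_edges(nb, a, v, mainEdges);
      bool applied = false;
      for (size_t f = 0; f < mainEdges.size(); ++f) {
        int x = mainEdges[f].first, y = mainEdges[f].second;
        if ((x == a && y == b) || (x == b && y == a)) continue; // no-op
        replace_nb(nb, x, y, v); replace_nb(nb, y, x, v);
        nb[v][0] = u; nb[v][1] = x; nb[v][2] = y;
        double cand = score(nb, nTip, 0, leaf, nsite, w, ws, len);
        if (cand < len - 1e-9) { len = cand; applied = true; break; }
        replace_nb(nb, x, v, y); replace_nb(nb, y, v, x);
      }
      if (applied) return true;
      // restore the original attachment of v between a and b
      replace_nb(nb, a, b, v); replace_nb(nb, b, a, v);
      nb[v][0] = u; nb[v][1] = a; nb[v][2] = b;
    }
  }
  return false;
}

static IntegerMatrix adj_to_edges(const Adj &nb) {
  std::vector<std::pair<int, int> > edges;
  collect_edges(nb, 0, -1, edges);
  IntegerMatrix out(edges.size(), 2);
  for (size_t i = 0; i < edges.size(); ++i) {
    out(i, 0) = edges[i].first + 1;
    out(i, 1) = edges[i].second + 1;
  }
  return out;
}

// [[Rcpp::export(name = ".mp_search_cpp")]]
List mp_search_cpp(IntegerMatrix leafStates, NumericVector weights,
                   int nStarts, int maxSweeps) {
  const int nTip = leafStates.nrow(), nsite = leafStates.ncol();
  if (nTip < 4) stop("need at least 4 taxa");
  // Row-major copy of leaf states.
  std::vector<uint32_t> leaf((size_t) nTip * nsite);
  for (int i = 0; i < nTip; ++i)
    for (int s = 0; s < nsite; ++s)
      leaf[(size_t) i * nsite + s] = (uint32_t) leafStates(i, s);
  Workspace ws;
  ws.buf.assign((size_t) (2 * nTip - 2) * nsite, 0u);
  List trees(nStarts);
  NumericVector lens(nStarts);
  std::vector<int> addorder;
  for (int r = 0; r < nStarts; ++r) {
    Adj nb;
    random_addition(nb, nTip, &leaf[0], nsite, &weights[0], ws, addorder);
    double len = score(nb, nTip, 0, &leaf[0], nsite, &weights[0], ws,
                       R_PosInf);
    int sweeps = 0;
    while (sweeps < maxSweeps &&
           spr_sweep(nb, nTip, &leaf[0], nsite, &weights[0], ws, len))
      ++sweeps;
    trees[r] = adj_to_edges(nb);
    lens[r] = len;
  }
  return List::create(_["edges"] = trees, _["lengths"] = lens);
}

// Weighted Fitch length for a fixed unrooted binary tree given as the
// 1-based undirected edge list produced by .mp_search_cpp (or built in R
// with the same node numbering: tips 1..n, internals n+1..2n-2).
// [[Rcpp::export(name = ".fitch_edges_cpp")]]
double fitch_edges_cpp(IntegerMatrix edges, int nTip,
                       IntegerMatrix leafStates, NumericVector weights) {
  const int nsite = leafStates.ncol();
  const int N = 2 * nTip - 2;
  Adj nb(N);
  for (int i = 0; i < N; ++i) nb[i][0] = nb[i][1] = nb[i][2] = -1;
  std::vector<int> deg(N, 0);
  for (int e = 0; e < edges.nrow(); ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    if (u < 0 || v < 0 || u >= N || v >= N) stop("bad node id in edges");
    nb[u][deg[u]++] = v;
    nb[v][deg[v]++] = u;
  }
  std::vector<uint32_t> leaf((size_t) nTip * nsite);
  for (int i = 0; i < nTip; ++i)
    for (int s = 0; s < nsite; ++s)
      leaf[(size_t) i * nsite + s] = (uint32_t) leafStates(i, s);
  Workspace ws;
  ws.buf.assign((size_t) N * nsite, 0u);
  return score(nb, nTip, 0, &leaf[0], nsite, &weights[0], ws, R_PosInf);
}
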