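#include <Rcpp.h>
using namespace Rcpp;

// Tips are 0..n-1, internal nodes n..2n-2.  A tree is held as child/parent
// arrays; Fitch state sets are bitmasks, so at most 31 states (the package
// caps discrete characters well below that).

namespace {

struct Topo {
  std::vector<int> parent, left, right;
  int root;
};

// Uniform rooted binary labelled topology by sequential random addition:
// tip i+1 is attached on an edge chosen uniformly among the 2i-1 edges of
// the current i-tip tree (the edge above the root included), which gives
// every labelled topology probability 1/(2n-3)!!.
Topo random_topo(int n) {
  Topo t;
  int m = 2 * n - 1;
  t.parent.assign(m, -1);
  t.left.assign(m, -1);
  t.right.assign(m, -1);
  std::vector<int> present;
  present.reserve(m);
  present.push_back(0);
  t.root = 0;
  for (int j = 1; j < n; ++j) {
    int idx = (int)(unif_rand() * present.size());
    if (idx >= (int)present.size()) idx = present.size() - 1;
    int v = present[idx];
    int u = n + j - 1;  // new internal node
    int p = t.parent[v];
    t.left[u] = v;
    t.right[u] = j;
    t.parent[v] = u;
    t.parent[j] = u;
    t.parent[u] = p;
    if (p == -1) {
      t.root = u;
    } else {
      if (t.left[p] == v) t.left[p] = u; else t.right[p] = u;
    }
    present.push_back(u);
    present.push_back(j);
  }
  return t;
}

// Unit-cost Fitch length on a binary topology given tip state indices
// (0-based).  Iterative postorder via an explicit stack.
int fitch_topo(const Topo &t, const std::vector<int> &state, int n) {
  if (n < 2) return 0;
  int m = 2 * n - 1;
  std::vector<unsigned int> mask(m, 0u);
  std::vector<int> stack, order;
  stack.reserve(m);
  order.reserve(m);
  stack.push_back(t.root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    if (t.left[v] >= 0) {
      stack.push_back(t.left[v]);
      stack.push_back(t.right[v]);
    }
  }
  int steps = 0;
  for (int i = (int)order.size() - 1; i >= 0; --i) {
    int v = order[i];
    if (t.left[v] < 0) {
      mask[v] = 1u << state[v];
    } else {
      unsigned int a = mask[t.left[v]], b = mask[t.right[v]];
      unsigned int inter = a & b;
      if (inter) mask[v] = inter; else { mask[v] = a | b; ++steps; }
    }
  }
  return steps;
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix random_topology_edges(int n) {
  Topo t = random_topo(n);
  // Emit edges in preorder from the root; node ids 0-based, tips 0..n-1.
  IntegerMatrix edge(2 * n - 2, 2);
  int r = 0;
  std::vector<int> stack;
  stack.push_back(t.root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    if (t.left[v] >= 0) {
      edge(r, 0) = v; edge(r, 1) = t.left[v]; ++r;
      edge(r, 0) = v; edge(r, 1) = t.right[v]; ++r;
      stack.push_back(t.right[v]);
      stack.push_back(t.left[v]);
    }
  }
  return edge;
}

// Fitch length on an arbitrary binary tree passed as a postorder edge list
// (parent, child; 0-based; tips 0..ntip-1).
// [[Rcpp::export]]
int fitch_count_edges(IntegerMatrix edge_po, IntegerVector tip_state,
                      int ntip, int nnode_total) {
  std::vector<unsigned int> mask(nnode_total, 0u);
  for (int i = 0; i < ntip; ++i) mask[i] = 1u << tip_state[i];
  int steps = 0;
  for (int e = 0; e < edge_po.nrow(); ++e) {
    int p = edge_po(e, 0), c = edge_po(e, 1);
    if (mask[p] == 0u) {
      mask[p] = mask[c];
    } else {
      unsigned int inter = mask[p] & mask[c];
      if (inter) mask[p] = inter; else { mask[p] |= mask[c]; ++steps; }
    }
  }
  return steps;
}

// Null parsimony lengths on N independent uniform random topologies, the
// tip-state assignment held fixed (tip i carries tip_state[i]).
// [[Rcpp::export]]
IntegerVector null_lengths_topology(IntegerVector tip_state, int N) {
  int n = tip_state.size();
  std::vector<int> st(tip_state.begin(), tip_state.end());
  IntegerVector out(N);
  for (int r = 0; r < N; ++r) {
    Topo t = random_topo(n);
    out[r] = fitch_topo(t, st, n);
  }
  return out;
}

// Null parsimony lengths under tip-label shuffling: the topology (postorder
// edge list) is fixed, the states are permuted uniformly each replicate.
// [[Rcpp::export]]
IntegerVector null_lengths_shuffle(IntegerMatrix edge_po,
                                   IntegerVector tip_state, int ntip,
                                   int nnode_total, int N) {
  std::vector<int> st0(tip_state.begin(), tip_state.end());
  IntegerVector out(N);
  for (int r = 0; r < N; ++r) {
    std::vector<int> st(st0);             // permute a fresh copy each time
    for (int i = ntip - 1; i > 0; --i) {  // Fisher-Yates with R's RNG
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(st[i], st[j]);
    }
    std::vector<unsigned int> mask(nnode_total, 0u);
    for (int i = 0; i < ntip; ++i) mask[i] = 1u << st[i];
    int steps = 0;
    for (int e = 0; e < edge_po.nrow(); ++e) {
      int p = edge_po(e, 0), c = edge_po(e, 1);
      if (mask[p] == 0u) {
        mask[p] = mask[c];
      } else {
        unsigned int inter = mask[p] & mask[c];
        if (inter) mask[p] = inter; else { mask[p] |= mask[c]; ++steps; }
      }
    }
    out[r] = steps;
  }
  return out;
}
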