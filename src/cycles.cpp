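// Directed simple-cycle counting via Johnson's blocked backtracking
// search.  Cycles are counted once each, anchored at their smallest
// vertex: for each start vertex s the search explores only vertices
// >= s, with the blocked-set machinery of Johnson's algorithm pruning
// vertices that cannot currently close a circuit back to s.
#include <Rcpp.h>
#include <vector>

namespace {

struct JohnsonCounter {
  int n, s;
  const std::vector<std::vector<int>>& adj;
  std::vector<bool> blocked;
  std::vector<std::vector<int>> B;
  double count;

  explicit JohnsonCounter(const std::vector<std::vector<int>>& a)
      : n((int)a.size()), s(0), adj(a), blocked(a.size(), false),
        B(a.size()), count(0.0) {}

  void unblock(int v) {
    blocked[v] = false;
    std::vector<int> pending;
    pending.swap(B[v]);
    for (int w : pending)
      if (blocked[w]) unblock(w);
  }

  bool circuit(int v) {
    bool found = false;
    blocked[v] = true;
    for (int w : adj[v]) {
      if (w < s) continue;
      if (w == s) {
        count += 1.0;
        found = true;
      } else if (!blocked[w]) {
        if (circuit(w)) found = true;
      }
    }
    if (found) {
      unblock(v);
    } else {
      for (int w : adj[v]) {
        if (w < s) continue;
        std::vector<int>& bw = B[w];
        bool present = false;
        for (int u : bw)
          if (u == v) { present = true; break; }
        if (!present) bw.push_back(v);
      }
    }
    return found;
  }

  double run() {
    for (s = 0; s < n; ++s) {
      for (int v = s; v < n; ++v) {
        blocked[v] = false;
        B[v].clear();
      }
      circuit(s);
    }
    return count;
  }
};

}  // namespace

// [[Rcpp::export]]
double count_cycles_cpp(Rcpp::LogicalMatrix adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> a(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j)) a[i].push_back(j);
  JohnsonCounter jc(a);
  return jc.run();
}
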