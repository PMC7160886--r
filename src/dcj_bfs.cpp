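// Breadth-first search over DCJ operations on adjacency-set states.
// Used as an independent validation route for the closed-form DCJ distance.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <set>
#include <algorithm>

using namespace Rcpp;

// extremities: marker g in 1..n -> tail 2g-1, head 2g; 0 = empty extremity.
// adjacency encoded as lo * 128 + hi with lo <= hi; (0,0) never stored.
typedef std::vector<int> State;

static inline int enc(int a, int b) {
  if (a > b) std::swap(a, b);
  return a * 128 + b;
}

static State chroms_to_state(const List& chroms) {
  State st;
  for (R_xlen_t c = 0; c < chroms.size(); ++c) {
    IntegerVector ch = chroms[c];
    int n = ch.size();
    if (n == 0) continue;
    std::vector<int> left(n), right(n);
    for (int i = 0; i < n; ++i) {
      int g = ch[i];
      int tail = 2 * std::abs(g) - 1, head = 2 * std::abs(g);
      if (g > 0) { left[i] = tail; right[i] = head; }
      else       { left[i] = head; right[i] = tail; }
    }
    st.push_back(enc(0, left[0]));
    for (int i = 0; i + 1 < n; ++i) st.push_back(enc(right[i], left[i + 1]));
    st.push_back(enc(0, right[n - 1]));
  }
  std::sort(st.begin(), st.end());
  return st;
}

static void push_adj(State& st, int a, int b) {
  if (a == 0 && b == 0) return; // empty adjacency vanishes
  st.push_back(enc(a, b));
}

static void neighbors(const State& st, std::vector<State>& out) {
  out.clear();
  int m = (int)st.size();
  std::vector<int> lo(m), hi(m);
  for (int i = 0; i < m; ++i) { lo[i] = st[i] / 128; hi[i] = st[i] % 128; }
  State base;
  base.reserve(m);
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      int p = lo[i], q = hi[i], r = lo[j], s = hi[j];
      for (int variant = 0; variant < 2; ++variant) {
        base.clear();
        for (int k = 0; k < m; ++k) if (k != i && k != j) base.push_back(st[k]);
        if (variant == 0) { push_adj(base, p, r); push_adj(base, q, s); }
        else              { push_adj(base, p, s); push_adj(base, q, r); }
        std::sort(base.begin(), base.end());
        out.push_back(base);
      }
    }
    // fission: cut one non-telomeric adjacency into two telomeres
    if (lo[i] > 0) {
      base.clear();
      for (int k = 0; k < m; ++k) if (k != i) base.push_back(st[k]);
      push_adj(base, 0, lo[i]);
      push_adj(base, 0, hi[i]);
      std::sort(base.begin(), base.end());
      out.push_back(base);
    }
  }
}

// [[Rcpp::export]]
int dcj_bfs_cpp(List g_chroms, List h_chroms, int n_markers, int max_depth) {
  if (n_markers > 60) stop("dcj_bfs_cpp: instance too large for exhaustive search");
  State start = chroms_to_state(g_chroms);
  State goal  = chroms_to_state(h_chroms);
  if (start == goal) return 0;
  std::set<State> seen;
  seen.insert(start);
  std::queue<std::pair<State, int> > q;
  q.push(std::make_pair(start, 0));
  std::vector<State> nb;
  while (!q.empty()) {
    State cur = q.front().first;
    int d = q.front().second;
    q.pop();
    if (d >= max_depth) continue;
    neighbors(cur, nb);
    for (size_t k = 0; k < nb.size(); ++k) {
      if (nb[k] == goal) return d + 1;
      if (seen.insert(nb[k]).second) q.push(std::make_pair(nb[k], d + 1));
    }
  }
  stop("dcj_bfs_cpp: target not reached within max_depth");
  return -1;
}
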