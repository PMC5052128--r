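#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Exact binary submodular energy minimization by push-relabel max-flow.
//
// Nodes 1..n carry terminal capacities u0 (cost of label 0 == capacity of
// the implicit source arc) and u1 (cost of label 1 == sink arc), plus
// undirected pairwise capacities w on the pair list (ei, ej) — the Potts
// cut cost. Terminal arcs are folded into per-node excess/drain instead of
// explicit arcs. FIFO push-relabel with periodic global relabeling; at
// termination the source side of a minimum cut is {i : h[i] >= n + 2}
// (the total vertex count including the implicit terminals), which is the
// label-1 (foreground) side under this construction.

static const double EPS = 1e-11;

// [[Rcpp::export]]
IntegerVector maxflow_labels_cpp(int n, IntegerVector ei, IntegerVector ej,
                                 NumericVector w, NumericVector u0,
                                 NumericVector u1) {
  int m = ei.size();
  if (ej.size() != m || w.size() != m)
    stop("pair list lengths disagree");
  if (u0.size() != n || u1.size() != n)
    stop("terminal capacity lengths disagree");

  // CSR adjacency with both arc directions
  std::vector<int> deg(n + 1, 0);
  for (int a = 0; a < m; ++a) {
    int i = ei[a] - 1, j = ej[a] - 1;
    if (i < 0 || i >= n || j < 0 || j >= n) stop("pair index out of range");
    ++deg[i]; ++deg[j];
  }
  std::vector<int> head(n + 1, 0);
  for (int i = 0; i < n; ++i) head[i + 1] = head[i] + deg[i];
  std::vector<int> pos(head.begin(), head.end() - 1);
  std::vector<int> to(2 * (size_t)m), rev(2 * (size_t)m);
  std::vector<double> capr(2 * (size_t)m);
  for (int a = 0; a < m; ++a) {
    int i = ei[a] - 1, j = ej[a] - 1;
    int pi = pos[i]++, pj = pos[j]++;
    to[pi] = j; to[pj] = i;
    rev[pi] = pj; rev[pj] = pi;
    capr[pi] = w[a]; capr[pj] = w[a];
  }

  const int HMAX = n + 2;  // total vertex count incl. implicit source/sink
  std::vector<double> e(n), d(n);
  std::vector<int> h(n, 0), cur(head.begin(), head.end() - 1);
  for (int i = 0; i < n; ++i) {
    e[i] = u0[i]; d[i] = u1[i];
    double f = std::min(e[i], d[i]);  // direct source->i->sink drain
    e[i] -= f; d[i] -= f;
  }

  std::queue<int> q;
  std::vector<char> inq(n, 0);

  // exact distance-to-sink labels by reverse residual BFS; unreachable -> HMAX
  auto global_relabel = [&]() {
    std::fill(h.begin(), h.end(), HMAX);
    std::queue<int> bq;
    for (int i = 0; i < n; ++i)
      if (d[i] > EPS) { h[i] = 1; bq.push(i); }
    while (!bq.empty()) {
      int j = bq.front(); bq.pop();
      for (int a = head[j]; a < head[j + 1]; ++a) {
        int k = to[a];
        // residual arc k->j is the reverse of arc a
        if (capr[rev[a]] > EPS && h[k] == HMAX) {
          h[k] = h[j] + 1;
          bq.push(k);
        }
      }
    }
    std::copy(head.begin(), head.end() - 1, cur.begin());
  };

  global_relabel();
  for (int i = 0; i < n; ++i)
    if (e[i] > EPS && h[i] < HMAX) { q.push(i); inq[i] = 1; }

  long long work = 0;
  const long long relabel_period = 6LL * n + 2LL * m;

  while (!q.empty()) {
    int i = q.front(); q.pop(); inq[i] = 0;
    // discharge i
    while (e[i] > EPS && h[i] < HMAX) {
      if (h[i] == 1 && d[i] > EPS) {          // push to sink
        double f = std::min(e[i], d[i]);
        e[i] -= f; d[i] -= f;
        if (e[i] <= EPS) break;
      }
      bool pushed = false;
      for (int &a = cur[i]; a < head[i + 1]; ++a) {
        int j = to[a];
        if (capr[a] > EPS && h[i] == h[j] + 1) {
          double f = std::min(e[i], capr[a]);
          capr[a] -= f; capr[rev[a]] += f;
          e[i] -= f; e[j] += f;
          if (!inq[j] && e[j] > EPS && h[j] < HMAX) { q.push(j); inq[j] = 1; }
          pushed = true;
          if (e[i] <= EPS) break;
        }
      }
      if (e[i] <= EPS) break;
      if (!pushed || cur[i] >= head[i + 1]) {  // relabel
        int nh = (d[i] > EPS) ? 1 : HMAX;
        for (int a = head[i]; a < head[i + 1]; ++a)
          if (capr[a] > EPS && h[to[a]] + 1 < nh) nh = h[to[a]] + 1;
        h[i] = nh;
        cur[i] = head[i];
        if (++work > relabel_period) {
          work = 0;
          global_relabel();
          // rebuild queue: heights changed globally
          std::queue<int> empty; std::swap(q, empty);
          std::fill(inq.begin(), inq.end(), 0);
          for (int k = 0; k < n; ++k)
            if (e[k] > EPS && h[k] < HMAX) { q.push(k); inq[k] = 1; }
          break;
        }
      }
    }
  }

  // min cut from the max preflow: nodes that cannot reach the sink in the
  // residual graph form the source (foreground) side. The final BFS of
  // global_relabel computes exactly this reachability.
  global_relabel();
  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) lab[i] = (h[i] >= HMAX) ? 1 : 0;
  return lab;
}
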