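#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <map>
using namespace Rcpp;

// Deterministic multilevel (Louvain) modularity optimization.
//
// Local moving visits nodes in the caller-supplied sweep order; a node
// moves to the neighbouring community with the largest positive
// modularity gain (ties: lowest community id).  When a sweep makes no
// move, communities are collapsed into super-nodes (weighted, with
// self-loops) and the procedure recurses; it stops when aggregation
// changes nothing.  With a fixed sweep order the result is fully
// deterministic.
//
// Q = sum_c [ e_c / m - (d_c / (2m))^2 ] with edge weights; self-loops
// contribute twice to degree, once to e_c (standard convention).

struct Level {
  int n;
  std::vector<std::vector<std::pair<int, double>>> adj;  // no self-loops
  std::vector<double> self_w;                            // self-loop weight
};

static double total_weight(const Level& g) {
  double m = 0.0;
  for (int v = 0; v < g.n; ++v) {
    m += g.self_w[v];
    for (auto& e : g.adj[v]) m += e.second / 2.0;
  }
  return m;
}

// one round of local moving; returns community labels (0-based, compacted)
static std::vector<int> local_move(const Level& g, const std::vector<int>& order,
                                   bool* moved_any) {
  const int n = g.n;
  const double m = total_weight(g);
  std::vector<int> comm(n);
  std::vector<double> deg(n, 0.0), tot(n, 0.0);
  for (int v = 0; v < n; ++v) {
    comm[v] = v;
    deg[v] = 2.0 * g.self_w[v];
    for (auto& e : g.adj[v]) deg[v] += e.second;
    tot[v] = deg[v];
  }
  *moved_any = false;
  std::vector<double> wsum(n, 0.0);
  bool improved = true;
  while (improved) {
    improved = false;
    for (int vi = 0; vi < n; ++vi) {
      const int v = order[vi];
      const int cv = comm[v];
      std::vector<int> seen;
      for (auto& e : g.adj[v]) {
        int c = comm[e.first];
        if (wsum[c] == 0.0) seen.push_back(c);
        wsum[c] += e.second;
      }
      tot[cv] -= deg[v];
      double base = wsum[cv] - deg[v] * tot[cv] / (2.0 * m);
      int best = cv;
      double best_gain = 0.0;
      std::sort(seen.begin(), seen.end());  // deterministic tie-break
      for (int c : seen) {
        if (c == cv) continue;
        double gain = (wsum[c] - deg[v] * tot[c] / (2.0 * m)) - base;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best = c;
        }
      }
      tot[best] += deg[v];
      if (best != cv) {
        comm[v] = best;
        improved = true;
        *moved_any = true;
      }
      for (int c : seen) wsum[c] = 0.0;
    }
  }
  // compact labels
  std::vector<int> relab(n, -1);
  int k = 0;
  for (int v = 0; v < n; ++v)
    if (relab[comm[v]] < 0) relab[comm[v]] = k++;
  for (int v = 0; v < n; ++v) comm[v] = relab[comm[v]];
  return comm;
}

static Level aggregate(const Level& g, const std::vector<int>& comm, int k) {
  Level h;
  h.n = k;
  h.adj.assign(k, {});
  h.self_w.assign(k, 0.0);
  std::vector<std::map<int, double>> acc(k);
  for (int v = 0; v < g.n; ++v) {
    h.self_w[comm[v]] += g.self_w[v];
    for (auto& e : g.adj[v]) {
      int cu = comm[v], cw = comm[e.first];
      if (cu == cw) {
        h.self_w[cu] += e.second / 2.0;  // each intra edge seen twice
      } else {
        acc[cu][cw] += e.second;
      }
    }
  }
  for (int c = 0; c < k; ++c)
    for (auto& kv : acc[c]) h.adj[c].push_back({kv.first, kv.second});
  return h;
}

// [[Rcpp::export(name = ".louvain_cpp")]]
List louvain_cpp(int n, IntegerMatrix edges, NumericVector weights,
                 IntegerVector order) {
  Level g;
  g.n = n;
  g.adj.assign(n, {});
  g.self_w.assign(n, 0.0);
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    double w = weights[e];
    if (i == j) {
      g.self_w[i] += w;
    } else {
      g.adj[i].push_back({j, w});
      g.adj[j].push_back({i, w});
    }
  }

  std::vector<int> membership(n);
  for (int v = 0; v < n; ++v) membership[v] = v;

  Level cur = g;
  std::vector<int> sweep(cur.n);
  for (int v = 0; v < cur.n; ++v) sweep[v] = order[v] - 1;

  while (true) {
    bool moved = false;
    std::vector<int> comm = local_move(cur, sweep, &moved);
    if (!moved) break;
    int k = 1 + *std::max_element(comm.begin(), comm.end());
    for (int v = 0; v < n; ++v) membership[v] = comm[membership[v]];
    if (k == 1) break;
    cur = aggregate(cur, comm, k);
    sweep.resize(cur.n);
    for (int v = 0; v < cur.n; ++v) sweep[v] = v;
  }

  // Q at the original level
  const double m = total_weight(g);
  int k = 1 + *std::max_element(membership.begin(), membership.end());
  std::vector<double> e_c(k, 0.0), d_c(k, 0.0);
  for (int v = 0; v < n; ++v) {
    int c = membership[v];
    e_c[c] += g.self_w[v];
    d_c[c] += 2.0 * g.self_w[v];
    for (auto& e : g.adj[v]) {
      d_c[c] += e.second;
      if (membership[e.first] == c) e_c[c] += e.second / 2.0;
    }
  }
  double q = 0.0;
  for (int c = 0; c < k; ++c)
    q += e_c[c] / m - std::pow(d_c[c] / (2.0 * m), 2.0);

  IntegerVector out(n);
  for (int v = 0; v < n; ++v) out[v] = membership[v] + 1;
  return List::create(_["membership"] = out, _["q"] = q);
}
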