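#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// BFS distances from `src` on a binary undirected graph given as adjacency
// lists; dist is reset and filled with -1 for unreachable nodes.
static void bfs(const std::vector< std::vector<int> >& adj, int src,
                std::vector<int>& dist) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[src] = 0;
  std::queue<int> q;
  q.push(src);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (size_t k = 0; k < adj[u].size(); ++k) {
      int v = adj[u][k];
      if (dist[v] < 0) {
        dist[v] = dist[u] + 1;
        q.push(v);
      }
    }
  }
}

// Global efficiency of the subgraph on node set `nodes` (paths confined to
// the subgraph), by BFS inside the subgraph.
static double subgraph_efficiency(const std::vector< std::vector<int> >& adj,
                                  const std::vector<int>& nodes) {
  int m = nodes.size();
  if (m < 2) return 0.0;
  std::vector<int> pos(adj.size(), -1);
  for (int k = 0; k < m; ++k) pos[nodes[k]] = k;
  // adjacency restricted to the node set
  std::vector< std::vector<int> > sub(m);
  for (int k = 0; k < m; ++k) {
    int u = nodes[k];
    for (size_t j = 0; j < adj[u].size(); ++j) {
      int v = adj[u][j];
      if (pos[v] >= 0) sub[k].push_back(pos[v]);
    }
  }
  double inv_sum = 0.0;
  std::vector<int> dist(m);
  for (int s = 0; s < m; ++s) {
    bfs(sub, s, dist);
    for (int t = 0; t < m; ++t) {
      if (t != s && dist[t] > 0) inv_sum += 1.0 / dist[t];
    }
  }
  return inv_sum / (double(m) * double(m - 1));
}

static void metrics_from_adj(const std::vector< std::vector<int> >& adj,
                             double* out) {
  int P = adj.size();
  // clustering coefficient: triangles over connected triples per node
  double cc_sum = 0.0;
  for (int i = 0; i < P; ++i) {
    int k = adj[i].size();
    if (k < 2) continue;
    std::vector<char> is_nb(P, 0);
    for (int a = 0; a < k; ++a) is_nb[adj[i][a]] = 1;
    int tri2 = 0; // counts each triangle twice
    for (int a = 0; a < k; ++a) {
      int u = adj[i][a];
      for (size_t b = 0; b < adj[u].size(); ++b) {
        if (is_nb[adj[u][b]]) ++tri2;
      }
    }
    cc_sum += double(tri2) / (double(k) * double(k - 1));
  }
  double cc = P > 0 ? cc_sum / P : 0.0;

  // shortest paths: Lp over reachable pairs, Eglobal with 0 for unreachable
  double lp_sum = 0.0, inv_sum = 0.0;
  long lp_n = 0;
  std::vector<int> dist(P);
  for (int s = 0; s < P; ++s) {
    bfs(adj, s, dist);
    for (int t = 0; t < P; ++t) {
      if (t == s) continue;
      if (dist[t] > 0) {
        lp_sum += dist[t];
        inv_sum += 1.0 / dist[t];
        ++lp_n;
      }
    }
  }
  double lp = lp_n > 0 ? lp_sum / lp_n : 0.0;
  double eglob = P > 1 ? inv_sum / (double(P) * double(P - 1)) : 0.0;

  // local efficiency: efficiency of each node's neighbourhood subgraph
  double eloc_sum = 0.0;
  for (int i = 0; i < P; ++i) {
    if (adj[i].size() >= 2) {
      eloc_sum += subgraph_efficiency(adj, adj[i]);
    }
  }
  double eloc = P > 0 ? eloc_sum / P : 0.0;

  out[0] = cc; out[1] = eglob; out[2] = eloc; out[3] = lp;
}

// [[Rcpp::export(name = ".metrics_binary")]]
NumericVector metrics_binary(const IntegerMatrix& A) {
  int P = A.nrow();
  std::vector< std::vector<int> > adj(P);
  for (int i = 0; i < P; ++i) {
    for (int j = 0; j < P; ++j) {
      if (i != j && A(i, j) != 0) adj[i].push_back(j);
    }
  }
  NumericVector out(4);
  metrics_from_adj(adj, REAL(out));
  out.names() = CharacterVector::create("cc", "Eglobal", "Elocal", "Lp");
  return out;
}

// Binarize one weighted matrix at each threshold and compute the four
// metrics: returns a length(pr) x 4 matrix (cc, Eglobal, Elocal, Lp).
// [[Rcpp::export(name = ".metrics_over_grid")]]
NumericMatrix metrics_over_grid(const NumericMatrix& W,
                                const NumericVector& pr,
                                const bool use_absolute) {
  int P = W.nrow(), T = pr.size();
  NumericMatrix out(T, 4);
  for (int k = 0; k < T; ++k) {
    double thr = pr[k];
    std::vector< std::vector<int> > adj(P);
    for (int i = 0; i < P; ++i) {
      for (int j = 0; j < P; ++j) {
        if (i == j) continue;
        double w = use_absolute ? std::abs(W(i, j)) : W(i, j);
        if (w > thr) adj[i].push_back(j);
      }
    }
    double m[4];
    metrics_from_adj(adj, m);
    for (int c = 0; c < 4; ++c) out(k, c) = m[c];
  }
  colnames(out) = CharacterVector::create("cc", "Eglobal", "Elocal", "Lp");
  return out;
}
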