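#include <Rcpp.h>
#include <vector>

// Breadth-first search from src, filling hop distances (-1 = unreachable)
// and geodesic counts.
static void bfs_count(const std::vector<std::vector<int> > &adj, int src,
                      std::vector<int> &dist, std::vector<double> &sigma) {
  const int n = adj.size();
  std::fill(dist.begin(), dist.end(), -1);
  std::fill(sigma.begin(), sigma.end(), 0.0);
  std::vector<int> queue;
  queue.reserve(n);
  dist[src] = 0;
  sigma[src] = 1.0;
  queue.push_back(src);
  for (std::size_t head = 0; head < queue.size(); ++head) {
    int u = queue[head];
    for (std::size_t k = 0; k < adj[u].size(); ++k) {
      int w = adj[u][k];
      if (dist[w] < 0) {
        dist[w] = dist[u] + 1;
        queue.push_back(w);
      }
      if (dist[w] == dist[u] + 1) sigma[w] += sigma[u];
    }
  }
}

// Total geodesic count over all unordered node pairs (g) and the count of
// geodesics with `focal` as an interior node (g_focal), hop metric.
// `edges` is a 0-based two-column matrix; `focal` is 0-based.
// [[Rcpp::export]]
Rcpp::NumericVector geodesic_counts_through(int n, Rcpp::IntegerMatrix edges,
                                            int focal) {
  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  std::vector<int> df(n), d(n);
  std::vector<double> sf(n), sg(n);
  bfs_count(adj, focal, df, sf);
  double g = 0.0, gf = 0.0;
  for (int s = 0; s < n; ++s) {
    bfs_count(adj, s, d, sg);
    for (int t = s + 1; t < n; ++t) {
      if (d[t] < 0) continue;
      g += sg[t];
      if (s != focal && t != focal && df[s] >= 0 && df[t] >= 0 &&
          d[t] == df[s] + df[t]) {
        // sigma_{s,focal} * sigma_{focal,t}
        gf += sg[focal] * sf[t];
      }
    }
  }
  return Rcpp::NumericVector::create(g, gf);
}
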