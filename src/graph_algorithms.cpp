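#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shortest-path machinery for weighted undirected networks. Edge weights are
// mapped to lengths (L = 1/w) before these routines are called; absent edges
// carry R_PosInf. Equal-length path ties are resolved with a relative
// tolerance because lengths are continuous (1/correlation) and exact float
// equality would undercount parallel shortest paths on constructed graphs.

static const double REL_TOL = 1e-12;

static inline bool close_to(double a, double b) {
  if (!std::isfinite(a) || !std::isfinite(b)) return false;
  return std::abs(a - b) <= REL_TOL * (1.0 + std::abs(a) + std::abs(b));
}

// Dijkstra from source s: fills dist, sigma (number of distinct shortest
// paths, fractional ties counted exactly), and settlement order.
static void dijkstra_counts(const NumericMatrix& L, int s,
                            std::vector<double>& dist,
                            std::vector<double>& sigma,
                            std::vector<int>& order, int& n_settled) {
  const int N = L.nrow();
  std::vector<bool> done(N, false);
  dist.assign(N, R_PosInf);
  sigma.assign(N, 0.0);
  dist[s] = 0.0;
  sigma[s] = 1.0;
  n_settled = 0;
  for (int it = 0; it < N; ++it) {
    int u = -1;
    double best = R_PosInf;
    for (int v = 0; v < N; ++v) {
      if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
    }
    if (u < 0) break;  // remaining nodes unreachable
    done[u] = true;
    order[n_settled++] = u;
    for (int v = 0; v < N; ++v) {
      const double l = L(u, v);
      if (done[v] || !(l < R_PosInf)) continue;
      const double alt = dist[u] + l;
      if (close_to(alt, dist[v])) {
        sigma[v] += sigma[u];
      } else if (alt < dist[v]) {
        dist[v] = alt;
        sigma[v] = sigma[u];
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_shortest_dist(NumericMatrix L) {
  const int N = L.nrow();
  NumericMatrix D(N, N);
  std::vector<double> dist, sigma;
  std::vector<int> order(N);
  int n_settled;
  for (int s = 0; s < N; ++s) {
    dijkstra_counts(L, s, dist, sigma, order, n_settled);
    for (int v = 0; v < N; ++v) D(s, v) = dist[v];
  }
  return D;
}

// [[Rcpp::export]]
List cpp_shortest_paths(NumericMatrix L) {
  const int N = L.nrow();
  NumericMatrix D(N, N), S(N, N);
  std::vector<double> dist, sigma;
  std::vector<int> order(N);
  int n_settled;
  for (int s = 0; s < N; ++s) {
    dijkstra_counts(L, s, dist, sigma, order, n_settled);
    for (int v = 0; v < N; ++v) { D(s, v) = dist[v]; S(s, v) = sigma[v]; }
  }
  return List::create(_["dist"] = D, _["n_paths"] = S);
}

// Brandes accumulation over ordered source-target pairs; returns raw
// (unnormalized) betweenness. Predecessors are recovered from the distance
// condition dist[v] + L(v,w) == dist[w] rather than stored lists.
// [[Rcpp::export]]
NumericVector cpp_betweenness_raw(NumericMatrix L) {
  const int N = L.nrow();
  NumericVector bc(N);
  std::vector<double> dist, sigma, delta(N);
  std::vector<int> order(N);
  int n_settled;
  for (int s = 0; s < N; ++s) {
    dijkstra_counts(L, s, dist, sigma, order, n_settled);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = n_settled - 1; i >= 0; --i) {
      const int w = order[i];
      if (w == s) continue;
      const double coef = (1.0 + delta[w]) / sigma[w];
      for (int v = 0; v < N; ++v) {
        const double l = L(v, w);
        if (!(l < R_PosInf) || !(dist[v] < R_PosInf)) continue;
        if (close_to(dist[v] + l, dist[w]) && dist[v] < dist[w]) {
          delta[v] += sigma[v] * coef;
        }
      }
      bc[w] += delta[w];
    }
  }
  return bc;
}
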