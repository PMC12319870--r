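#include <Rcpp.h>
#include <queue>
#include <map>
#include <set>
#include <vector>
#include <utility>
#include <cmath>
using namespace Rcpp;

// Truncated single-source Dijkstra over the mesh edge graph, repeated for
// each source. Adjacency is CSR (0-based): adj_ptr has n+1 entries,
// adj_idx/adj_w hold neighbour indices and Euclidean edge lengths.
// Returns all (source, vertex, distance) triples with distance <= radius,
// including the source itself at distance 0.
// [[Rcpp::export(name = ".dijkstra_radius")]]
List dijkstra_radius(int n, IntegerVector adj_ptr, IntegerVector adj_idx,
                     NumericVector adj_w, IntegerVector sources,
                     double radius) {
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> touched;
  touched.reserve(256);
  std::vector<int> out_i, out_j;
  std::vector<double> out_d;
  typedef std::pair<double, int> QN;

  for (int s_idx = 0; s_idx < sources.size(); ++s_idx) {
    int s = sources[s_idx];
    std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;
    dist[s] = 0.0;
    touched.push_back(s);
    pq.push(QN(0.0, s));
    while (!pq.empty()) {
      QN top = pq.top();
      pq.pop();
      double d = top.first;
      int u = top.second;
      if (d > dist[u]) continue;      // stale entry
      if (d > radius) break;          // early termination
      for (int e = adj_ptr[u]; e < adj_ptr[u + 1]; ++e) {
        int v = adj_idx[e];
        double nd = d + adj_w[e];
        if (nd <= radius && nd < dist[v]) {
          if (!std::isfinite(dist[v])) touched.push_back(v);
          dist[v] = nd;
          pq.push(QN(nd, v));
        }
      }
    }
    for (size_t t = 0; t < touched.size(); ++t) {
      int v = touched[t];
      if (dist[v] <= radius) {
        out_i.push_back(s);
        out_j.push_back(v);
        out_d.push_back(dist[v]);
      }
      dist[v] = R_PosInf;
    }
    touched.clear();
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["d"] = wrap(out_d));
}

// Contiguity-constrained Ward agglomeration. Clusters start as singleton
// vertices with feature rows of x (n x T). Only cluster pairs joined by at
// least one mesh edge may merge; merge cost is the Ward increase in
// within-cluster sum of squares, (ni*nj/(ni+nj)) * ||ci - cj||^2.
// Ties are broken by the lowest (i, j) cluster-representative pair, where a
// cluster's representative is the smallest original vertex index it holds.
// Returns 0-based cluster representatives per vertex at K clusters.
// [[Rcpp::export(name = ".ward_constrained")]]
IntegerVector ward_constrained(NumericMatrix x, IntegerVector adj_ptr,
                               IntegerVector adj_idx, int K) {
  int n = x.nrow(), T = x.ncol();
  if (K < 1 || K > n) stop("K must be in [1, n_vertices]");
  std::vector<int> size(n, 1);
  std::vector<bool> active(n, true);
  // centroid sums, row-major
  std::vector<double> csum((size_t)n * T);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t) csum[(size_t)i * T + t] = x(i, t);
  std::vector<std::set<int> > nbr(n);
  for (int u = 0; u < n; ++u)
    for (int e = adj_ptr[u]; e < adj_ptr[u + 1]; ++e)
      if (adj_idx[e] != u) nbr[u].insert(adj_idx[e]);

  typedef std::pair<int, int> PR;
  std::map<PR, double> cost;
  // membership for final labelling
  std::vector<std::vector<int> > members(n);
  for (int i = 0; i < n; ++i) members[i].push_back(i);

  // Ward cost between active clusters a < b
  struct CostFn {
    std::vector<double>* csum;
    std::vector<int>* size;
    int T;
    double operator()(int a, int b) const {
      double na = (double)(*size)[a], nb = (double)(*size)[b];
      double ss = 0.0;
      const double* ca = &(*csum)[(size_t)a * T];
      const double* cb = &(*csum)[(size_t)b * T];
      for (int t = 0; t < T; ++t) {
        double d = ca[t] / na - cb[t] / nb;
        ss += d * d;
      }
      return na * nb / (na + nb) * ss;
    }
  } ward_cost;
  ward_cost.csum = &csum;
  ward_cost.size = &size;
  ward_cost.T = T;

  for (int u = 0; u < n; ++u)
    for (std::set<int>::iterator it = nbr[u].begin(); it != nbr[u].end(); ++it)
      if (u < *it) cost[PR(u, *it)] = ward_cost(u, *it);

  int n_clusters = n;
  while (n_clusters > K) {
    if (cost.empty())
      stop("mesh has more connected components than K clusters");
    // ordered map scan: first strictly-smaller cost wins => lowest (i,j) tie-break
    std::map<PR, double>::iterator best = cost.begin();
    for (std::map<PR, double>::iterator it = cost.begin(); it != cost.end(); ++it)
      if (it->second < best->second) best = it;
    int a = best->first.first, b = best->first.second; // a < b
    // merge b into a
    for (int t = 0; t < T; ++t)
      csum[(size_t)a * T + t] += csum[(size_t)b * T + t];
    size[a] += size[b];
    members[a].insert(members[a].end(), members[b].begin(), members[b].end());
    members[b].clear();
    active[b] = false;
    // rewire neighbours of b to a, drop stale costs
    for (std::set<int>::iterator it = nbr[b].begin(); it != nbr[b].end(); ++it) {
      int k = *it;
      cost.erase(k < b ? PR(k, b) : PR(b, k));
      if (k == a) continue;
      nbr[k].erase(b);
      nbr[k].insert(a);
      nbr[a].insert(k);
    }
    nbr[a].erase(b);
    nbr[b].clear();
    // refresh costs between a and its neighbours
    for (std::set<int>::iterator it = nbr[a].begin(); it != nbr[a].end(); ++it) {
      int k = *it;
      PR key = k < a ? PR(k, a) : PR(a, k);
      cost[key] = ward_cost(key.first, key.second);
    }
    --n_clusters;
  }

  IntegerVector labels(n);
  for (int c = 0; c < n; ++c) {
    if (!active[c]) continue;
    int rep = members[c][0];
    for (size_t m = 0; m < members[c].size(); ++m)
      if (members[c][m] < rep) rep = members[c][m];
    for (size_t m = 0; m < members[c].size(); ++m) labels[members[c][m]] = rep;
  }
  return labels;
}
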