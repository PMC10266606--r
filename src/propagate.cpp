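#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Seeded propagation segmentation (regularized geodesic / Dijkstra).
//
// Each foreground pixel receives the label of the seed with minimal
// accumulated path cost, where a step between 8-neighbors p -> q costs
//   sqrt(dI(p,q)^2 + lambda^2 * s^2)
// with dI the absolute guide-intensity difference and s the Euclidean step
// length (1 or sqrt(2)).  Ties in accumulated cost resolve to the lower
// seed label (lexicographic (cost, label) minimization, so the result is
// deterministic and matches an exhaustive relaxation fixpoint).

struct Node {
  double cost;
  int label;
  int idx;
};
struct NodeCmp {
  bool operator()(const Node &a, const Node &b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    return a.label > b.label;
  }
};

// [[Rcpp::export]]
IntegerMatrix propagate_dijkstra(NumericMatrix guide, IntegerMatrix seeds,
                                 LogicalMatrix mask, double lambda) {
  int nr = guide.nrow(), nc = guide.ncol(), n = nr * nc;
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> lab(n, 0);
  std::priority_queue<Node, std::vector<Node>, NodeCmp> pq;

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double l2 = lambda * lambda;

  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      int s = seeds(i, j);
      if (s > 0 && mask(i, j)) {
        int idx = i * nc + j;
        if (dist[idx] > 0.0 || s < lab[idx]) {
          dist[idx] = 0.0;
          lab[idx] = s;
        }
        pq.push({0.0, s, idx});
      }
    }

  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int idx = nd.idx;
    if (nd.cost != dist[idx] || nd.label != lab[idx]) continue;  // stale
    int pi = idx / nc, pj = idx % nc;
    double gp = guide(pi, pj);
    for (int t = 0; t < 8; ++t) {
      int qi = pi + dr[t], qj = pj + dc[t];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      if (!mask(qi, qj)) continue;
      int qidx = qi * nc + qj;
      double s2 = (dr[t] != 0 && dc[t] != 0) ? 2.0 : 1.0;
      double dI = std::fabs(guide(qi, qj) - gp);
      double step = std::sqrt(dI * dI + l2 * s2);
      double ncost = nd.cost + step;
      if (ncost < dist[qidx] ||
          (ncost == dist[qidx] && nd.label < lab[qidx])) {
        dist[qidx] = ncost;
        lab[qidx] = nd.label;
        pq.push({ncost, nd.label, qidx});
      }
    }
  }

  IntegerMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) out(i, j) = lab[i * nc + j];
  return out;
}
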