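#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra on the 8-connected grid graph.
//
// cost: per-cell traversal cost, NA = barrier (non-traversable).
// sources: 0-based column-major linear cell indices (must be traversable).
// cell_size: cell edge length; link length is cell_size for rook moves and
//   sqrt(2)*cell_size for diagonal moves.
// Link weight between adjacent traversable cells i, j is
//   ((cost_i + cost_j) / 2) * length(i, j),
// the standard cost-distance convention, so accumulated values are
// "weighted km" when cost is unitless and cell_size is km.
// A diagonal move is disallowed when BOTH cells orthogonally adjacent to the
// move are barriers (a "pinched" corner must not leak paths).
//
// Returns dist (accumulated cost-weighted distance, Inf = unreachable) and
// pred (0-based linear index of the predecessor on a least-cost route,
// -1 for sources and unreachable cells).
// [[Rcpp::export]]
List grid_cost_distance(NumericMatrix cost, IntegerVector sources,
                        double cell_size) {
  const int nr = cost.nrow(), nc = cost.ncol();
  const R_xlen_t n = (R_xlen_t)nr * nc;
  NumericVector dist(n, R_PosInf);
  IntegerVector pred(n, -1);

  typedef std::pair<double, int> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;

  for (int k = 0; k < sources.size(); ++k) {
    int s = sources[k];
    if (s < 0 || s >= n) stop("source index out of range");
    if (NumericVector::is_na(cost[s])) continue;  // barrier sources skipped
    dist[s] = 0.0;
    pq.push(QN(0.0, s));
  }
  if (pq.empty()) stop("all source cells lie on barriers");

  static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double rt2 = std::sqrt(2.0);

  while (!pq.empty()) {
    QN top = pq.top(); pq.pop();
    double d = top.first;
    int u = top.second;
    if (d > dist[u]) continue;
    int r = u % nr, c = u / nr;
    double vu = cost[u];
    for (int k = 0; k < 8; ++k) {
      int r2 = r + DR[k], c2 = c + DC[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int v = c2 * nr + r2;
      double vv = cost[v];
      if (NumericVector::is_na(vv)) continue;
      bool diag = (DR[k] != 0) && (DC[k] != 0);
      if (diag) {
        // orthogonal companions of the diagonal move
        double s1 = cost(r, c2), s2 = cost(r2, c);
        if (NumericVector::is_na(s1) && NumericVector::is_na(s2)) continue;
      }
      double len = (diag ? rt2 : 1.0) * cell_size;
      double nd = d + 0.5 * (vu + vv) * len;
      if (nd < dist[v]) {
        dist[v] = nd;
        pred[v] = u;
        pq.push(QN(nd, v));
      }
    }
  }

  dist.attr("dim") = Dimension(nr, nc);
  pred.attr("dim") = Dimension(nr, nc);
  return List::create(_["dist"] = dist, _["pred"] = pred);
}
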