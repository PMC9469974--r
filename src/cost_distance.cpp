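#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra over the 8-neighbour lattice of a resistance
// raster. Step cost between adjacent cells i, j is the mean of their
// resistances times the centre-to-centre distance (cell_size for rook
// moves, sqrt(2) * cell_size for diagonal moves) -- the usual GIS
// cost-surface convention. Non-finite resistance (nodata) is impassable.
//
// sources are 1-based column-major cell indices. Returns the cost-weighted
// distance surface (Inf where unreachable) and a 1-based back-link matrix
// (0 on sources, NA on unreachable cells) for least-cost-path
// reconstruction.
// [[Rcpp::export]]
List grid_cost_distance_cpp(NumericMatrix resistance, IntegerVector sources,
                            double cell_size) {
  const int nr = resistance.nrow(), nc = resistance.ncol();
  const int n = nr * nc;
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> back(n, NA_INTEGER);

  typedef std::pair<double, int> QItem;
  std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem> > pq;

  for (int k = 0; k < sources.size(); ++k) {
    int s = sources[k] - 1;
    if (s < 0 || s >= n) stop("source cell index out of range");
    if (!R_finite(resistance[s])) continue;  // sources on nodata are skipped
    if (dist[s] > 0.0) {
      dist[s] = 0.0;
      back[s] = 0;
      pq.push(QItem(0.0, s));
    }
  }

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double sqrt2 = std::sqrt(2.0);

  while (!pq.empty()) {
    double d = pq.top().first;
    int u = pq.top().second;
    pq.pop();
    if (d > dist[u]) continue;
    int ur = u % nr, uc = u / nr;
    double Ru = resistance[u];
    for (int k = 0; k < 8; ++k) {
      int vr = ur + dr[k], vc = uc + dc[k];
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      int v = vr + vc * nr;
      double Rv = resistance[v];
      if (!R_finite(Rv)) continue;
      double mult = (dr[k] != 0 && dc[k] != 0) ? sqrt2 : 1.0;
      double step = 0.5 * (Ru + Rv) * cell_size * mult;
      if (dist[u] + step < dist[v]) {
        dist[v] = dist[u] + step;
        back[v] = u + 1;
        pq.push(QItem(dist[v], v));
      }
    }
  }

  NumericMatrix cwd(nr, nc);
  IntegerMatrix bl(nr, nc);
  for (int i = 0; i < n; ++i) {
    cwd[i] = dist[i];
    bl[i] = back[i];
  }
  return List::create(Named("cwd") = cwd, Named("back") = bl);
}
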