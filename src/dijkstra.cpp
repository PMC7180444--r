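#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
using namespace Rcpp;

// Shortest left-to-right path on the pixel lattice of a gradient image.
//
// Nodes are pixels plus two virtual endpoints S (left) and T (right).
// Moves from a pixel: column-advancing {(+1c,-1r),(+1c,0),(+1c,+1r)} and
// vertical moves within a column {(+1r),(-1r)}. Edge weight between pixels
// a and b is 2 - (g_a + g_b) + w_min (strictly positive for g in [0,1]).
// S connects to every unblocked pixel of the first column and every
// unblocked pixel of the last column connects to T, both at cost w_min, so
// the path may start and end at any row. Ties in the priority queue are
// broken deterministically by (cost, row, col).
//
// [[Rcpp::export]]
List lattice_dijkstra(NumericMatrix grad, double w_min,
                      LogicalMatrix blocked) {
  const int H = grad.nrow(), W = grad.ncol();
  if (W < 2) stop("gradient image must have width >= 2");
  if (blocked.nrow() != H || blocked.ncol() != W)
    stop("blocked mask shape must match the gradient image");
  const int N = H * W;
  const int S = N, T = N + 1;
  std::vector<double> dist(N + 2, R_PosInf);
  std::vector<int> prev(N + 2, -1);

  typedef std::tuple<double, int, int, int> Node;  // cost, row, col, id
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  dist[S] = 0.0;
  pq.push(Node(0.0, -1, -1, S));

  const int dr[5] = {-1, 0, 1, -1, 1};
  const int dc[5] = { 1, 1, 1,  0, 0};

  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d = std::get<0>(top);
    int id = std::get<3>(top);
    if (d > dist[id]) continue;
    if (id == T) break;

    if (id == S) {
      for (int r = 0; r < H; ++r) {
        if (blocked(r, 0)) continue;
        int nid = r;  // column 0
        double nd = d + w_min;
        if (nd < dist[nid]) {
          dist[nid] = nd; prev[nid] = S;
          pq.push(Node(nd, r, 0, nid));
        }
      }
      continue;
    }
    int c = id / H, r = id % H;
    if (c == W - 1) {
      double nd = d + w_min;
      if (nd < dist[T]) {
        dist[T] = nd; prev[T] = id;
        pq.push(Node(nd, H, W, T));
      }
    }
    for (int k = 0; k < 5; ++k) {
      int nr = r + dr[k], nc = c + dc[k];
      if (nr < 0 || nr >= H || nc >= W) continue;
      if (blocked(nr, nc)) continue;
      double w = 2.0 - (grad(r, c) + grad(nr, nc)) + w_min;
      double nd = d + w;
      if (nd < dist[nc * H + nr]) {
        dist[nc * H + nr] = nd; prev[nc * H + nr] = id;
        pq.push(Node(nd, nr, nc, nc * H + nr));
      }
    }
  }

  if (!R_FINITE(dist[T]))
    stop("no feasible left-to-right path (blocked region spans a column)");

  std::vector<int> rows, cols;
  for (int id = prev[T]; id != S; id = prev[id]) {
    rows.push_back(id % H + 1);   // 1-based for R
    cols.push_back(id / H + 1);
  }
  const int n = rows.size();
  IntegerMatrix path(n, 2);
  for (int i = 0; i < n; ++i) {   // reverse into left-to-right order
    path(i, 0) = rows[n - 1 - i];
    path(i, 1) = cols[n - 1 - i];
  }
  return List::create(_["path"] = path, _["cost"] = dist[T]);
}
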