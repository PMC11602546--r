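#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Raster geodesic kernels shared by the mask-to-graph pipeline and the
// synthetic fixtures. Matrices are column-major (R layout); linear index
// id = r + c * nrow. All solvers stay strictly inside the supplied mask.

static const double INF = std::numeric_limits<double>::infinity();

struct QNode {
  double d;
  int label;  // tie-break: lower label wins
  int id;     // final tie-break: lower linear index
};
struct QCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.d != b.d) return a.d > b.d;
    if (a.label != b.label) return a.label > b.label;
    return a.id > b.id;
  }
};
typedef std::priority_queue<QNode, std::vector<QNode>, QCmp> MinHeap;

// First-order fast marching (Eikonal |grad T| = 1) on the 4-neighbour
// stencil, unit grid spacing. dist = 0 on source pixels; NA outside mask;
// +Inf for in-mask pixels unreachable from any source.
// [[Rcpp::export(name = ".cpp_fmm_distance")]]
NumericMatrix cpp_fmm_distance(LogicalMatrix mask, LogicalMatrix source) {
  int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  if (source.nrow() != nr || source.ncol() != nc)
    stop("mask and source shapes differ");
  NumericMatrix dist(nr, nc);
  std::vector<char> state(n, 0);  // 0 far, 1 trial, 2 accepted
  MinHeap heap;

  for (int i = 0; i < n; ++i) {
    if (!mask[i]) { dist[i] = NA_REAL; state[i] = 2; continue; }
    dist[i] = INF;
  }
  int nsrc = 0;
  for (int i = 0; i < n; ++i) {
    if (mask[i] && source[i]) {
      dist[i] = 0.0;
      state[i] = 1;
      heap.push(QNode{0.0, 0, i});
      ++nsrc;
    }
  }
  if (nsrc == 0) stop("no source pixels inside the mask");

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  while (!heap.empty()) {
    QNode top = heap.top();
    heap.pop();
    int id = top.id;
    if (state[id] == 2) continue;
    state[id] = 2;
    int r = id % nr, c = id / nr;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int jd = rr + cc * nr;
      if (!mask[jd] || state[jd] == 2) continue;
      // upwind neighbours of (rr, cc)
      double a = INF, b = INF;
      if (rr > 0 && mask[jd - 1] && state[jd - 1] == 2) a = std::min(a, dist[jd - 1]);
      if (rr + 1 < nr && mask[jd + 1] && state[jd + 1] == 2) a = std::min(a, dist[jd + 1]);
      if (cc > 0 && mask[jd - nr] && state[jd - nr] == 2) b = std::min(b, dist[jd - nr]);
      if (cc + 1 < nc && mask[jd + nr] && state[jd + nr] == 2) b = std::min(b, dist[jd + nr]);
      double cand;
      if (a > b) std::swap(a, b);
      if (b == INF) cand = a + 1.0;
      else if (b - a >= 1.0) cand = a + 1.0;
      else {
        double diff = a - b;
        cand = 0.5 * (a + b + std::sqrt(2.0 - diff * diff));
      }
      if (cand < dist[jd]) {
        dist[jd] = cand;
        state[jd] = 1;
        heap.push(QNode{cand, 0, jd});
      }
    }
  }
  return dist;
}

// Marker-controlled watershed by priority flooding of a basin (elevation)
// map, 4-connected, restricted to mask. Markers keep their labels; ties in
// elevation are resolved toward the lower label, then the lower index.
// [[Rcpp::export(name = ".cpp_priority_flood")]]
IntegerMatrix cpp_priority_flood(NumericMatrix basins, IntegerMatrix markers,
                                 LogicalMatrix mask) {
  int nr = basins.nrow(), nc = basins.ncol(), n = nr * nc;
  if (markers.nrow() != nr || markers.ncol() != nc ||
      mask.nrow() != nr || mask.ncol() != nc)
    stop("basins, markers and mask shapes differ");
  IntegerMatrix lab(nr, nc);
  MinHeap heap;
  int nmark = 0;
  for (int i = 0; i < n; ++i) {
    lab[i] = 0;
    if (mask[i] && markers[i] > 0) {
      lab[i] = markers[i];
      double h = basins[i];
      if (ISNAN(h)) h = 0.0;
      heap.push(QNode{h, markers[i], i});
      ++nmark;
    }
  }
  if (nmark == 0) stop("no marker pixels inside the mask");

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!heap.empty()) {
    QNode top = heap.top();
    heap.pop();
    int id = top.id;
    int r = id % nr, c = id / nr;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int jd = rr + cc * nr;
      if (!mask[jd] || lab[jd] != 0) continue;
      lab[jd] = lab[id];
      double h = basins[jd];
      if (ISNAN(h)) h = top.d;
      if (h < top.d) h = top.d;  // flood level never recedes
      heap.push(QNode{h, lab[jd], jd});
    }
  }
  return lab;
}

// Geodesic nearest-seed partition (in-mask Voronoi): multi-source Dijkstra
// on the 8-connected pixel lattice with weights 1 / sqrt(2), carrying seed
// labels. Equidistant ties go to the lower label.
// [[Rcpp::export(name = ".cpp_geodesic_voronoi")]]
List cpp_geodesic_voronoi(LogicalMatrix mask, IntegerMatrix seeds) {
  int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  if (seeds.nrow() != nr || seeds.ncol() != nc)
    stop("mask and seeds shapes differ");
  NumericMatrix dist(nr, nc);
  IntegerMatrix lab(nr, nc);
  MinHeap heap;
  int nseed = 0;
  for (int i = 0; i < n; ++i) {
    lab[i] = 0;
    if (!mask[i]) { dist[i] = NA_REAL; continue; }
    dist[i] = INF;
    if (seeds[i] > 0) {
      dist[i] = 0.0;
      lab[i] = seeds[i];
      heap.push(QNode{0.0, seeds[i], i});
      ++nseed;
    }
  }
  if (nseed == 0) stop("no seed pixels inside the mask");

  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const double SQRT2 = std::sqrt(2.0);
  std::vector<char> done(n, 0);
  while (!heap.empty()) {
    QNode top = heap.top();
    heap.pop();
    int id = top.id;
    if (done[id]) continue;
    done[id] = 1;
    lab[id] = top.label;
    int r = id % nr, c = id / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int jd = rr + cc * nr;
      if (!mask[jd] || done[jd]) continue;
      double w = (k < 4) ? 1.0 : SQRT2;
      double cand = top.d + w;
      if (cand < dist[jd] ||
          (cand == dist[jd] && top.label < lab[jd]) ||
          (cand == dist[jd] && lab[jd] == 0)) {
        dist[jd] = cand;
        lab[jd] = top.label;
        heap.push(QNode{cand, top.label, jd});
      }
    }
  }
  return List::create(_["dist"] = dist, _["label"] = lab);
}
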