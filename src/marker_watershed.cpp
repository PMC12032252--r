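#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Marker-based watershed by priority flooding (Meyer's algorithm).
// Labels grow outward from the supplied markers across the masked region in
// order of increasing elevation; for nuclei splitting the elevation is the
// negated Euclidean distance transform, so basins flood from the distance
// peaks down to the touching ridges. Ties are broken by insertion order,
// which makes the result deterministic for a fixed input.
struct QItem {
  double elev;
  long long order;
  int idx;
  int label;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;   // lower elevation first
    return a.order > b.order;                        // then FIFO
  }
};

// [[Rcpp::export(name = ".marker_watershed_cpp")]]
IntegerMatrix marker_watershed_cpp(NumericMatrix elev, IntegerMatrix markers,
                                   LogicalMatrix mask) {
  const int nr = elev.nrow(), nc = elev.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc ||
      mask.nrow() != nr || mask.ncol() != nc)
    stop("marker_watershed: input shapes differ");

  IntegerMatrix out(nr, nc);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long long counter = 0;

  // 8-connected neighborhood
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j) && markers(i, j) > 0)
        out(i, j) = markers(i, j);

  // seed the queue with unlabeled masked neighbors of marker pixels
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (out(i, j) <= 0) continue;
      for (int k = 0; k < 8; ++k) {
        int ni = i + dr[k], nj = j + dc[k];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        if (!mask(ni, nj) || out(ni, nj) > 0) continue;
        pq.push({elev(ni, nj), counter++, ni + nj * nr, out(i, j)});
      }
    }

  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    int i = it.idx % nr, j = it.idx / nr;
    if (out(i, j) > 0) continue;   // already claimed
    out(i, j) = it.label;
    for (int k = 0; k < 8; ++k) {
      int ni = i + dr[k], nj = j + dc[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (!mask(ni, nj) || out(ni, nj) > 0) continue;
      pq.push({elev(ni, nj), counter++, ni + nj * nr, it.label});
    }
  }
  return out;
}
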