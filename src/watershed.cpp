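#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 4-connected component labelling of a binary H x W matrix.
// Labels are consecutive 1..n in raster (column-major) order of first pixel.
// [[Rcpp::export]]
IntegerMatrix label_components_4(const IntegerMatrix& bin) {
  const int H = bin.nrow(), W = bin.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (bin(y, x) == 0 || lab(y, x) != 0) continue;
      ++next;
      stack.push_back(y + x * H);
      lab(y, x) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int py = p % H, px = p / H;
        const int ny[4] = {py - 1, py + 1, py, py};
        const int nx[4] = {px, px, px - 1, px + 1};
        for (int d = 0; d < 4; ++d) {
          if (ny[d] < 0 || ny[d] >= H || nx[d] < 0 || nx[d] >= W) continue;
          if (bin(ny[d], nx[d]) != 0 && lab(ny[d], nx[d]) == 0) {
            lab(ny[d], nx[d]) = next;
            stack.push_back(ny[d] + nx[d] * H);
          }
        }
      }
    }
  }
  return lab;
}

struct QItem {
  double prio;
  long order;
  int pos;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;  // lowest relief first
    return a.order > b.order;                      // FIFO tie-break
  }
};

// Meyer's flooding watershed from labelled markers over a relief surface.
// markers: 0 = to be flooded, >0 = seed labels. Pixels where floods from two
// different labels meet become ridge pixels and are returned as 0.
// [[Rcpp::export]]
IntegerMatrix marker_watershed(const NumericMatrix& relief,
                               const IntegerMatrix& markers) {
  const int H = relief.nrow(), W = relief.ncol();
  if (markers.nrow() != H || markers.ncol() != W)
    stop("relief and markers must have identical dimensions");
  IntegerMatrix lab(H, W);
  std::vector<char> inq(H * W, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> q;
  long order = 0;
  const int RIDGE = -1;

  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      lab(y, x) = markers(y, x);

  auto push_neighbours = [&](int py, int px) {
    const int ny[4] = {py - 1, py + 1, py, py};
    const int nx[4] = {px, px, px - 1, px + 1};
    for (int d = 0; d < 4; ++d) {
      if (ny[d] < 0 || ny[d] >= H || nx[d] < 0 || nx[d] >= W) continue;
      const int p = ny[d] + nx[d] * H;
      if (lab(ny[d], nx[d]) == 0 && !inq[p]) {
        inq[p] = 1;
        q.push({relief(ny[d], nx[d]), order++, p});
      }
    }
  };

  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      if (lab(y, x) > 0) push_neighbours(y, x);

  while (!q.empty()) {
    const QItem it = q.top();
    q.pop();
    const int py = it.pos % H, px = it.pos / H;
    if (lab(py, px) != 0) continue;
    const int ny[4] = {py - 1, py + 1, py, py};
    const int nx[4] = {px, px, px - 1, px + 1};
    int found = 0;
    bool ridge = false;
    for (int d = 0; d < 4; ++d) {
      if (ny[d] < 0 || ny[d] >= H || nx[d] < 0 || nx[d] >= W) continue;
      const int l = lab(ny[d], nx[d]);
      if (l > 0) {
        if (found == 0) found = l;
        else if (found != l) ridge = true;
      }
    }
    if (ridge) {
      lab(py, px) = RIDGE;
    } else if (found > 0) {
      lab(py, px) = found;
      push_neighbours(py, px);
    }
    // found == 0 can only happen for pixels queued from a ridge; leave at 0
  }

  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      if (lab(y, x) == RIDGE) lab(y, x) = 0;
  return lab;
}
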