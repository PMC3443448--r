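// Low-level morphological engines used by the segmentation and fusion stages.
// All routines are deterministic: ties in flooding order are broken by
// insertion sequence, which itself follows column-major (R) pixel order.

#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {

struct QItem {
  double value;      // flooding priority (gray level)
  long long seq;     // insertion order, breaks gray-level ties
  int idx;           // linear pixel index
  int label;         // label of the pixel that inserted this one
};

struct QItemCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.value != b.value) return a.value > b.value;  // min-heap on value
    return a.seq > b.seq;                              // then FIFO
  }
};

// neighbour offsets for a 2D grid in fixed scan order: up, down, left, right
// (8-connectivity appends the four diagonals)
inline int neighbours2d(int idx, int nr, int nc, int conn, int* out) {
  int r = idx % nr, c = idx / nr, n = 0;
  if (r > 0)      out[n++] = idx - 1;
  if (r < nr - 1) out[n++] = idx + 1;
  if (c > 0)      out[n++] = idx - nr;
  if (c < nc - 1) out[n++] = idx + nr;
  if (conn == 8) {
    if (r > 0      && c > 0)      out[n++] = idx - 1 - nr;
    if (r > 0      && c < nc - 1) out[n++] = idx - 1 + nr;
    if (r < nr - 1 && c > 0)      out[n++] = idx + 1 - nr;
    if (r < nr - 1 && c < nc - 1) out[n++] = idx + 1 + nr;
  }
  return n;
}

} // namespace

//' @name cpp_marker_watershed
//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_marker_watershed(NumericMatrix img, IntegerMatrix seeds,
                                   int connectivity = 4) {
  const int nr = img.nrow(), nc = img.ncol(), np = nr * nc;
  if (seeds.nrow() != nr || seeds.ncol() != nc)
    stop("seed matrix must match image dimensions");
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");

  IntegerVector lab(np, 0);
  std::priority_queue<QItem, std::vector<QItem>, QItemCmp> pq;
  long long seq = 0;
  int nb[8];

  for (int i = 0; i < np; ++i) lab[i] = seeds[i];
  // seed the frontier in column-major order
  for (int i = 0; i < np; ++i) {
    if (lab[i] <= 0) continue;
    int nn = neighbours2d(i, nr, nc, connectivity, nb);
    for (int k = 0; k < nn; ++k) {
      int j = nb[k];
      if (lab[j] == 0) pq.push(QItem{img[j], seq++, j, lab[i]});
    }
  }
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    if (lab[it.idx] != 0) continue;
    lab[it.idx] = it.label;
    int nn = neighbours2d(it.idx, nr, nc, connectivity, nb);
    for (int k = 0; k < nn; ++k) {
      int j = nb[k];
      if (lab[j] == 0) pq.push(QItem{img[j], seq++, j, it.label});
    }
  }
  IntegerMatrix out(nr, nc);
  for (int i = 0; i < np; ++i) out[i] = lab[i];
  return out;
}

//' Greyscale reconstruction by dilation (Vincent's hybrid algorithm).
//' marker must be <= mask everywhere; result is the largest image <= mask
//' whose regional maxima are controlled by marker.
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask,
                                     int connectivity = 4) {
  const int nr = marker.nrow(), nc = marker.ncol(), np = nr * nc;
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask must share dimensions");
  NumericVector J(np);
  for (int i = 0; i < np; ++i) {
    if (marker[i] > mask[i]) stop("reconstruction requires marker <= mask");
    J[i] = marker[i];
  }
  int nb[8];
  // forward raster sweep (column-major): propagate from already-visited side
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    int i = c * nr + r;
    double v = J[i];
    if (r > 0 && J[i - 1] > v) v = J[i - 1];
    if (c > 0 && J[i - nr] > v) v = J[i - nr];
    if (connectivity == 8) {
      if (r > 0 && c > 0 && J[i - 1 - nr] > v) v = J[i - 1 - nr];
      if (r < nr - 1 && c > 0 && J[i + 1 - nr] > v) v = J[i + 1 - nr];
    }
    if (v > mask[i]) v = mask[i];
    J[i] = v;
  }
  // backward sweep + queue of pixels that can still propagate
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c) for (int r = nr - 1; r >= 0; --r) {
    int i = c * nr + r;
    double v = J[i];
    if (r < nr - 1 && J[i + 1] > v) v = J[i + 1];
    if (c < nc - 1 && J[i + nr] > v) v = J[i + nr];
    if (connectivity == 8) {
      if (r < nr - 1 && c < nc - 1 && J[i + 1 + nr] > v) v = J[i + 1 + nr];
      if (r > 0 && c < nc - 1 && J[i - 1 + nr] > v) v = J[i - 1 + nr];
    }
    if (v > mask[i]) v = mask[i];
    J[i] = v;
    int nn = neighbours2d(i, nr, nc, connectivity, nb);
    for (int k = 0; k < nn; ++k) {
      int j = nb[k];
      if (J[j] < J[i] && J[j] < mask[j]) { fifo.push(i); break; }
    }
  }
  while (!fifo.empty()) {
    int i = fifo.front(); fifo.pop();
    int nn = neighbours2d(i, nr, nc, connectivity, nb);
    for (int k = 0; k < nn; ++k) {
      int j = nb[k];
      if (J[j] < J[i] && mask[j] != J[j]) {
        double v = J[i] < mask[j] ? J[i] : mask[j];
        if (v > J[j]) { J[j] = v; fifo.push(j); }
      }
    }
  }
  NumericMatrix out(nr, nc);
  for (int i = 0; i < np; ++i) out[i] = J[i];
  return out;
}

//' Regional maxima of a 2D image, plateau-aware.
//' A plateau (connected set of equal-valued pixels) is a regional maximum
//' iff no pixel bordering it is strictly higher.
//' @noRd
// [[Rcpp::export]]
LogicalMatrix cpp_regional_maxima(NumericMatrix img, int connectivity = 8) {
  const int nr = img.nrow(), nc = img.ncol(), np = nr * nc;
  std::vector<char> state(np, 0);  // 0 unvisited, 1 max plateau, 2 not max
  int nb[8];
  std::vector<int> plateau;
  std::queue<int> fifo;
  for (int start = 0; start < np; ++start) {
    if (state[start] != 0) continue;
    double v = img[start];
    bool is_max = true;
    plateau.clear();
    fifo.push(start);
    state[start] = 1;
    while (!fifo.empty()) {
      int i = fifo.front(); fifo.pop();
      plateau.push_back(i);
      int nn = neighbours2d(i, nr, nc, connectivity, nb);
      for (int k = 0; k < nn; ++k) {
        int j = nb[k];
        if (img[j] > v) is_max = false;
        else if (img[j] == v && state[j] == 0) { state[j] = 1; fifo.push(j); }
      }
    }
    if (!is_max)
      for (size_t k = 0; k < plateau.size(); ++k) state[plateau[k]] = 2;
  }
  LogicalMatrix out(nr, nc);
  for (int i = 0; i < np; ++i) out[i] = state[i] == 1;
  return out;
}

//' Flat greyscale dilation (op = 0) or erosion (op = 1) with an arbitrary
//' structuring element given as a logical matrix centred on its middle
//' pixel. Neighbourhoods are clipped at the image border (max/min over the
//' in-bounds support), so constants are fixed points of both operators.
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_morpho(NumericMatrix img, LogicalMatrix se, int op) {
  const int nr = img.nrow(), nc = img.ncol();
  const int sr = se.nrow(), sc = se.ncol();
  const int cr = sr / 2, cc = sc / 2;
  std::vector<int> dr, dc;
  for (int j = 0; j < sc; ++j) for (int i = 0; i < sr; ++i)
    if (se(i, j)) { dr.push_back(i - cr); dc.push_back(j - cc); }
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    double best = op == 0 ? R_NegInf : R_PosInf;
    for (size_t k = 0; k < dr.size(); ++k) {
      int rr = r + dr[k], cc2 = c + dc[k];
      if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
      double v = img(rr, cc2);
      if (op == 0) { if (v > best) best = v; }
      else         { if (v < best) best = v; }
    }
    out(r, c) = best;
  }
  return out;
}

//' Connected-component labelling of a 3D binary array (26- or 6-connectivity).
//' Components are numbered in order of their first voxel in column-major scan.
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector x, IntegerVector dims,
                          int connectivity = 26) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const long long np = (long long)n1 * n2 * n3;
  if ((long long)x.size() != np) stop("array size does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  IntegerVector lab(x.size(), 0);
  int next = 0;
  std::queue<long long> fifo;
  for (long long s = 0; s < np; ++s) {
    if (!x[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    fifo.push(s);
    while (!fifo.empty()) {
      long long i = fifo.front(); fifo.pop();
      int i1 = (int)(i % n1), rest = (int)(i / n1);
      int i2 = rest % n2, i3 = rest / n2;
      for (int d3 = -1; d3 <= 1; ++d3)
      for (int d2 = -1; d2 <= 1; ++d2)
      for (int d1 = -1; d1 <= 1; ++d1) {
        if (d1 == 0 && d2 == 0 && d3 == 0) continue;
        if (connectivity == 6 && (std::abs(d1) + std::abs(d2) + std::abs(d3)) != 1)
          continue;
        int j1 = i1 + d1, j2 = i2 + d2, j3 = i3 + d3;
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3)
          continue;
        long long j = (long long)(j3 * n2 + j2) * n1 + j1;
        if (x[j] && lab[j] == 0) { lab[j] = next; fifo.push(j); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
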