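#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// BFS connected-component labelling of a logical matrix.
// connectivity: 4 or 8. Background (FALSE/NA) gets label 0.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity = 4) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> qr, qc;
  qr.reserve(1024); qc.reserve(1024);
  const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1},
            dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  int ndir = connectivity == 8 ? 8 : 4;
  int next = 0;
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    if (mask(r, c) != TRUE || lab(r, c) != 0) continue;
    ++next;
    lab(r, c) = next;
    qr.clear(); qc.clear();
    qr.push_back(r); qc.push_back(c);
    size_t head = 0;
    while (head < qr.size()) {
      int cr = qr[head], cc2 = qc[head]; ++head;
      for (int k = 0; k < ndir; ++k) {
        int rr = cr + dr[k], cc3 = cc2 + dc[k];
        if (rr < 0 || rr >= nr || cc3 < 0 || cc3 >= nc) continue;
        if (mask(rr, cc3) == TRUE && lab(rr, cc3) == 0) {
          lab(rr, cc3) = next;
          qr.push_back(rr); qc.push_back(cc3);
        }
      }
    }
  }
  return lab;
}

// Fill holes: background regions not reachable from the image border
// (4-connectivity) become foreground.
// [[Rcpp::export(name = ".fill_holes")]]
LogicalMatrix fill_holes(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> outside((size_t)nr * nc, 0);
  std::vector<int> qr, qc;
  qr.reserve(2 * (nr + nc));
  qc.reserve(2 * (nr + nc));
  auto push_bg = [&](int r, int c) {
    size_t i = (size_t)c * nr + r;
    if (!outside[i] && mask(r, c) != TRUE) {
      outside[i] = 1;
      qr.push_back(r); qc.push_back(c);
    }
  };
  for (int r = 0; r < nr; ++r) { push_bg(r, 0); push_bg(r, nc - 1); }
  for (int c = 0; c < nc; ++c) { push_bg(0, c); push_bg(nr - 1, c); }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  size_t head = 0;
  while (head < qr.size()) {
    int cr = qr[head], cc2 = qc[head]; ++head;
    for (int k = 0; k < 4; ++k) {
      int rr = cr + dr[k], cc3 = cc2 + dc[k];
      if (rr < 0 || rr >= nr || cc3 < 0 || cc3 >= nc) continue;
      push_bg(rr, cc3);
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r)
    out(r, c) = (mask(r, c) == TRUE) || !outside[(size_t)c * nr + r];
  return out;
}

// Binary erosion with a 3x3 cross structuring element, repeated niter times.
// Pixels outside the image count as background.
// [[Rcpp::export(name = ".binary_erode")]]
LogicalMatrix binary_erode(LogicalMatrix mask, int niter = 1) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix cur = clone(mask);
  for (int it = 0; it < niter; ++it) {
    LogicalMatrix nxt(nr, nc);
    for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
      bool keep = cur(r, c) == TRUE &&
        r > 0 && cur(r - 1, c) == TRUE &&
        r < nr - 1 && cur(r + 1, c) == TRUE &&
        c > 0 && cur(r, c - 1) == TRUE &&
        c < nc - 1 && cur(r, c + 1) == TRUE;
      nxt(r, c) = keep;
    }
    cur = nxt;
  }
  return cur;
}
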