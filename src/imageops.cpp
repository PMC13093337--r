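#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Image primitives used by the nuclei and morpho modules: connected-component
// labelling, marker-seeded watershed (priority flood, highest intensity
// first), and Moore-neighbour boundary tracing for contour extraction.

static const int DR8[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DC8[8] = {0, 1, 1, 1, 0, -1, -1, -1};  // N NE E SE S SW W NW

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int nnb = (connectivity == 8) ? 8 : 4;
  static const int DR4[4] = {-1, 1, 0, 0};
  static const int DC4[4] = {0, 0, -1, 1};
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> cur = q.front();
        q.pop();
        for (int k = 0; k < nnb; ++k) {
          int rr = cur.first + ((connectivity == 8) ? DR8[k] : DR4[k]);
          int cc = cur.second + ((connectivity == 8) ? DC8[k] : DC4[k]);
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

struct WsEntry {
  double h;
  long order;
  int r, c, label;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.h != b.h) return a.h < b.h;  // max-heap on height
    return a.order > b.order;          // FIFO among equal heights
  }
};

// Flood the masked domain downhill from the markers; each unlabelled pixel
// joins the basin of the first (highest) front that reaches it.
// [[Rcpp::export]]
IntegerMatrix watershed_cpp(NumericMatrix height, IntegerMatrix markers,
                            LogicalMatrix mask) {
  int nr = height.nrow(), nc = height.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long order = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) > 0 && mask(r, c)) {
        lab(r, c) = markers(r, c);
        WsEntry e = {height(r, c), order++, r, c, markers(r, c)};
        pq.push(e);
      }
  while (!pq.empty()) {
    WsEntry e = pq.top();
    pq.pop();
    for (int k = 0; k < 8; ++k) {
      int rr = e.r + DR8[k], cc = e.c + DC8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (mask(rr, cc) && !lab(rr, cc)) {
        lab(rr, cc) = e.label;
        WsEntry ne = {height(rr, cc), order++, rr, cc, e.label};
        pq.push(ne);
      }
    }
  }
  return lab;
}

// Ordered outer boundary of the (single-component) mask, Moore tracing with
// Jacob's stopping criterion. Returns 1-based (row, col) pairs.
// [[Rcpp::export]]
IntegerMatrix trace_boundary_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (mask(r, c)) {
        sr = r;
        sc = c;
        break;
      }
  if (sr < 0) return IntegerMatrix(0, 2);

  std::vector<int> rows, cols;
  int cr = sr, cc = sc;
  int bd = 6;  // backtrack direction: W (scan order guarantees W is bg)
  const int bd0 = bd;
  rows.push_back(cr);
  cols.push_back(cc);
  long maxiter = 8L * (long)nr * nc + 8;
  for (long it = 0; it < maxiter; ++it) {
    int d = (bd + 1) % 8;
    int found = -1, lastbg_r = cr + DR8[bd], lastbg_c = cc + DC8[bd];
    for (int k = 0; k < 8; ++k, d = (d + 1) % 8) {
      int rr = cr + DR8[d], ccol = cc + DC8[d];
      bool fg = (rr >= 0 && rr < nr && ccol >= 0 && ccol < nc) &&
                mask(rr, ccol);
      if (fg) {
        found = d;
        break;
      }
      lastbg_r = rr;
      lastbg_c = ccol;
    }
    if (found < 0) break;  // isolated pixel
    cr = cr + DR8[found];
    cc = cc + DC8[found];
    // new backtrack = last background checked (8-adjacent to new pixel)
    int nbd = -1;
    for (int k = 0; k < 8; ++k)
      if (cr + DR8[k] == lastbg_r && cc + DC8[k] == lastbg_c) {
        nbd = k;
        break;
      }
    if (nbd < 0) nbd = (found + 4) % 8;  // defensive; should not happen
    bd = nbd;
    if (cr == sr && cc == sc && bd == bd0) break;
    rows.push_back(cr);
    cols.push_back(cc);
  }
  IntegerMatrix out((int)rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i] + 1;
    out(i, 1) = cols[i] + 1;
  }
  return out;
}
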