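// Hydrological operators: priority-flood sink filling, Freeman
// multiple-flow-direction accumulation and D8 downstream flow-path length.
#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

struct Cell {
  double z;
  int idx;
  long order;  // FIFO tie-break for stable pop order
};
struct CellCmp {
  bool operator()(const Cell& a, const Cell& b) const {
    if (a.z != b.z) return a.z > b.z;
    return a.order > b.order;
  }
};

// Priority-flood with epsilon drainage enforcement: every cell ends with a
// strictly descending path to the boundary (or to nodata, treated as an
// outlet). Output >= input everywhere.
// [[Rcpp::export]]
NumericMatrix fill_sinks_cpp(NumericMatrix z, double eps) {
  const int nr = z.nrow(), nc = z.ncol(), n = nr * nc;
  NumericMatrix out(nr, nc);
  std::vector<char> seen(n, 0);
  std::priority_queue<Cell, std::vector<Cell>, CellCmp> pq;
  long ord = 0;
  auto push = [&](int r, int c, double zz) {
    int i = r + c * nr;
    if (seen[i]) return;
    seen[i] = 1;
    out(r, c) = zz;
    pq.push({zz, i, ord++});
  };
  // seed: boundary cells, nodata cells (outlets) and their neighbours
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v = z(r, c);
      if (!R_finite(v)) {
        int i = r + c * nr;
        seen[i] = 1;
        out(r, c) = NA_REAL;
      }
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v = z(r, c);
      if (!R_finite(v)) continue;
      bool edge = (r == 0 || r == nr - 1 || c == 0 || c == nc - 1);
      if (!edge) {
        for (int k = 0; k < 8 && !edge; ++k) {
          int rr = r + DR[k], cc = c + DC[k];
          if (!R_finite(z(rr, cc))) edge = true;  // drains into nodata
        }
      }
      if (edge) push(r, c, v);
    }
  while (!pq.empty()) {
    Cell cur = pq.top();
    pq.pop();
    int r = cur.idx % nr, c = cur.idx / nr;
    double zc = out(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int i = rr + cc * nr;
      if (seen[i]) continue;
      double zn = z(rr, cc);
      double lvl = zc + eps;
      push(rr, cc, zn > lvl ? zn : lvl);
    }
  }
  return out;
}

// Freeman multiple-flow-direction accumulation (exponent p) on a
// sink-filled surface. Returns accumulated area in cell units (>= 1,
// including the cell itself).
// [[Rcpp::export]]
NumericMatrix mfd_accum_cpp(NumericMatrix z, double cs, double p) {
  const int nr = z.nrow(), nc = z.ncol(), n = nr * nc;
  NumericMatrix acc(nr, nc);
  std::vector<int> idx;
  idx.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (R_finite(z[i])) { idx.push_back(i); acc[i] = 1.0; }
    else acc[i] = NA_REAL;
  }
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return z[a] > z[b]; });
  const double diag = cs * std::sqrt(2.0);
  for (int i : idx) {
    int r = i % nr, c = i / nr;
    double z0 = z(r, c);
    double w[8], sw = 0.0;
    for (int k = 0; k < 8; ++k) {
      w[k] = 0.0;
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      double v = z(rr, cc);
      if (!R_finite(v) || v >= z0) continue;
      double d = (DR[k] && DC[k]) ? diag : cs;
      w[k] = std::pow((z0 - v) / d, p);
      sw += w[k];
    }
    if (sw <= 0) continue;  // pit or boundary outlet: flow leaves the grid
    double a = acc(r, c);
    for (int k = 0; k < 8; ++k)
      if (w[k] > 0) acc(r + DR[k], c + DC[k]) += a * w[k] / sw;
  }
  return acc;
}

// D8 downstream flow-path length (metres) to the grid edge or to an
// unresolvable pit; boundary cells are 0 by convention.
// [[Rcpp::export]]
NumericMatrix d8_fpl_cpp(NumericMatrix z, double cs) {
  const int nr = z.nrow(), nc = z.ncol(), n = nr * nc;
  NumericMatrix fpl(nr, nc);
  std::vector<int> idx;
  idx.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (R_finite(z[i])) idx.push_back(i);
    else fpl[i] = NA_REAL;
  }
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return z[a] < z[b]; });
  const double diag = cs * std::sqrt(2.0);
  for (int i : idx) {
    int r = i % nr, c = i / nr;
    if (r == 0 || r == nr - 1 || c == 0 || c == nc - 1) { fpl(r, c) = 0.0; continue; }
    double z0 = z(r, c), best = 0.0, bdist = 0.0;
    int br = -1, bc = -1;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      double v = z(rr, cc);
      if (!R_finite(v) || v >= z0) continue;
      double d = (DR[k] && DC[k]) ? diag : cs;
      double s = (z0 - v) / d;
      if (s > best) { best = s; br = rr; bc = cc; bdist = d; }
    }
    if (br < 0) { fpl(r, c) = 0.0; continue; }  // pit: path ends here
    double down = fpl(br, bc);
    fpl(r, c) = (R_finite(down) ? down : 0.0) + bdist;
  }
  return fpl;
}
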