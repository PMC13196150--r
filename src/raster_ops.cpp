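#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Neighbor offsets; first 4 entries are the 4-connected cross.
static const int DR[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// Connected-component labeling of a logical mask. Labels are assigned in
// row-major scan order (lowest row, then lowest column, first), so the
// result is deterministic. connectivity is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int nn = (connectivity == 4) ? 4 : 8;
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r * nc + c);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pr = p / nc, pc = p % nc;
        for (int k = 0; k < nn; ++k) {
          const int qr = pr + DR[k], qc = pc + DC[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr * nc + qc);
          }
        }
      }
    }
  }
  return lab;
}

// Iterated binary erosion. Structuring element: 3x3 square (8-connected
// neighborhood) or 3x3 cross when diamond = true. Pixels outside the image
// count as background, so objects touching the border erode there too.
// [[Rcpp::export]]
LogicalMatrix cpp_erode(const LogicalMatrix& mask, int cycles, bool diamond) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int nn = diamond ? 4 : 8;
  LogicalMatrix cur = clone(mask);
  for (int it = 0; it < cycles; ++it) {
    LogicalMatrix nxt(nr, nc);
    bool any = false;
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        if (!cur(r, c)) { nxt(r, c) = false; continue; }
        bool keep = true;
        for (int k = 0; k < nn && keep; ++k) {
          const int qr = r + DR[k], qc = c + DC[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc || !cur(qr, qc))
            keep = false;
        }
        nxt(r, c) = keep;
        any = any || keep;
      }
    }
    cur = nxt;
    if (!any) break;
  }
  return cur;
}

// Fill holes: background components not connected to the image border become
// foreground. Background connectivity follows the global convention (8).
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int nn = (connectivity == 4) ? 4 : 8;
  LogicalMatrix reached(nr, nc);
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (r != 0 && r != nr - 1 && c != 0 && c != nc - 1) continue;
      if (!mask(r, c) && !reached(r, c)) {
        reached(r, c) = true;
        stack.push_back(r * nc + c);
        while (!stack.empty()) {
          const int p = stack.back(); stack.pop_back();
          const int pr = p / nc, pc = p % nc;
          for (int k = 0; k < nn; ++k) {
            const int qr = pr + DR[k], qc = pc + DC[k];
            if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
            if (!mask(qr, qc) && !reached(qr, qc)) {
              reached(qr, qc) = true;
              stack.push_back(qr * nc + qc);
            }
          }
        }
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = mask(r, c) || !reached(r, c);
  return out;
}

// Median filter over a discrete disk {(dr,dc): dr^2 + dc^2 <= radius^2}.
// Boundary mode: reflect (edge pixel duplicated), matching the Gaussian blur.
// [[Rcpp::export]]
NumericMatrix cpp_disk_median(const NumericMatrix& img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dr, dc;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { dr.push_back(a); dc.push_back(b); }
  const int m = (int)dr.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(m);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      for (int k = 0; k < m; ++k) {
        int qr = r + dr[k], qc = c + dc[k];
        while (qr < 0 || qr >= nr) qr = (qr < 0) ? -qr - 1 : 2 * nr - 1 - qr;
        while (qc < 0 || qc >= nc) qc = (qc < 0) ? -qc - 1 : 2 * nc - 1 - qc;
        buf[k] = img(qr, qc);
      }
      std::sort(buf.begin(), buf.end());
      out(r, c) = (m % 2 == 1) ? buf[m / 2]
                               : 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
    }
  }
  return out;
}

// Local maxima with plateau collapse: a pixel is a candidate when no
// 8-neighbor is strictly greater; an equal-value connected component (8) is a
// maximum when all its pixels are candidates, and contributes one seed at its
// row-major-first ("top-left") pixel.
// [[Rcpp::export]]
LogicalMatrix cpp_local_maxima(const NumericMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix seed(nr, nc);
  std::vector<char> visited((size_t)nr * nc, 0);
  std::vector<int> stack, comp;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (visited[(size_t)r * nc + c]) continue;
      const double v = img(r, c);
      bool is_max = true;
      comp.clear();
      stack.clear();
      visited[(size_t)r * nc + c] = 1;
      stack.push_back(r * nc + c);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        comp.push_back(p);
        const int pr = p / nc, pc = p % nc;
        for (int k = 0; k < 8; ++k) {
          const int qr = pr + DR[k], qc = pc + DC[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          const double w = img(qr, qc);
          if (w > v) is_max = false;
          else if (w == v && !visited[(size_t)qr * nc + qc]) {
            visited[(size_t)qr * nc + qc] = 1;
            stack.push_back(qr * nc + qc);
          }
        }
      }
      if (is_max) {
        // row-major-first member of the component
        int best = comp[0];
        for (size_t i = 1; i < comp.size(); ++i)
          if (comp[i] < best) best = comp[i];
        seed(best / nc, best % nc) = true;
      }
    }
  }
  return seed;
}

struct GrowItem {
  long long d2;
  int label;
  int idx;
};
struct GrowCmp {
  bool operator()(const GrowItem& a, const GrowItem& b) const {
    if (a.d2 != b.d2) return a.d2 > b.d2;
    if (a.label != b.label) return a.label > b.label;
    return a.idx > b.idx;
  }
};

// Voronoi-like expansion of labeled seeds across a foreground mask:
// foreground pixels are claimed in order of increasing squared Euclidean
// distance to the claiming seed (ties: lower label, then row-major index),
// expanding through 8-connected foreground only. Foreground components that
// contain no seed remain background.
// [[Rcpp::export]]
IntegerMatrix cpp_seed_grow(const IntegerMatrix& seeds, const LogicalMatrix& fg) {
  const int nr = seeds.nrow(), nc = seeds.ncol();
  const int nlab = max(seeds);
  IntegerMatrix out(nr, nc);
  if (nlab <= 0) return out;
  std::vector<int> sr(nlab + 1, 0), sc(nlab + 1, 0);
  std::priority_queue<GrowItem, std::vector<GrowItem>, GrowCmp> pq;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (seeds(r, c) > 0 && fg(r, c)) {
        const int l = seeds(r, c);
        sr[l] = r; sc[l] = c;
        pq.push({0LL, l, r * nc + c});
      }
  while (!pq.empty()) {
    const GrowItem it = pq.top(); pq.pop();
    const int pr = it.idx / nc, pc = it.idx % nc;
    if (out(pr, pc) != 0) continue;
    out(pr, pc) = it.label;
    for (int k = 0; k < 8; ++k) {
      const int qr = pr + DR[k], qc = pc + DC[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      if (!fg(qr, qc) || out(qr, qc) != 0) continue;
      const long long dy = qr - sr[it.label], dx = qc - sc[it.label];
      pq.push({dy * dy + dx * dx, it.label, qr * nc + qc});
    }
  }
  return out;
}
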