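#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// All rasters are R matrices (column-major, nrow = image rows).
// Connectivity throughout is 8 (basins are compact fiber cross-sections).

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Grayscale reconstruction by dilation of `marker` under `mask`
// (Vincent 1993 hybrid algorithm, 8-connectivity). Requires marker <= mask.
// h-minima and h-maxima transforms are derived from this in R via negation.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix J(clone(marker));
  // raster scan: N+ = neighbours already visited in raster order
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = J(r, c);
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (cc < c || (cc == c && rr < r)) { // visited before (r,c) scanning col-major
          if (J(rr, cc) > m) m = J(rr, cc);
        }
      }
      J(r, c) = std::min(m, mask(r, c));
    }
  }
  // anti-raster scan + queue initialisation
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double m = J(r, c);
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (cc > c || (cc == c && rr > r)) {
          if (J(rr, cc) > m) m = J(rr, cc);
        }
      }
      J(r, c) = std::min(m, mask(r, c));
      // queue pixels with a lagging N- neighbour
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (cc > c || (cc == c && rr > r)) {
          if (J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) {
            fifo.push(c * nr + r);
            break;
          }
        }
      }
    }
  }
  // queue propagation
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int r = p % nr, c = p / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < J(r, c) && mask(rr, cc) != J(rr, cc)) {
        double v = std::min(J(r, c), mask(rr, cc));
        if (v > J(rr, cc)) {
          J(rr, cc) = v;
          fifo.push(cc * nr + rr);
        }
      }
    }
  }
  return J;
}

// Regional minima of a grayscale image, 8-connectivity.
// Returns integer matrix: 0 = not a minimum, k > 0 = plateau id of the k-th
// regional minimum (plateaus of equal value with no lower neighbour).
// [[Rcpp::export]]
IntegerMatrix cpp_regional_minima(NumericMatrix im) {
  int nr = im.nrow(), nc = im.ncol();
  IntegerMatrix lab(nr, nc); // 0 = unvisited here; -1 marks visited non-min
  std::vector<int> stack;
  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (lab(r0, c0) != 0) continue;
      double v = im(r0, c0);
      // BFS over the equal-value plateau
      stack.clear();
      stack.push_back(c0 * nr + r0);
      lab(r0, c0) = -2; // provisional plateau mark
      bool is_min = true;
      std::vector<int> members;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        members.push_back(p);
        int r = p % nr, c = p / nr;
        for (int k = 0; k < 8; ++k) {
          int rr = r + DR[k], cc = c + DC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          double w = im(rr, cc);
          if (w < v) is_min = false;
          else if (w == v && lab(rr, cc) == 0) {
            lab(rr, cc) = -2;
            stack.push_back(cc * nr + rr);
          }
        }
      }
      int mark = is_min ? ++next : -1;
      for (size_t i = 0; i < members.size(); ++i) {
        int p = members[i];
        lab(p % nr, p / nr) = mark;
      }
    }
  }
  for (int i = 0; i < nr * nc; ++i) if (lab[i] < 0) lab[i] = 0;
  return lab;
}

struct QEntry {
  double value;
  unsigned long order;
  int idx;
};
struct QCompare {
  bool operator()(const QEntry &a, const QEntry &b) const {
    if (a.value != b.value) return a.value > b.value; // min-heap on intensity
    return a.order > b.order;                         // FIFO within a level
  }
};

// Meyer flooding watershed from the regional minima of `im`.
// Output: 0 on watershed ridge pixels, k > 0 basin labels.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix im) {
  int nr = im.nrow(), nc = im.ncol();
  IntegerMatrix lab = cpp_regional_minima(im); // seeds
  std::vector<char> queued(static_cast<size_t>(nr) * nc, 0);
  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
  unsigned long order = 0;
  const int WSHED = -1;
  // queue unlabelled neighbours of seed basins
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) <= 0) continue;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int q = cc * nr + rr;
        if (lab(rr, cc) == 0 && !queued[q]) {
          queued[q] = 1;
          pq.push({im(rr, cc), order++, q});
        }
      }
    }
  }
  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    int r = e.idx % nr, c = e.idx / nr;
    if (lab(r, c) != 0) continue;
    int found = 0; bool conflict = false;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int l = lab(rr, cc);
      if (l > 0) {
        if (found == 0) found = l;
        else if (l != found) conflict = true;
      }
    }
    lab(r, c) = conflict ? WSHED : (found > 0 ? found : WSHED);
    if (lab(r, c) > 0) {
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int q = cc * nr + rr;
        if (lab(rr, cc) == 0 && !queued[q]) {
          queued[q] = 1;
          pq.push({im(rr, cc), order++, q});
        }
      }
    }
  }
  for (int i = 0; i < nr * nc; ++i) if (lab[i] == WSHED) lab[i] = 0;
  return lab;
}

// Connected-component labelling of a logical matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix bin, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  int nr = bin.nrow(), nc = bin.ncol();
  IntegerMatrix lab(nr, nc);
  int nn = connectivity;
  const int D4R[4] = {-1, 0, 0, 1}, D4C[4] = {0, -1, 1, 0};
  std::vector<int> stack;
  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!bin(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      stack.clear();
      stack.push_back(c0 * nr + r0);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int r = p % nr, c = p / nr;
        for (int k = 0; k < nn; ++k) {
          int rr = r + (nn == 8 ? DR[k] : D4R[k]);
          int cc = c + (nn == 8 ? DC[k] : D4C[k]);
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (bin(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(cc * nr + rr);
          }
        }
      }
    }
  }
  return lab;
}

static void edt_1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  // Felzenszwalb & Huttenlocher lower envelope of parabolas
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in pixels) from every pixel to the nearest TRUE
// (feature) pixel. Pixels with no feature anywhere get Inf.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix features) {
  int nr = features.nrow(), nc = features.ncol();
  const double INF = 1e20;
  NumericMatrix g(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // columns first
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = features(r, c) ? 0.0 : INF;
    edt_1d(f, d, nr);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    edt_1d(f, d, nc);
    for (int c = 0; c < nc; ++c) g(r, c) = d[c];
  }
  for (int i = 0; i < nr * nc; ++i)
    g[i] = g[i] >= INF ? R_PosInf : std::sqrt(g[i]);
  return g;
}

// Label every pixel with the index (1-based) of its nearest seed point.
// Seeds in pixel coordinates (row, col), 1-based from R.
// [[Rcpp::export]]
IntegerMatrix cpp_nearest_seed(int nr, int nc, NumericVector seed_row, NumericVector seed_col) {
  int n = seed_row.size();
  if (n == 0) stop("no seeds");
  IntegerMatrix lab(nr, nc);
  for (int c = 0; c < nc; ++c) {
    double x = c + 1.0;
    for (int r = 0; r < nr; ++r) {
      double y = r + 1.0;
      double best = std::numeric_limits<double>::infinity();
      int bi = 1;
      for (int i = 0; i < n; ++i) {
        double dy = y - seed_row[i], dx = x - seed_col[i];
        double d = dy * dy + dx * dx;
        if (d < best) { best = d; bi = i + 1; }
      }
      lab(r, c) = bi;
    }
  }
  return lab;
}

// TRUE where a positive label touches a pixel of a different label,
// background (0), or the image edge — the per-fiber boundary set used by
// the centrally-nucleated-fiber border distance.
// [[Rcpp::export]]
LogicalMatrix cpp_label_boundary(IntegerMatrix lab) {
  int nr = lab.nrow(), nc = lab.ncol();
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l <= 0) continue;
      bool b = (r == 0 || r == nr - 1 || c == 0 || c == nc - 1);
      for (int k = 0; !b && k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (lab(rr, cc) != l) b = true;
      }
      out(r, c) = b;
    }
  }
  return out;
}

// Ridge pixels (label 0) adjacent to at least `min_labels` distinct positive
// labels — used to paint segmentation boundaries on overlays.
// [[Rcpp::export]]
LogicalMatrix cpp_ridge_pixels(IntegerMatrix lab, int min_labels) {
  int nr = lab.nrow(), nc = lab.ncol();
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) != 0) continue;
      int seen[8];
      int nseen = 0;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int l = lab(rr, cc);
        if (l <= 0) continue;
        bool isnew = true;
        for (int j = 0; j < nseen; ++j) if (seen[j] == l) { isnew = false; break; }
        if (isnew) seen[nseen++] = l;
      }
      out(r, c) = nseen >= min_labels;
    }
  }
  return out;
}
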