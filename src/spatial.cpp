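#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Cell-list helpers for planar point sets (coordinates in nm).

namespace {

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  }
  void unite(int a, int b) {
    a = find(a);
    b = find(b);
    if (a != b) parent[b] = a;
  }
};

inline long long cell_key(long long cx, long long cy) {
  return (cx << 32) ^ (cy & 0xffffffffLL);
}

typedef std::unordered_map<long long, std::vector<int> > CellMap;

CellMap build_cells(const NumericVector &x, const NumericVector &y, double h) {
  CellMap cells;
  int n = x.size();
  for (int i = 0; i < n; ++i) {
    long long cx = (long long)std::floor(x[i] / h);
    long long cy = (long long)std::floor(y[i] / h);
    cells[cell_key(cx, cy)].push_back(i);
  }
  return cells;
}

} // namespace

// Single-linkage components under distance <= cutoff (ties link).
// [[Rcpp::export]]
IntegerVector link_points_cpp(NumericVector x, NumericVector y, double cutoff) {
  int n = x.size();
  if (n == 0) return IntegerVector(0);
  UnionFind uf(n);
  double h = cutoff;
  double c2 = cutoff * cutoff;
  CellMap cells = build_cells(x, y, h);
  for (CellMap::const_iterator it = cells.begin(); it != cells.end(); ++it) {
    long long key = it->first;
    long long cx = key >> 32;
    long long cy = (int)(key & 0xffffffffLL);
    const std::vector<int> &pts = it->second;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        CellMap::const_iterator jt = cells.find(cell_key(cx + dx, cy + dy));
        if (jt == cells.end()) continue;
        const std::vector<int> &qts = jt->second;
        for (size_t a = 0; a < pts.size(); ++a) {
          int i = pts[a];
          for (size_t b = 0; b < qts.size(); ++b) {
            int j = qts[b];
            if (j <= i) continue;
            double ddx = x[i] - x[j], ddy = y[i] - y[j];
            if (ddx * ddx + ddy * ddy <= c2) uf.unite(i, j);
          }
        }
      }
    }
  }
  // relabel roots 1..k in order of first appearance
  IntegerVector lab(n);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    std::unordered_map<int, int>::iterator f = remap.find(r);
    if (f == remap.end()) {
      remap[r] = ++next;
      lab[i] = next;
    } else {
      lab[i] = f->second;
    }
  }
  return lab;
}

// All pairwise distances <= max_distance (each unordered pair once).
// [[Rcpp::export]]
NumericVector pair_distances_cpp(NumericVector x, NumericVector y,
                                 double max_distance) {
  std::vector<double> out;
  double h = max_distance;
  double m2 = max_distance * max_distance;
  CellMap cells = build_cells(x, y, h);
  for (CellMap::const_iterator it = cells.begin(); it != cells.end(); ++it) {
    long long key = it->first;
    long long cx = key >> 32;
    long long cy = (int)(key & 0xffffffffLL);
    const std::vector<int> &pts = it->second;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        CellMap::const_iterator jt = cells.find(cell_key(cx + dx, cy + dy));
        if (jt == cells.end()) continue;
        const std::vector<int> &qts = jt->second;
        for (size_t a = 0; a < pts.size(); ++a) {
          int i = pts[a];
          for (size_t b = 0; b < qts.size(); ++b) {
            int j = qts[b];
            if (j <= i) continue;
            double ddx = x[i] - x[j], ddy = y[i] - y[j];
            double d2 = ddx * ddx + ddy * ddy;
            if (d2 <= m2) out.push_back(std::sqrt(d2));
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return NumericVector(out.begin(), out.end());
}

// Nearest-neighbor distance for each point (brute force O(n^2)).
// [[Rcpp::export]]
NumericVector nnd_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  NumericVector out(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
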