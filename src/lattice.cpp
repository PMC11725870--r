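#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sticky excluded-volume random walk on a rectangular grid.
//
// Each sweep updates every particle once in a freshly shuffled order. A
// particle draws one of {stay, up, down, left, right} with weights
// {w, 1, 1, 1, 1}, where w = w_bound if it has at least one occupied
// 4-neighbor and w_free otherwise. A draw into an occupied or out-of-bounds
// site becomes a stay (with periodic boundaries, out-of-bounds wraps
// instead). Uses R's RNG so set.seed() controls trajectories.

namespace {

struct Grid {
  int width, height;
  bool periodic;
  std::vector<int> occ; // particle index + 1, 0 = empty
  std::vector<int> row, col;

  Grid(int w, int h, bool per, const IntegerVector &r0, const IntegerVector &c0)
      : width(w), height(h), periodic(per), occ(w * h, 0) {
    int n = r0.size();
    row.resize(n);
    col.resize(n);
    for (int i = 0; i < n; ++i) {
      row[i] = r0[i];
      col[i] = c0[i];
      int idx = row[i] * width + col[i];
      if (row[i] < 0 || row[i] >= height || col[i] < 0 || col[i] >= width)
        stop("particle outside grid");
      if (occ[idx] != 0) stop("two particles on one site");
      occ[idx] = i + 1;
    }
  }

  inline bool occupied(int r, int c) const {
    if (periodic) {
      r = (r + height) % height;
      c = (c + width) % width;
    } else if (r < 0 || r >= height || c < 0 || c >= width) {
      return false; // walls are not "neighbors"
    }
    return occ[r * width + c] != 0;
  }

  inline bool has_neighbor(int i) const {
    int r = row[i], c = col[i];
    return occupied(r - 1, c) || occupied(r + 1, c) ||
           occupied(r, c - 1) || occupied(r, c + 1);
  }

  // attempt a move of particle i by (dr, dc); blocked moves are no-ops
  inline void try_move(int i, int dr, int dc) {
    int r = row[i] + dr, c = col[i] + dc;
    if (periodic) {
      r = (r + height) % height;
      c = (c + width) % width;
    } else if (r < 0 || r >= height || c < 0 || c >= width) {
      return;
    }
    int to = r * width + c;
    if (occ[to] != 0) return;
    occ[row[i] * width + col[i]] = 0;
    occ[to] = i + 1;
    row[i] = r;
    col[i] = c;
  }

  void sweep(double w_bound, double w_free, std::vector<int> &order) {
    int n = (int)row.size();
    // Fisher-Yates shuffle with R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int k = 0; k < n; ++k) {
      int i = order[k];
      double w = has_neighbor(i) ? w_bound : w_free;
      double u = unif_rand() * (w + 4.0);
      if (u < w) continue; // stay
      int dir = (int)(u - w);
      if (dir > 3) dir = 3;
      switch (dir) {
      case 0: try_move(i, -1, 0); break;
      case 1: try_move(i, 1, 0); break;
      case 2: try_move(i, 0, -1); break;
      default: try_move(i, 0, 1); break;
      }
    }
  }
};

// 4-connected components of occupied sites; returns per-particle labels 1..k
std::vector<int> component_labels(const Grid &g) {
  int n = (int)g.row.size();
  std::vector<int> lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  const int drs[4] = {-1, 1, 0, 0};
  const int dcs[4] = {0, 0, -1, 1};
  for (int i = 0; i < n; ++i) {
    if (lab[i]) continue;
    lab[i] = ++next;
    stack.push_back(i);
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      for (int d = 0; d < 4; ++d) {
        int r = g.row[p] + drs[d], c = g.col[p] + dcs[d];
        if (g.periodic) {
          r = (r + g.height) % g.height;
          c = (c + g.width) % g.width;
        } else if (r < 0 || r >= g.height || c < 0 || c >= g.width) {
          continue;
        }
        int q = g.occ[r * g.width + c];
        if (q != 0 && lab[q - 1] == 0) {
          lab[q - 1] = next;
          stack.push_back(q - 1);
        }
      }
    }
  }
  return lab;
}

} // namespace

// [[Rcpp::export]]
List lattice_run_cpp(int width, int height, IntegerVector row0, IntegerVector col0,
                     double w_bound, double w_free, int n_sweeps, int burn_in,
                     int sample_every, bool periodic, bool keep_states) {
  if (n_sweeps <= burn_in) stop("n_sweeps must exceed burn_in");
  Grid g(width, height, periodic, row0, col0);
  int n = row0.size();
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> hist(n + 1, 0.0);
  int n_samples = 0;
  List states;

  for (int s = 1; s <= n_sweeps; ++s) {
    g.sweep(w_bound, w_free, order);
    if (s > burn_in && (s - burn_in) % sample_every == 0) {
      std::vector<int> lab = component_labels(g);
      int k = 0;
      for (int i = 0; i < n; ++i) k = std::max(k, lab[i]);
      std::vector<int> csize(k + 1, 0);
      for (int i = 0; i < n; ++i) csize[lab[i]]++;
      for (int c = 1; c <= k; ++c) hist[csize[c]] += 1.0;
      ++n_samples;
      if (keep_states) {
        IntegerMatrix pos(n, 2);
        for (int i = 0; i < n; ++i) {
          pos(i, 0) = g.row[i];
          pos(i, 1) = g.col[i];
        }
        states.push_back(pos);
      }
    }
    if (s % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector h(hist.begin() + 1, hist.end());
  IntegerMatrix pos(n, 2);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = g.row[i];
    pos(i, 1) = g.col[i];
  }
  return List::create(_["hist_total"] = h, _["n_samples"] = n_samples,
                      _["final"] = pos, _["states"] = states);
}

// [[Rcpp::export]]
IntegerMatrix lattice_sweep_cpp(int width, int height, IntegerVector row0,
                                IntegerVector col0, double w_bound, double w_free,
                                bool periodic, int n_sweeps) {
  Grid g(width, height, periodic, row0, col0);
  int n = row0.size();
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  for (int s = 0; s < n_sweeps; ++s) g.sweep(w_bound, w_free, order);
  IntegerMatrix pos(n, 2);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = g.row[i];
    pos(i, 1) = g.col[i];
  }
  return pos;
}

// [[Rcpp::export]]
IntegerVector lattice_components_cpp(int width, int height, IntegerVector row0,
                                     IntegerVector col0, bool periodic) {
  Grid g(width, height, periodic, row0, col0);
  std::vector<int> lab = component_labels(g);
  return IntegerVector(lab.begin(), lab.end());
}
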