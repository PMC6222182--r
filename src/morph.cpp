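// Binary morphology on 3D grids: connected-component labeling and seeded
// region growing with a leakage guard.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static void neighbor_offsets(int connectivity, const int dim[3],
                             std::vector<long>& off,
                             std::vector<int>& di, std::vector<int>& dj,
                             std::vector<int>& dk) {
  const long sy = dim[0], sz = (long)dim[0] * dim[1];
  for (int z = -1; z <= 1; ++z)
    for (int y = -1; y <= 1; ++y)
      for (int x = -1; x <= 1; ++x) {
        if (x == 0 && y == 0 && z == 0) continue;
        int manh = std::abs(x) + std::abs(y) + std::abs(z);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back(x + (long)y * sy + (long)z * sz);
        di.push_back(x); dj.push_back(y); dk.push_back(z);
      }
}

// Label connected components of a logical mask. Returns integer array of
// labels (0 = background) with attribute "sizes".
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int dim[3] = {dims[0], dims[1], dims[2]};
  long n = (long)dim[0] * dim[1] * dim[2];
  std::vector<long> off; std::vector<int> di, dj, dk;
  neighbor_offsets(connectivity, dim, off, di, dj, dk);
  int nb = (int)off.size();

  IntegerVector lab(n, 0);
  std::vector<long> stack;
  std::vector<int> sizes;
  int cur = 0;
  const long sy = dim[0], sz = (long)dim[0] * dim[1];

  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    int count = 0;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      long p = stack.back(); stack.pop_back();
      ++count;
      int pi = (int)(p % sy), pj = (int)((p / sy) % dim[1]), pk = (int)(p / sz);
      for (int t = 0; t < nb; ++t) {
        int qi = pi + di[t], qj = pj + dj[t], qk = pk + dk[t];
        if (qi < 0 || qi >= dim[0] || qj < 0 || qj >= dim[1] ||
            qk < 0 || qk >= dim[2]) continue;
        long q = p + off[t];
        if (mask[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
      }
    }
    sizes.push_back(count);
  }
  lab.attr("dim") = dims;
  lab.attr("sizes") = IntegerVector(sizes.begin(), sizes.end());
  return lab;
}

// Seeded region growing: BFS over voxels with vol < thr, processed in
// frontier waves. A wave whose voxel gain exceeds leak_factor times the
// running median gain (after a warmup) aborts the growth: the classic
// lung-parenchyma explosion guard.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dims,
                              IntegerVector seed0, double thr,
                              int connectivity, double leak_factor) {
  int dim[3] = {dims[0], dims[1], dims[2]};
  long n = (long)dim[0] * dim[1] * dim[2];
  std::vector<long> off; std::vector<int> di, dj, dk;
  neighbor_offsets(connectivity, dim, off, di, dj, dk);
  int nb = (int)off.size();
  const long sy = dim[0], sz = (long)dim[0] * dim[1];

  LogicalVector out(n, false);
  long s = seed0[0] + (long)seed0[1] * sy + (long)seed0[2] * sz;
  bool aborted = false;
  if (seed0[0] < 0 || seed0[0] >= dim[0] || seed0[1] < 0 || seed0[1] >= dim[1] ||
      seed0[2] < 0 || seed0[2] >= dim[2])
    stop("seed outside volume");
  if (vol[s] < thr) {
    std::vector<long> frontier{ s }, next;
    out[s] = true;
    std::vector<double> gains;
    while (!frontier.empty()) {
      next.clear();
      for (long p : frontier) {
        int pi = (int)(p % sy), pj = (int)((p / sy) % dim[1]), pk = (int)(p / sz);
        for (int t = 0; t < nb; ++t) {
          int qi = pi + di[t], qj = pj + dj[t], qk = pk + dk[t];
          if (qi < 0 || qi >= dim[0] || qj < 0 || qj >= dim[1] ||
              qk < 0 || qk >= dim[2]) continue;
          long q = p + off[t];
          if (!out[q] && vol[q] < thr) { out[q] = true; next.push_back(q); }
        }
      }
      double gain = (double)next.size();
      if (gains.size() >= 5 && gain > 0) {
        std::vector<double> g(gains);
        std::nth_element(g.begin(), g.begin() + g.size() / 2, g.end());
        double med = g[g.size() / 2];
        if (med > 0 && gain > leak_factor * med) {
          for (long q : next) out[q] = false;  // drop the exploding wave
          aborted = true;
          break;
        }
      }
      gains.push_back(gain);
      frontier.swap(next);
    }
  }
  out.attr("dim") = dims;
  out.attr("aborted") = aborted;
  return out;
}

// Per-voxel count of 26-neighbors inside the mask (degree map for skeletons).
// [[Rcpp::export]]
IntegerVector cpp_neighbor_count(LogicalVector mask, IntegerVector dims) {
  int dim[3] = {dims[0], dims[1], dims[2]};
  long n = (long)dim[0] * dim[1] * dim[2];
  std::vector<long> off; std::vector<int> di, dj, dk;
  neighbor_offsets(26, dim, off, di, dj, dk);
  const long sy = dim[0], sz = (long)dim[0] * dim[1];
  IntegerVector out(n, 0);
  for (long p = 0; p < n; ++p) {
    if (!mask[p]) continue;
    int pi = (int)(p % sy), pj = (int)((p / sy) % dim[1]), pk = (int)(p / sz);
    int c = 0;
    for (size_t t = 0; t < off.size(); ++t) {
      int qi = pi + di[t], qj = pj + dj[t], qk = pk + dk[t];
      if (qi < 0 || qi >= dim[0] || qj < 0 || qj >= dim[1] ||
          qk < 0 || qk >= dim[2]) continue;
      if (mask[p + off[t]]) ++c;
    }
    out[p] = c;
  }
  out.attr("dim") = dims;
  return out;
}
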