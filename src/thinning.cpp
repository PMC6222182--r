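// 3D topology-preserving curve thinning.
//
// A border voxel is deleted when it is a simple point (deletion preserves
// both object 26-connectivity and background 6-connectivity; Bertrand &
// Malandain characterization on the 3x3x3 neighborhood) and not a curve
// endpoint (more than one 26-neighbor). Deletion proceeds in 6 directional
// subiterations (U/D/N/S/E/W borders) for medial positioning; within a pass
// voxels are removed sequentially, which is unconditionally topology-safe.

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// local 3x3x3 cube indexing: c = (x+1) + 3*(y+1) + 9*(z+1), center c = 13
static inline int cube_idx(int x, int y, int z) {
  return (x + 1) + 3 * (y + 1) + 9 * (z + 1);
}

// Condition A: exactly one 26-connected component of object voxels in N26*.
static bool one_object_component(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int c = 0; c < 27; ++c) {
    if (c == 13 || !nb[c] || seen[c]) continue;
    ++comps;
    if (comps > 1) return false;
    int top = 0;
    stack[top++] = c; seen[c] = true;
    while (top > 0) {
      int p = stack[--top];
      int px = p % 3 - 1, py = (p / 3) % 3 - 1, pz = p / 9 - 1;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int qx = px + dx, qy = py + dy, qz = pz + dz;
            if (qx < -1 || qx > 1 || qy < -1 || qy > 1 || qz < -1 || qz > 1)
              continue;
            int q = cube_idx(qx, qy, qz);
            if (q == 13 || !nb[q] || seen[q]) continue;
            seen[q] = true; stack[top++] = q;
          }
    }
  }
  return comps == 1;
}

// Condition B: exactly one 6-connected component of background voxels in the
// 18-neighborhood that is 6-adjacent to the center.
static bool one_background_component(const bool nb[27]) {
  // membership in N18: exclude corners (|x|=|y|=|z|=1) and center
  bool in18[27];
  for (int c = 0; c < 27; ++c) {
    int x = c % 3 - 1, y = (c / 3) % 3 - 1, z = c / 9 - 1;
    int ax = x ? 1 : 0, ay = y ? 1 : 0, az = z ? 1 : 0;
    in18[c] = (c != 13) && (ax + ay + az <= 2);
  }
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int c = 0; c < 27; ++c) {
    if (!in18[c] || nb[c] || seen[c]) continue;
    // start BFS only from face-neighbors of the center
    int x = c % 3 - 1, y = (c / 3) % 3 - 1, z = c / 9 - 1;
    if (std::abs(x) + std::abs(y) + std::abs(z) != 1) continue;
    ++comps;
    if (comps > 1) return false;
    int top = 0;
    stack[top++] = c; seen[c] = true;
    while (top > 0) {
      int p = stack[--top];
      int px = p % 3 - 1, py = (p / 3) % 3 - 1, pz = p / 9 - 1;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int t = 0; t < 6; ++t) {
        int qx = px + d6[t][0], qy = py + d6[t][1], qz = pz + d6[t][2];
        if (qx < -1 || qx > 1 || qy < -1 || qy > 1 || qz < -1 || qz > 1)
          continue;
        int q = cube_idx(qx, qy, qz);
        if (!in18[q] || nb[q] || seen[q]) continue;
        seen[q] = true; stack[top++] = q;
      }
    }
  }
  return comps == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dims) {
  int dim[3] = {dims[0], dims[1], dims[2]};
  long n = (long)dim[0] * dim[1] * dim[2];
  const long sy = dim[0], sz = (long)dim[0] * dim[1];
  std::vector<char> m(n);
  for (long i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

  std::vector<long> obj;
  for (long i = 0; i < n; ++i) if (m[i]) obj.push_back(i);

  auto at = [&](int x, int y, int z) -> bool {
    if (x < 0 || x >= dim[0] || y < 0 || y >= dim[1] || z < 0 || z >= dim[2])
      return false;
    return m[x + (long)y * sy + (long)z * sz] != 0;
  };

  auto fill_cube = [&](int x, int y, int z, bool nb[27]) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[cube_idx(dx, dy, dz)] = at(x + dx, y + dy, z + dz);
  };

  auto n26 = [&](int x, int y, int z) -> int {
    int c = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          if (at(x + dx, y + dy, z + dz)) ++c;
        }
    return c;
  };

  const int dirs[6][3] = {{0,0,1},{0,0,-1},{0,1,0},{0,-1,0},{1,0,0},{-1,0,0}};
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      std::vector<long> cand;
      for (long p : obj) {
        if (!m[p]) continue;
        int x = (int)(p % sy), y = (int)((p / sy) % dim[1]), z = (int)(p / sz);
        if (!at(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2]))
          cand.push_back(p);
      }
      for (long p : cand) {
        if (!m[p]) continue;
        int x = (int)(p % sy), y = (int)((p / sy) % dim[1]), z = (int)(p / sz);
        int cnt = n26(x, y, z);
        if (cnt <= 1) continue;  // endpoint or isolated: keep
        fill_cube(x, y, z, nb);
        if (one_object_component(nb) && one_background_component(nb)) {
          m[p] = 0;
          changed = true;
        }
      }
    }
    // compact the object list occasionally
    std::vector<long> keep;
    keep.reserve(obj.size());
    for (long p : obj) if (m[p]) keep.push_back(p);
    obj.swap(keep);
  }

  LogicalVector out(n, false);
  for (long p : obj) out[p] = true;
  out.attr("dim") = dims;
  return out;
}
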