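// Iso-surface extraction by marching tetrahedra: each grid cell (cube of 8
// voxel centers) is split into 6 tetrahedra around the main diagonal; surface
// vertices are interpolated on sign-change edges and deduplicated by edge.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vol, IntegerVector dims, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const long sy = nx, sz = (long)nx * ny;

  // cube corner offsets: c0..c7 with bit0 = x, bit1 = y, bit2 = z
  const int co[8][3] = {{0,0,0},{1,0,0},{0,1,0},{1,1,0},
                        {0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  // 6 tetrahedra sharing diagonal c0-c7
  const int tets[6][4] = {{0,1,3,7},{0,3,2,7},{0,2,6,7},
                          {0,6,4,7},{0,4,5,7},{0,5,1,7}};

  std::vector<double> vx, vy, vzc;
  std::vector<int> fa, fb, fc;
  std::unordered_map<uint64_t, int> edge_vertex;

  auto vert_on_edge = [&](long ga, long gb, double va, double vb) -> int {
    uint64_t key = ga < gb
      ? ((uint64_t)ga << 32) | (uint64_t)gb
      : ((uint64_t)gb << 32) | (uint64_t)ga;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - va) / (vb - va);
    int ax = (int)(ga % sy), ay = (int)((ga / sy) % ny), az = (int)(ga / sz);
    int bx = (int)(gb % sy), by = (int)((gb / sy) % ny), bz = (int)(gb / sz);
    vx.push_back(ax + t * (bx - ax));
    vy.push_back(ay + t * (by - ay));
    vzc.push_back(az + t * (bz - az));
    int id = (int)vx.size();  // 1-based
    edge_vertex[key] = id;
    return id;
  };

  long gid[8];
  double val[8];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        for (int c = 0; c < 8; ++c) {
          gid[c] = (x + co[c][0]) + (long)(y + co[c][1]) * sy +
                   (long)(z + co[c][2]) * sz;
          val[c] = vol[gid[c]];
        }
        for (int t = 0; t < 6; ++t) {
          const int* tv = tets[t];
          int inside = 0, code = 0;
          for (int c = 0; c < 4; ++c)
            if (val[tv[c]] > iso) { ++inside; code |= (1 << c); }
          if (inside == 0 || inside == 4) continue;

          if (inside == 1 || inside == 3) {
            // single triangle around the odd vertex
            int odd = -1;
            for (int c = 0; c < 4; ++c) {
              bool in = (code >> c) & 1;
              if ((inside == 1 && in) || (inside == 3 && !in)) { odd = c; break; }
            }
            int vv[3], k = 0;
            for (int c = 0; c < 4; ++c) {
              if (c == odd) continue;
              vv[k++] = vert_on_edge(gid[tv[odd]], gid[tv[c]],
                                     val[tv[odd]], val[tv[c]]);
            }
            if (vv[0] != vv[1] && vv[1] != vv[2] && vv[0] != vv[2]) {
              fa.push_back(vv[0]); fb.push_back(vv[1]); fc.push_back(vv[2]);
            }
          } else {
            // two inside, two outside: quad split into two triangles
            int in[2], out[2], ni = 0, no = 0;
            for (int c = 0; c < 4; ++c) {
              if ((code >> c) & 1) in[ni++] = c; else out[no++] = c;
            }
            int e00 = vert_on_edge(gid[tv[in[0]]], gid[tv[out[0]]],
                                   val[tv[in[0]]], val[tv[out[0]]]);
            int e01 = vert_on_edge(gid[tv[in[0]]], gid[tv[out[1]]],
                                   val[tv[in[0]]], val[tv[out[1]]]);
            int e10 = vert_on_edge(gid[tv[in[1]]], gid[tv[out[0]]],
                                   val[tv[in[1]]], val[tv[out[0]]]);
            int e11 = vert_on_edge(gid[tv[in[1]]], gid[tv[out[1]]],
                                   val[tv[in[1]]], val[tv[out[1]]]);
            if (e00 != e01 && e01 != e10 && e00 != e10) {
              fa.push_back(e00); fb.push_back(e01); fc.push_back(e10);
            }
            if (e10 != e01 && e01 != e11 && e10 != e11) {
              fa.push_back(e10); fb.push_back(e01); fc.push_back(e11);
            }
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)fa.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = vx[i]; verts(i, 1) = vy[i]; verts(i, 2) = vzc[i];
  }
  IntegerMatrix faces(nf, 3);
  for (int i = 0; i < nf; ++i) {
    faces(i, 0) = fa[i]; faces(i, 1) = fb[i]; faces(i, 2) = fc[i];
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
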