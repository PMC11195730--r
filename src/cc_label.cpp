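#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Label connected components of a 3-D logical array.
// connectivity: 6, 18 or 26 (face / face+edge / face+edge+corner neighbours).
// Returns an integer array of the same shape; 0 = background, components
// numbered 1..k in first-voxel (column-major) order.
// [[Rcpp::export]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dim, int connectivity = 26) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  IntegerVector lab(n, 0);
  std::vector<int> parent;
  parent.reserve(1024);
  parent.push_back(0); // dummy so labels are 1-based

  // Two-pass: scan forward, merging with already-visited neighbours
  // (those with strictly smaller linear index).
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        R_xlen_t idx = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (mask[idx] == NA_LOGICAL || !mask[idx]) continue;
        int cur = 0;
        for (int dz = -1; dz <= 0; ++dz) {
          int zz = z + dz;
          if (zz < 0) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = x + dx;
              if (xx < 0 || xx >= nx) continue;
              int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
              if (manh == 0) continue;
              if (connectivity == 6 && manh > 1) continue;
              if (connectivity == 18 && manh > 2) continue;
              R_xlen_t nidx = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
              if (nidx >= idx) continue; // only already-visited
              int nl = lab[nidx];
              if (nl == 0) continue;
              if (cur == 0) cur = uf_find(parent, nl);
              else uf_union(parent, cur, nl);
            }
          }
        }
        if (cur == 0) {
          cur = (int)parent.size();
          parent.push_back(cur);
        }
        lab[idx] = uf_find(parent, cur);
      }
    }
  }

  // Second pass: flatten and renumber 1..k in order of first appearance.
  std::vector<int> remap(parent.size(), 0);
  int k = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (lab[i] == 0) continue;
    int r = uf_find(parent, lab[i]);
    if (remap[r] == 0) remap[r] = ++k;
    lab[i] = remap[r];
  }
  lab.attr("dim") = dim;
  lab.attr("n_components") = k;
  return lab;
}
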