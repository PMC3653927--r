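#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// union-find
static int uf_find(std::vector<int>& par, int a) {
  while (par[a] != a) { par[a] = par[par[a]]; a = par[a]; }
  return a;
}
static void uf_union(std::vector<int>& par, int a, int b) {
  a = uf_find(par, a); b = uf_find(par, b);
  if (a != b) par[std::max(a, b)] = std::min(a, b);
}

// Connected-component labeling of a binary grid under 8-connectivity,
// followed by merging of components whose minimum pixel-centre distance is
// <= merge_gap (metres, exact Euclidean on centres; transitive via
// union-find). Labels are assigned 1..P in row-major order of each
// component's first pixel; 0 = background.
// [[Rcpp::export(name = ".cc_label_merge")]]
IntegerMatrix cc_label_merge(const IntegerMatrix& grid, double pixel_size,
                             double merge_gap) {
  const int nr = grid.nrow(), nc = grid.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> comp_of; // nothing yet
  int ncomp = 0;
  std::vector<int> stack;
  stack.reserve(256);
  // flood fill, row-major seed order
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (grid(r, c) != 0 && lab(r, c) == 0) {
        ++ncomp;
        lab(r, c) = ncomp;
        stack.clear();
        stack.push_back(r * nc + c);
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          int cr = cur / nc, cc2 = cur % nc;
          for (int dr = -1; dr <= 1; ++dr) {
            for (int dc = -1; dc <= 1; ++dc) {
              if (dr == 0 && dc == 0) continue;
              int r2 = cr + dr, c2 = cc2 + dc;
              if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
              if (grid(r2, c2) != 0 && lab(r2, c2) == 0) {
                lab(r2, c2) = ncomp;
                stack.push_back(r2 * nc + c2);
              }
            }
          }
        }
      }
    }
  }
  if (ncomp == 0) return lab;

  if (merge_gap > 0 && ncomp > 1) {
    // boundary pixels only: the minimum inter-component distance is attained
    // between boundary pixels
    std::vector<int> br, bc, bl;
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        if (grid(r, c) == 0) continue;
        bool boundary = (r == 0 || r == nr - 1 || c == 0 || c == nc - 1);
        if (!boundary) {
          for (int dr = -1; dr <= 1 && !boundary; ++dr)
            for (int dc = -1; dc <= 1 && !boundary; ++dc)
              if (grid(r + dr, c + dc) == 0) boundary = true;
        }
        if (boundary) { br.push_back(r); bc.push_back(c); bl.push_back(lab(r, c)); }
      }
    }
    // spatial window search: centres are pixel_size apart, so only pixels
    // within ceil(gap/pixel_size) rows/cols can be within the gap
    const int R = (int)std::ceil(merge_gap / pixel_size + 1e-9);
    const double gap2 = (merge_gap / pixel_size) * (merge_gap / pixel_size)
                        + 1e-9; // squared, pixel units
    // index boundary pixels by cell row for windowed lookup
    std::vector<std::vector<int> > byrow(nr);
    for (size_t i = 0; i < br.size(); ++i) byrow[br[i]].push_back((int)i);
    std::vector<int> par(ncomp + 1);
    for (int i = 0; i <= ncomp; ++i) par[i] = i;
    for (size_t i = 0; i < br.size(); ++i) {
      int r0 = br[i], c0 = bc[i], l0 = bl[i];
      for (int r2 = r0; r2 <= std::min(nr - 1, r0 + R); ++r2) {
        const std::vector<int>& row = byrow[r2];
        for (size_t k = 0; k < row.size(); ++k) {
          int j = row[k];
          if (j <= (int)i && r2 == r0) continue; // forward half only
          if (bl[j] == l0) continue;
          double dr = r2 - r0, dc = bc[j] - c0;
          if (dc > R || dc < -R) continue;
          if (dr * dr + dc * dc <= gap2) uf_union(par, l0, bl[j]);
        }
      }
    }
    // relabel by row-major first pixel of each merged group
    std::vector<int> newlab(ncomp + 1, 0);
    int next = 0;
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        if (lab(r, c) == 0) continue;
        int root = uf_find(par, lab(r, c));
        if (newlab[root] == 0) newlab[root] = ++next;
      }
    }
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c)
        if (lab(r, c) != 0) lab(r, c) = newlab[uf_find(par, lab(r, c))];
  }
  return lab;
}
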