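#include <Rcpp.h>
using namespace Rcpp;

// Two-pass connected-component labelling with 8-connectivity (union-find).
// Returns an integer matrix: 0 = background, components numbered 1..k
// in raster order of first appearance after relabelling.

static int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];  // path halving
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int> &parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerMatrix label_components_8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0);  // 0 = background sentinel
  int next = 1;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      // previously visited 8-neighbours: (i-1,j), (i-1,j-1), (i,j-1), (i+1,j-1)
      int nb[4];
      int nn = 0;
      if (i > 0 && mask(i - 1, j)) nb[nn++] = lab(i - 1, j);
      if (j > 0) {
        if (i > 0 && mask(i - 1, j - 1)) nb[nn++] = lab(i - 1, j - 1);
        if (mask(i, j - 1)) nb[nn++] = lab(i, j - 1);
        if (i + 1 < nr && mask(i + 1, j - 1)) nb[nn++] = lab(i + 1, j - 1);
      }
      if (nn == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        int m = nb[0];
        for (int k = 1; k < nn; ++k) m = std::min(m, nb[k]);
        lab(i, j) = m;
        for (int k = 0; k < nn; ++k) unite(parent, m, nb[k]);
      }
    }
  }

  // second pass: resolve roots, relabel compactly
  std::vector<int> newlab(parent.size(), 0);
  int k = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = find_root(parent, l);
      if (newlab[r] == 0) newlab[r] = ++k;
      lab(i, j) = newlab[r];
    }
  }
  return lab;
}
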