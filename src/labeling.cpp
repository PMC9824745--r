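#include <Rcpp.h>
using namespace Rcpp;

// Two-pass union-find connected-component labeling on a binary matrix.
// Labels are renumbered consecutively in raster (column-major) order of
// first appearance, matching the deterministic ordering promised to callers.

static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int>& parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // index 0 unused (background)
  int next = 1;

  // first pass: column-major scan; neighbours already visited are those
  // above in the same column and in the previous column
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      int neigh[4] = {0, 0, 0, 0};
      int nn = 0;
      if (r > 0 && mask(r - 1, c)) neigh[nn++] = lab(r - 1, c);
      if (c > 0 && mask(r, c - 1)) neigh[nn++] = lab(r, c - 1);
      if (connectivity == 8 && c > 0) {
        if (r > 0 && mask(r - 1, c - 1)) neigh[nn++] = lab(r - 1, c - 1);
        if (r < nr - 1 && mask(r + 1, c - 1)) neigh[nn++] = lab(r + 1, c - 1);
      }
      for (int k = 0; k < nn; ++k)
        if (best == 0 || neigh[k] < best) best = neigh[k];
      if (best == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        lab(r, c) = best;
        for (int k = 0; k < nn; ++k) unite(parent, best, neigh[k]);
      }
    }
  }

  // second pass: resolve equivalences, renumber consecutively
  std::vector<int> newlab(next, 0);
  int out = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = find_root(parent, l);
      if (newlab[root] == 0) newlab[root] = ++out;
      lab(r, c) = newlab[root];
    }
  }
  return lab;
}
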