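#include <Rcpp.h>
using namespace Rcpp;

// Two-pass union-find connected-component labeling on a logical mask.
// connectivity: 4 (edge neighbors) or 8 (edge + diagonal neighbors).
// Labels are positive integers assigned in row-major order of each
// component's first cell (reading order: left to right, top to bottom);
// background cells get 0.

static int find_root(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void unite(std::vector<int>& parent, int a, int b) {
  a = find_root(parent, a);
  b = find_root(parent, b);
  if (a != b) parent[std::max(a, b)] = std::min(a, b);
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  int next = 0;

  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c)) continue;
      int best = 0;
      // scan already-visited neighbors (row-major order)
      int up = (r > 0 && mask(r - 1, c)) ? lab(r - 1, c) : 0;
      int left = (c > 0 && mask(r, c - 1)) ? lab(r, c - 1) : 0;
      int ul = 0, ur = 0;
      if (connectivity == 8) {
        ul = (r > 0 && c > 0 && mask(r - 1, c - 1)) ? lab(r - 1, c - 1) : 0;
        ur = (r > 0 && c < W - 1 && mask(r - 1, c + 1)) ? lab(r - 1, c + 1) : 0;
      }
      int nb[4] = {up, left, ul, ur};
      for (int k = 0; k < 4; ++k)
        if (nb[k] > 0 && (best == 0 || nb[k] < best)) best = nb[k];
      if (best == 0) {
        ++next;
        parent.push_back(next);
        lab(r, c) = next;
      } else {
        lab(r, c) = best;
        for (int k = 0; k < 4; ++k)
          if (nb[k] > 0) unite(parent, best, nb[k]);
      }
    }
  }

  // second pass: resolve equivalences and relabel compactly in order of
  // first appearance (row-major)
  std::vector<int> remap(next + 1, 0);
  int out_next = 0;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      if (!lab(r, c)) continue;
      int root = find_root(parent, lab(r, c));
      if (!remap[root]) remap[root] = ++out_next;
      lab(r, c) = remap[root];
    }
  return lab;
}
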