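#include <Rcpp.h>
using namespace Rcpp;

// Two-pass union-find connected-component labelling with selectable
// 4/8-connectivity. Labels are 1..n in first-encounter (column-major)
// order of their root pixel.

static int find_root(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(1024);
  std::vector<int> tmp((size_t) nr * nc, -1);  // provisional label per pixel
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      size_t idx = (size_t) c * nr + r;
      // neighbours already visited in column-major order
      int nbr[4][2] = {{r - 1, c}, {r, c - 1}, {r - 1, c - 1}, {r + 1, c - 1}};
      int nn = (connectivity == 8) ? 4 : 2;
      int lab_min = -1;
      int found[4]; int nf = 0;
      for (int k = 0; k < nn; ++k) {
        int rr = nbr[k][0], cc = nbr[k][1];
        if (rr < 0 || cc < 0 || rr >= nr) continue;
        if (!mask(rr, cc)) continue;
        int l = find_root(parent, tmp[(size_t) cc * nr + rr]);
        found[nf++] = l;
        if (lab_min < 0 || l < lab_min) lab_min = l;
      }
      if (lab_min < 0) {
        int fresh = (int) parent.size();
        parent.push_back(fresh);
        tmp[idx] = fresh;
      } else {
        tmp[idx] = lab_min;
        for (int k = 0; k < nf; ++k) parent[found[k]] = lab_min;
      }
    }
  }
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      size_t idx = (size_t) c * nr + r;
      int root = find_root(parent, tmp[idx]);
      if (remap[root] == 0) remap[root] = ++next;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}
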