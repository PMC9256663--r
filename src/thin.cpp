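#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen morphological thinning of a binary image, producing a
// one-pixel-wide, 8-connected skeleton. Pixels outside the image count as
// background. Each pass only revisits pixels whose neighbourhood changed
// (boundary candidates), so the cost scales with the object's perimeter
// times its half-width, not with image area.

static inline int px(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c);
}

static inline bool deletable(const IntegerMatrix &m, int r, int c, int sub) {
  // neighbours clockwise from north: p2..p9
  int p2 = px(m, r - 1, c),     p3 = px(m, r - 1, c + 1);
  int p4 = px(m, r, c + 1),     p5 = px(m, r + 1, c + 1);
  int p6 = px(m, r + 1, c),     p7 = px(m, r + 1, c - 1);
  int p8 = px(m, r, c - 1),     p9 = px(m, r - 1, c - 1);
  int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
  if (B < 2 || B > 6) return false;
  int n[8] = {p2, p3, p4, p5, p6, p7, p8, p9};
  int A = 0;
  for (int k = 0; k < 8; ++k)
    if (n[k] == 0 && n[(k + 1) % 8] == 1) ++A;
  if (A != 1) return false;
  if (sub == 0)
    return p2 * p4 * p6 == 0 && p4 * p6 * p8 == 0;
  return p2 * p4 * p8 == 0 && p2 * p6 * p8 == 0;
}

// [[Rcpp::export(name = ".thin_zhangsuen")]]
IntegerMatrix thin_zhangsuen(IntegerMatrix input) {
  IntegerMatrix m = clone(input);
  int nr = m.nrow(), nc = m.ncol();
  std::vector<int> cand, next_cand, del;
  std::vector<char> in_cand((size_t) nr * nc, 0);
  cand.reserve(4096); next_cand.reserve(4096); del.reserve(4096);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (m(r, c)) {
        int idx = c * nr + r;
        cand.push_back(idx);
        in_cand[idx] = 1;
      }
  bool changed = true;
  std::vector<int> del_round;
  del_round.reserve(4096);
  while (changed) {
    changed = false;
    del_round.clear();
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (size_t k = 0; k < cand.size(); ++k) {
        int idx = cand[k];
        int r = idx % nr, c = idx / nr;
        if (m(r, c) && deletable(m, r, c, sub)) del.push_back(idx);
      }
      if (!del.empty()) {
        changed = true;
        for (size_t k = 0; k < del.size(); ++k) {
          m(del[k] % nr, del[k] / nr) = 0;
          del_round.push_back(del[k]);
        }
      }
    }
    // next round revisits only surviving pixels adjacent to a deletion
    next_cand.clear();
    for (size_t k = 0; k < cand.size(); ++k) in_cand[cand[k]] = 0;
    for (size_t k = 0; k < del_round.size(); ++k) {
      int idx = del_round[k];
      int r = idx % nr, c = idx / nr;
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
          if (!m(rr, cc)) continue;
          int nidx = cc * nr + rr;
          if (!in_cand[nidx]) {
            in_cand[nidx] = 1;
            next_cand.push_back(nidx);
          }
        }
      }
    }
    cand.swap(next_cand);
  }
  return m;
}
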