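#include <Rcpp.h>
using namespace Rcpp;

// Union of filled discs, used to rasterize a tube swept along a spine.
// Centres and radii are in (possibly fractional) pixel units, 1-based.

// [[Rcpp::export(name = ".stamp_discs")]]
LogicalMatrix stamp_discs(int nr, int nc, NumericVector r0, NumericVector c0,
                          NumericVector radius) {
  LogicalMatrix m(nr, nc);
  for (int k = 0; k < r0.size(); ++k) {
    double rr = r0[k], cc = c0[k], rad = radius[k];
    double rad2 = rad * rad;
    int rlo = std::max(0, (int) std::floor(rr - rad) - 1);
    int rhi = std::min(nr - 1, (int) std::ceil(rr + rad));
    int clo = std::max(0, (int) std::floor(cc - rad) - 1);
    int chi = std::min(nc - 1, (int) std::ceil(cc + rad));
    for (int c = clo; c <= chi; ++c) {
      double dc = (c + 1) - cc;
      for (int r = rlo; r <= rhi; ++r) {
        double dr = (r + 1) - rr;
        if (dr * dr + dc * dc <= rad2) m(r, c) = true;
      }
    }
  }
  return m;
}
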