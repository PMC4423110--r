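#include <Rcpp.h>
using namespace Rcpp;

// Local-linear smoother for per-CpG methylation estimates.
//
// At each CpG the smallest symmetric (in CpG count) window holding at
// least min_cpgs sites and spanning at least min_window_bp is selected
// (clipped and re-balanced at chromosome ends), and a weighted linear
// trend is fit with tricube distance weights times the per-site weight
// (read coverage).  The fitted value at the site is returned.  Positions
// must be sorted; call per chromosome.
//
// [[Rcpp::export(name = ".smooth_llin_cpp")]]
NumericVector smooth_llin_cpp(NumericVector pos, NumericVector y,
                              NumericVector wt, int min_cpgs,
                              double min_window_bp) {
  const int n = pos.size();
  NumericVector out(n);
  if (n == 0) return out;
  const int half = (min_cpgs - 1) / 2;

  for (int i = 0; i < n; ++i) {
    int j0 = i - half, j1 = i + half;
    if (min_cpgs % 2 == 0) ++j1;
    if (j0 < 0) { j1 -= j0; j0 = 0; }
    if (j1 > n - 1) { j0 -= j1 - (n - 1); j1 = n - 1; if (j0 < 0) j0 = 0; }
    // grow until the bp span reaches min_window_bp (or the chrom ends)
    while (pos[j1] - pos[j0] < min_window_bp && (j0 > 0 || j1 < n - 1)) {
      double dl = j0 > 0 ? pos[i] - pos[j0 - 1] : R_PosInf;
      double dr = j1 < n - 1 ? pos[j1 + 1] - pos[i] : R_PosInf;
      if (dl <= dr) --j0; else ++j1;
    }
    double h = std::max(pos[i] - pos[j0], pos[j1] - pos[i]);
    if (h <= 0) h = 1.0;
    h *= 1.0001;  // keep endpoint weights positive

    double s0 = 0, s1 = 0, s2 = 0, t0 = 0, t1 = 0;
    for (int j = j0; j <= j1; ++j) {
      if (NumericVector::is_na(y[j])) continue;
      double d = (pos[j] - pos[i]) / h;
      double a = 1.0 - std::abs(d) * std::abs(d) * std::abs(d);
      double w = a * a * a * wt[j];
      if (w <= 0) continue;
      double x = pos[j] - pos[i];
      s0 += w; s1 += w * x; s2 += w * x * x;
      t0 += w * y[j]; t1 += w * x * y[j];
    }
    if (s0 <= 0) { out[i] = NA_REAL; continue; }
    double det = s0 * s2 - s1 * s1;
    if (det <= 1e-12 * s0 * s2 || s2 == 0) {
      out[i] = t0 / s0;               // degenerate spread: weighted mean
    } else {
      // intercept of the weighted linear fit centred at pos[i]
      out[i] = (s2 * t0 - s1 * t1) / det;
    }
  }
  return out;
}
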