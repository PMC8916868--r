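#include <Rcpp.h>
using namespace Rcpp;

// Patch-search NLM pass over a pre-padded image.
//
// padded: (h + 2*pad) x (w + 2*pad), pad = patch_radius + search_radius
// mu:     h x w per-pixel filter parameter (adaptive variants pass a map)
// gk:     (2p+1) x (2p+1) Gaussian kernel over patch offsets, sums to 1
// gamma:  exponent of the cosine-similarity factor ((1 + S_c)/2)^gamma;
//         gamma == 0 skips the patch-statistics accumulation entirely
// center_rule: 0 = max_other, 1 = one, 2 = zero
//
// The cosine similarity S_c is computed on mean-centered raw patch vectors
// (uniform weights). Near-constant patches are detected with a relative
// tolerance: both constant -> S_c = 1, exactly one constant -> S_c = 0.
// [[Rcpp::export]]
NumericMatrix nlm_filter_cpp(const NumericMatrix& padded, int h, int w,
                             int p, int s, const NumericMatrix& mu,
                             double gamma, const NumericMatrix& gk,
                             int center_rule) {
  const int pad = p + s;
  const double n = (2 * p + 1) * (2 * p + 1);
  NumericMatrix out(h, w);
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      const int cr = r + pad, cc = c + pad;
      double wsum = 0.0, vsum = 0.0, wmax = 0.0;
      for (int dr = -s; dr <= s; ++dr) {
        for (int dc = -s; dc <= s; ++dc) {
          if (dr == 0 && dc == 0) continue;
          const int jr = cr + dr, jc = cc + dc;
          double d = 0.0, sa = 0, sb = 0, sab = 0, saa = 0, sbb = 0;
          for (int pr = -p; pr <= p; ++pr) {
            for (int pc = -p; pc <= p; ++pc) {
              const double a = padded(cr + pr, cc + pc);
              const double b = padded(jr + pr, jc + pc);
              const double df = a - b;
              d += gk(pr + p, pc + p) * df * df;
              if (gamma > 0) {
                sa += a; sb += b; sab += a * b; saa += a * a; sbb += b * b;
              }
            }
          }
          double wgt = std::exp(-d / mu(r, c));
          if (gamma > 0) {
            const double va = saa - sa * sa / n;
            const double vb = sbb - sb * sb / n;
            const double epsa = 1e-9 * (1.0 + saa / n);
            const double epsb = 1e-9 * (1.0 + sbb / n);
            double sc;
            if (va <= epsa && vb <= epsb) {
              sc = 1.0;
            } else if (va <= epsa || vb <= epsb) {
              sc = 0.0;
            } else {
              sc = (sab - sa * sb / n) / std::sqrt(va * vb);
              if (sc > 1.0) sc = 1.0;
              if (sc < -1.0) sc = -1.0;
            }
            wgt *= std::pow(0.5 * (1.0 + sc), gamma);
          }
          if (wgt > wmax) wmax = wgt;
          wsum += wgt;
          vsum += wgt * padded(jr, jc);
        }
      }
      double wc = 0.0;
      if (center_rule == 0) wc = (wmax > 0.0) ? wmax : 1.0;
      else if (center_rule == 1) wc = 1.0;
      wsum += wc;
      vsum += wc * padded(cr, cc);
      out(r, c) = (wsum > 0.0) ? vsum / wsum : padded(cr, cc);
    }
  }
  return out;
}
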