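#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Lomb-Scargle periodogram, unnormalised ("psd") form with Scargle's tau
// phase offset. Input y must already be mean-subtracted. Returns P(f) such
// that for an evenly sampled sinusoid of amplitude A the peak is ~ N*A^2/4.
// One pass of trig per (beat, frequency): sin/cos of w*t are computed once
// and the 2w*t and w*(t - tau) terms derived by identities.
// [[Rcpp::export]]
NumericVector ls_power_cpp(NumericVector t, NumericVector y, NumericVector freq) {
  const int n = t.size();
  const int nf = freq.size();
  NumericVector p(nf);
  std::vector<double> sx(n), cx(n);
  for (int k = 0; k < nf; ++k) {
    const double w = 2.0 * M_PI * freq[k];
    double s2 = 0.0, c2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double arg = w * t[i];
      const double s = std::sin(arg), c = std::cos(arg);
      sx[i] = s; cx[i] = c;
      s2 += 2.0 * s * c;        // sin(2wt)
      c2 += c * c - s * s;      // cos(2wt)
    }
    const double wtau = 0.5 * std::atan2(s2, c2);
    const double ct = std::cos(wtau), st = std::sin(wtau);
    double ys = 0.0, yc = 0.0, ss = 0.0, cc = 0.0;
    for (int i = 0; i < n; ++i) {
      // cos(wt - wtau), sin(wt - wtau)
      const double c = cx[i] * ct + sx[i] * st;
      const double s = sx[i] * ct - cx[i] * st;
      yc += y[i] * c;
      ys += y[i] * s;
      cc += c * c;
      ss += s * s;
    }
    double pk = 0.0;
    if (cc > 0.0) pk += yc * yc / cc;
    if (ss > 0.0) pk += ys * ys / ss;
    p[k] = 0.5 * pk;
  }
  return p;
}
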