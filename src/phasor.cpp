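#include <Rcpp.h>
using namespace Rcpp;

// Sum of scatterer phasors: out[t] = sum_s amp[s] * exp(i*(phase0[s] + fac[s]*cumphase[t]))
// cumphase is the integrated Doppler phase of the centreline velocity; each
// scatterer scales it by its profile factor (its velocity is proportional to
// the centreline velocity at all times for a rigid profile shape).
// [[Rcpp::export]]
ComplexVector phasor_sum(NumericVector cumphase, NumericVector fac,
                         NumericVector phase0, NumericVector amp) {
  const int n = cumphase.size();
  const int ns = fac.size();
  ComplexVector out(n);
  std::vector<double> re(n, 0.0), im(n, 0.0);
  for (int s = 0; s < ns; ++s) {
    const double f = fac[s], p0 = phase0[s], a = amp[s];
    for (int t = 0; t < n; ++t) {
      const double ph = p0 + f * cumphase[t];
      re[t] += a * std::cos(ph);
      im[t] += a * std::sin(ph);
    }
  }
  for (int t = 0; t < n; ++t) {
    out[t].r = re[t];
    out[t].i = im[t];
  }
  return out;
}
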