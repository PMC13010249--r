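#include <Rcpp.h>
#include <cmath>
#include <complex>
#include <vector>
using namespace Rcpp;

// Abeles optical-matrix reflectivity of a slab stack.
// q: momentum transfer (A^-1); thickness, rough: A; sld: 1e-6 A^-2.
// First and last slabs are the semi-infinite fronting and backing media;
// rough[j] is the roughness of the interface between slab j-1 and slab j
// (rough[0] unused), applied as a Nevot-Croce factor on the Fresnel
// coefficient.
//
// SLDs are real (imaginary part neglected: weakly absorbing materials),
// so kz^2 is real and kz is either purely real (propagating) or purely
// imaginary (evanescent); the branches below avoid complex sqrt/exp.
// [[Rcpp::export]]
NumericVector abeles_cpp(NumericVector q, NumericVector thickness,
                         NumericVector sld, NumericVector rough) {
  const int nq = q.size();
  const int nl = thickness.size();
  if (sld.size() != nl || rough.size() != nl)
    stop("thickness, sld and rough must have equal length");
  if (nl < 2) stop("need at least fronting and backing media");
  NumericVector out(nq);
  typedef std::complex<double> cd;
  std::vector<cd> kz(nl);
  std::vector<double> drho(nl);
  for (int j = 0; j < nl; ++j)
    drho[j] = 4.0 * M_PI * (sld[j] - sld[0]) * 1e-6;
  for (int iq = 0; iq < nq; ++iq) {
    const double kz0sq = q[iq] * q[iq] / 4.0;
    for (int j = 0; j < nl; ++j) {
      const double a = kz0sq - drho[j];
      kz[j] = (a >= 0.0) ? cd(std::sqrt(a), 0.0) : cd(0.0, std::sqrt(-a));
    }
    cd M00(1, 0), M01(0, 0), M10(0, 0), M11(0, 0);
    for (int j = 0; j < nl - 1; ++j) {
      const cd den = kz[j] + kz[j + 1];
      cd rj(0, 0);
      if (std::norm(den) > 0.0) {
        rj = (kz[j] - kz[j + 1]) / den;
        const double s2 = rough[j + 1] * rough[j + 1];
        if (s2 > 0.0) {
          // Nevot-Croce factor exp(-2 k_j k_{j+1} sigma^2); the product
          // k_j k_{j+1} is real or purely imaginary, so the complex exp
          // is only needed in the mixed case.
          const cd kk = kz[j] * kz[j + 1];
          if (kk.imag() == 0.0) {
            rj *= std::exp(-2.0 * kk.real() * s2);
          } else {
            rj *= std::exp(cd(-2.0 * s2 * kk.real(), -2.0 * s2 * kk.imag()));
          }
        }
      }
      cd ep(1, 0), em(1, 0);
      if (j > 0) {
        // exp(+/- i kz d): kz real -> phase rotation; kz imaginary ->
        // real growth/decay
        const double d = thickness[j];
        if (kz[j].imag() == 0.0) {
          const double ph = kz[j].real() * d;
          const double c = std::cos(ph), s = std::sin(ph);
          ep = cd(c, s); em = cd(c, -s);
        } else {
          const double g = kz[j].imag() * d;
          ep = cd(std::exp(-g), 0.0); em = cd(std::exp(g), 0.0);
        }
      }
      if (j == 0) {
        M00 = ep; M01 = rj * ep; M10 = rj * em; M11 = em;
      } else {
        const cd C00 = ep, C01 = rj * ep, C10 = rj * em, C11 = em;
        const cd n00 = M00 * C00 + M01 * C10;
        const cd n01 = M00 * C01 + M01 * C11;
        const cd n10 = M10 * C00 + M11 * C10;
        const cd n11 = M10 * C01 + M11 * C11;
        M00 = n00; M01 = n01; M10 = n10; M11 = n11;
      }
    }
    double R = std::norm(M10 / M00);
    out[iq] = (R > 1.0) ? 1.0 : R;
  }
  return out;
}
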