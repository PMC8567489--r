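#include <Rcpp.h>
#include <complex>

using namespace Rcpp;

// Accumulate pore-echo spectra onto scanlines.
//
// For every (pore, line) pair p and support bin b:
//   S(b, line[p]) += pulse[b] * A(b, p) *
//                    exp(decay[b] * zeta[p] + i*(phi[p] - 2*pi*f[b]*t[p]))
// where decay[b] = -ln(10)/20 * 2 * alpha(f_b) encodes the two-way
// attenuation per mm of bone path. The support bins lie on a uniform
// frequency grid, so both the phase rotation and the attenuation decay
// advance by a constant factor per bin and are evaluated by recurrence
// (one complex multiply per bin).
// [[Rcpp::export(name = ".accum_spectra")]]
ComplexMatrix accum_spectra(NumericMatrix A, double decay0, double decay_df,
                            double f0, double df, NumericVector pulse,
                            NumericVector zeta, NumericVector phi,
                            NumericVector tj, IntegerVector line,
                            int nlines) {
  const int nb = A.nrow();
  const int np = A.ncol();
  ComplexMatrix S(nb, nlines);
  std::vector<std::complex<double>> acc((size_t) nb * nlines,
                                        std::complex<double>(0.0, 0.0));
  const double twopi = 2.0 * M_PI;
  for (int p = 0; p < np; ++p) {
    const int l = line[p] - 1;
    const double z = zeta[p];
    const double t = tj[p];
    std::complex<double>* col = &acc[(size_t) l * nb];
    const double ang0 = phi[p] - twopi * f0 * t;
    const double dang = -twopi * df * t;
    std::complex<double> rot(std::cos(ang0), std::sin(ang0));
    const std::complex<double> rot_step(std::cos(dang), std::sin(dang));
    double mag = std::exp(decay0 * z);
    const double mag_step = std::exp(decay_df * z);
    for (int b = 0; b < nb; ++b) {
      col[b] += (pulse[b] * A(b, p) * mag) * rot;
      rot *= rot_step;
      mag *= mag_step;
    }
  }
  for (int l = 0; l < nlines; ++l)
    for (int b = 0; b < nb; ++b) {
      Rcomplex v;
      v.r = acc[(size_t) l * nb + b].real();
      v.i = acc[(size_t) l * nb + b].imag();
      S(b, l) = v;
    }
  return S;
}
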