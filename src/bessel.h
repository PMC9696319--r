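#ifndef LCBP_BESSEL_H
#define LCBP_BESSEL_H

#include <complex>
#include <vector>

typedef std::complex<double> cplx;

void bessel_j_seq(const cplx z, const int nmax, std::vector<cplx>& J);
void bessel_y_seq(const cplx z, const int nmax, const std::vector<cplx>& J,
                  std::vector<cplx>& Y);

#endif
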