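// Complex-argument Bessel functions J_n, Y_n for the cylindrical-harmonic
// Green's function. Arguments arise as beta*rho with beta the complex
// propagation constant of a lossy medium (fourth quadrant under e^{+jwt});
// magnitudes stay below ~25 for catheter-scale geometry, where the power
// series for Y0/Y1 retain ~10 significant digits in double precision.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef std::complex<double> cplx;

static const double EULER_GAMMA = 0.57721566490153286060;

// J_0..J_nmax by Miller's backward recurrence, normalised with the
// generating-function identity J0(z) + 2*sum_{k>=1} J_{2k}(z) = 1,
// which holds for all complex z.
void bessel_j_seq(const cplx z, const int nmax, std::vector<cplx>& J) {
  J.assign(nmax + 1, cplx(0.0, 0.0));
  const double az = std::abs(z);
  if (az == 0.0) {
    J[0] = cplx(1.0, 0.0);
    return;
  }
  int M = std::max(nmax, (int)std::ceil(az)) + 30;
  if (M % 2) ++M;
  cplx fp(0.0, 0.0);       // f_{k+1}
  cplx fc(1e-30, 0.0);     // f_k, arbitrary seed
  cplx sum(0.0, 0.0);      // running 2*sum over even orders >= 2
  const cplx two_over_z = 2.0 / z;
  for (int k = M; k >= 1; --k) {
    const cplx fm = (double)k * two_over_z * fc - fp;  // f_{k-1}
    fp = fc;
    fc = fm;
    const int ord = k - 1;
    if (ord <= nmax) J[ord] = fc;
    if (ord >= 2 && ord % 2 == 0) sum += 2.0 * fc;
    if (std::abs(fc.real()) > 1e250 || std::abs(fc.imag()) > 1e250) {
      const double sc = 1e-250;
      fc *= sc;
      fp *= sc;
      sum *= sc;
      for (int i = 0; i <= nmax; ++i) J[i] *= sc;
    }
  }
  sum += J[0];
  for (int i = 0; i <= nmax; ++i) J[i] /= sum;
}

// Y_0, Y_1 by ascending series, then stable forward recurrence.
// Series (integer order, principal log branch):
//   Y0 = (2/pi)[(log(z/2)+gamma) J0 - sum_{k>=1} (-w)^k H_k / (k!)^2]
//   Y1 = (2/pi)(log(z/2)+gamma) J1 - 2/(pi z)
//        - (1/pi) sum_{k>=0} (-1)^k (H_k + H_{k+1}) (z/2)^{2k+1}/(k!(k+1)!)
// with w = z^2/4 and H_k the k-th harmonic number.
void bessel_y_seq(const cplx z, const int nmax, const std::vector<cplx>& J,
                  std::vector<cplx>& Y) {
  Y.assign(nmax + 1, cplx(0.0, 0.0));
  const cplx lg = std::log(z / 2.0) + EULER_GAMMA;
  const cplx w = z * z / 4.0;

  cplx u(1.0, 0.0), s0(0.0, 0.0);
  double Hk = 0.0;
  for (int k = 1; k <= 400; ++k) {
    u *= -w / (double)(k * k);
    Hk += 1.0 / k;
    const cplx term = u * Hk;
    s0 += term;
    if (std::abs(term) < 1e-18 * (std::abs(s0) + 1e-300)) break;
  }
  Y[0] = (2.0 / M_PI) * (lg * J[0] - s0);
  if (nmax == 0) return;

  cplx v = z / 2.0;
  cplx s1 = v;  // k = 0 term: H_0 + H_1 = 1
  double Hk1 = 1.0;
  Hk = 0.0;
  for (int k = 1; k <= 400; ++k) {
    v *= -w / (double)(k * (k + 1));
    Hk += 1.0 / k;
    Hk1 += 1.0 / (k + 1);
    const cplx term = v * (Hk + Hk1);
    s1 += term;
    if (std::abs(term) < 1e-18 * (std::abs(s1) + 1e-300)) break;
  }
  Y[1] = (2.0 / M_PI) * lg * J[1] - 2.0 / (M_PI * z) - s1 / M_PI;

  for (int n = 2; n <= nmax; ++n)
    Y[n] = (2.0 * (n - 1)) / z * Y[n - 1] - Y[n - 2];
}

//' @title Bessel J and Y sequences at complex argument
//' @description Evaluates \eqn{J_n(z)} and \eqn{Y_n(z)} for integer orders
//'   \code{0..nmax} at each complex argument. Internal workhorse behind the
//'   cylindrical-harmonic Green's function.
//' @param z complex vector of arguments (nonzero).
//' @param nmax highest order.
//' @return list with complex matrices \code{J} and \code{Y},
//'   \code{length(z)} rows and \code{nmax + 1} columns.
//' @keywords internal
// [[Rcpp::export]]
List bessel_jy_cpp(ComplexVector z, int nmax) {
  const int nz = z.size();
  if (nmax < 0) stop("nmax must be >= 0");
  ComplexMatrix Jm(nz, nmax + 1), Ym(nz, nmax + 1);
  std::vector<cplx> J, Y;
  for (int i = 0; i < nz; ++i) {
    const cplx zi(z[i].r, z[i].i);
    if (std::abs(zi) == 0.0) stop("bessel_jy_cpp: argument must be nonzero");
    bessel_j_seq(zi, nmax, J);
    bessel_y_seq(zi, nmax, J, Y);
    for (int n = 0; n <= nmax; ++n) {
      Jm(i, n).r = J[n].real();
      Jm(i, n).i = J[n].imag();
      Ym(i, n).r = Y[n].real();
      Ym(i, n).i = Y[n].imag();
    }
  }
  return List::create(Named("J") = Jm, Named("Y") = Ym);
}

// ---- scaled sequences -----------------------------------------------------
// For orders far beyond |z| the factors J_n (underflow) and Y_n (overflow)
// leave double range although products like J_n(z<) H_n(z>) stay O(1).
// Scaled representation: value = m * 10^e with the exponent carried apart.

struct ScaledC {
  cplx m;
  int e;
};

static ScaledC sc_norm(cplx v, int e) {
  const double a = std::abs(v);
  if (a == 0.0 || !std::isfinite(a)) return ScaledC{cplx(0.0, 0.0), 0};
  const int s = (int)std::floor(std::log10(a));
  return ScaledC{v * std::pow(10.0, (double)(-s)), e + s};
}
static ScaledC sc_mul(const ScaledC& a, const ScaledC& b) {
  if (a.m == cplx(0.0, 0.0) || b.m == cplx(0.0, 0.0))
    return ScaledC{cplx(0.0, 0.0), 0};
  return sc_norm(a.m * b.m, a.e + b.e);
}
static ScaledC sc_div(const ScaledC& a, const ScaledC& b) {
  if (a.m == cplx(0.0, 0.0)) return ScaledC{cplx(0.0, 0.0), 0};
  return sc_norm(a.m / b.m, a.e - b.e);
}
static ScaledC sc_add(const ScaledC& a, const ScaledC& b) {
  if (a.m == cplx(0.0, 0.0)) return b;
  if (b.m == cplx(0.0, 0.0)) return a;
  if (a.e >= b.e) {
    if (a.e - b.e > 320) return a;
    return sc_norm(a.m + b.m * std::pow(10.0, (double)(b.e - a.e)), a.e);
  }
  if (b.e - a.e > 320) return b;
  return sc_norm(b.m + a.m * std::pow(10.0, (double)(a.e - b.e)), b.e);
}
static cplx sc_double(const ScaledC& a) {
  if (a.m == cplx(0.0, 0.0) || a.e < -300) return cplx(0.0, 0.0);
  return a.m * std::pow(10.0, (double)a.e);
}

// J_0..J_nmax and Y_0..Y_nmax in scaled form
static void bessel_scaled(const cplx z, const int nmax,
                          std::vector<ScaledC>& J, std::vector<ScaledC>& Y) {
  J.assign(nmax + 1, ScaledC{cplx(0.0, 0.0), 0});
  Y.assign(nmax + 1, ScaledC{cplx(0.0, 0.0), 0});

  int M = std::max(nmax, (int)std::ceil(std::abs(z))) + 30;
  if (M % 2) ++M;
  cplx fp(0.0, 0.0), fc(1e-30, 0.0);
  int k = 0, ksum = 0;
  std::vector<cplx> val(nmax + 1, cplx(0.0, 0.0));
  std::vector<int> kst(nmax + 1, 0);
  cplx sum(0.0, 0.0);
  const cplx two_over_z = 2.0 / z;
  for (int q = M; q >= 1; --q) {
    const cplx fm = (double)q * two_over_z * fc - fp;
    fp = fc;
    fc = fm;
    if (std::abs(fc.real()) > 1e250 || std::abs(fc.imag()) > 1e250) {
      fc *= 1e-250;
      fp *= 1e-250;
      ++k;
    }
    const int ord = q - 1;
    if (ord <= nmax) {
      val[ord] = fc;
      kst[ord] = k;
    }
    if (ord >= 2 && ord % 2 == 0) {
      if (k > ksum) {
        sum *= std::pow(1e-250, (double)(k - ksum));
        ksum = k;
      }
      sum += 2.0 * fc;
    }
  }
  if (k > ksum) sum *= std::pow(1e-250, (double)(k - ksum));
  sum += val[0];  // order 0 is stored at the final scale
  const ScaledC S = sc_norm(sum, 0);
  for (int n = 0; n <= nmax; ++n)
    J[n] = sc_div(sc_norm(val[n], 250 * (kst[n] - k)), S);

  // Y by series then forward recurrence with its own exponent tracking
  std::vector<cplx> j01(2);
  j01[0] = sc_double(J[0]);
  j01[1] = (nmax >= 1) ? sc_double(J[1]) : cplx(0.0, 0.0);
  std::vector<cplx> jtmp(j01), ytmp;
  bessel_y_seq(z, std::min(nmax, 1), jtmp, ytmp);
  Y[0] = sc_norm(ytmp[0], 0);
  if (nmax == 0) return;
  Y[1] = sc_norm(ytmp[1], 0);
  cplx ym2 = ytmp[0], ym1 = ytmp[1];
  int m = 0;
  for (int n = 2; n <= nmax; ++n) {
    cplx y = (2.0 * (n - 1)) / z * ym1 - ym2;
    if (std::abs(y.real()) > 1e250 || std::abs(y.imag()) > 1e250) {
      y *= 1e-250;
      ym1 *= 1e-250;
      ++m;
    }
    ym2 = ym1;
    ym1 = y;
    Y[n] = sc_norm(y, 250 * m);
  }
}

//' @title Harmonic series terms of the medium Green's function
//' @description Computes the term sequence t_n (orders 0..nmax) of the
//'   cylindrical-harmonic series in scaled arithmetic, so that orders far
//'   beyond |z| remain correct even where individual Bessel factors leave
//'   double range. mode: 0 free space, 1 rod scatter, 2 rod total.
//' @keywords internal
// [[Rcpp::export]]
ComplexVector greens_terms_cpp(Rcomplex z_lo_, Rcomplex z_hi_, Rcomplex z_a_,
                               int nmax, int mode) {
  const cplx z_lo(z_lo_.r, z_lo_.i), z_hi(z_hi_.r, z_hi_.i),
      z_a(z_a_.r, z_a_.i);
  const ScaledC mi{cplx(0.0, -1.0), 0};
  std::vector<ScaledC> Jlo, Ylo, Jhi, Yhi, Ja, Ya;
  bessel_scaled(z_lo, nmax, Jlo, Ylo);
  bessel_scaled(z_hi, nmax, Jhi, Yhi);
  if (mode > 0) bessel_scaled(z_a, nmax, Ja, Ya);
  ComplexVector out(nmax + 1);
  for (int n = 0; n <= nmax; ++n) {
    const ScaledC Hhi = sc_add(Jhi[n], sc_mul(mi, Yhi[n]));
    cplx t(0.0, 0.0);
    if (mode != 1) t += sc_double(sc_mul(Jlo[n], Hhi));
    if (mode > 0) {
      const ScaledC Ha = sc_add(Ja[n], sc_mul(mi, Ya[n]));
      const ScaledC Hlo = sc_add(Jlo[n], sc_mul(mi, Ylo[n]));
      ScaledC c = sc_div(Ja[n], Ha);
      c.m = -c.m;
      t += sc_double(sc_mul(c, sc_mul(Hlo, Hhi)));
    }
    out[n].r = t.real();
    out[n].i = t.imag();
  }
  return out;
}
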