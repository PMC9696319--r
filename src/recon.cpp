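// Hot loop of the loss-compensated back-propagation (LC-BP) imaging
// functional: per voxel, re-centre the cylindrical frame on the voxel,
// evaluate the truncated harmonic series of the medium Green's function for
// every antenna pair, and coherently sum the pattern/polarization-weighted,
// loss-compensated (rho * rho') backpropagated data.
#include <RcppArmadillo.h>
#include "bessel.h"
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// wrap to (-pi, pi]
static inline double ang_diff(double a, double b) {
  return std::remainder(a - b, 2.0 * M_PI);
}

// kernel_mode: 0 = free_space, 1 = rod_scatter, 2 = rod_total
// pattern_mode: 0 = isotropic, 1 = short_dipole, 2 = short_dipole_shadowed
// [[Rcpp::export]]
NumericVector lcbp_image_cpp(NumericMatrix vox, NumericMatrix elem_xyz,
                             NumericVector elem_phi, NumericMatrix elem_axis,
                             ComplexMatrix S, Rcomplex beta_mm_,
                             Rcomplex prefac_, int kernel_mode, double a_mm,
                             int nmax, int pattern_mode, double back_lobe,
                             double g1, double g2, double min_dist) {
  const int nv = vox.nrow();
  const int Q = elem_xyz.nrow();
  if (S.nrow() != Q || S.ncol() != Q)
    stop("data matrix dimension does not match the number of elements");
  const cplx beta(beta_mm_.r, beta_mm_.i);
  const cplx prefac(prefac_.r, prefac_.i);
  const cplx mi(0.0, -1.0);  // H^(2) = J - i Y

  // PEC rod scattering coefficients c_n = -J_n(beta a) / H^(2)_n(beta a)
  std::vector<cplx> cn(nmax + 1, cplx(0.0, 0.0));
  if (kernel_mode > 0) {
    if (a_mm <= 0.0) stop("rod kernels require a positive rod radius");
    std::vector<cplx> Ja, Ya;
    bessel_j_seq(beta * a_mm, nmax, Ja);
    bessel_y_seq(beta * a_mm, nmax, Ja, Ya);
    for (int n = 0; n <= nmax; ++n) cn[n] = -Ja[n] / (Ja[n] + mi * Ya[n]);
  }

  arma::cx_mat Smat(Q, Q);
  for (int q = 0; q < Q; ++q)
    for (int m = 0; m < Q; ++m) Smat(q, m) = cplx(S(q, m).r, S(q, m).i);

  std::vector<double> d(Q), phi(Q), uT(Q), uR(Q);
  std::vector<bool> skip(Q);
  std::vector<std::vector<cplx> > Jv(Q), Hv(Q);
  std::vector<cplx> Ytmp;

  NumericVector out(nv);
  for (int v = 0; v < nv; ++v) {
    if (v % 256 == 0) Rcpp::checkUserInterrupt();
    const double px = vox(v, 0), py = vox(v, 1), pz = vox(v, 2);
    const double phi_pix = std::atan2(py, px);

    for (int q = 0; q < Q; ++q) {
      const double dx = elem_xyz(q, 0) - px;
      const double dy = elem_xyz(q, 1) - py;
      const double dz = elem_xyz(q, 2) - pz;
      d[q] = std::sqrt(dx * dx + dy * dy + dz * dz);
      skip[q] = (d[q] < min_dist) || (kernel_mode > 0 && d[q] < a_mm);
      if (skip[q]) continue;
      phi[q] = std::atan2(dy, dx);

      double gain = 1.0;
      if (pattern_mode >= 1) {
        // |sin(theta)| between the dipole axis and the element-to-pixel ray
        const double ux = -dx / d[q], uy = -dy / d[q], uz = -dz / d[q];
        const double ax = elem_axis(q, 0), ay = elem_axis(q, 1),
                     az = elem_axis(q, 2);
        const double cx = ay * uz - az * uy;
        const double cy = az * ux - ax * uz;
        const double cz = ax * uy - ay * ux;
        gain = std::sqrt(cx * cx + cy * cy + cz * cz);
      }
      const double dphi_rod = ang_diff(phi_pix, elem_phi[q]);
      if (pattern_mode == 2 && std::fabs(dphi_rod) > M_PI / 2.0)
        gain *= back_lobe;
      const double ca = std::fabs(std::cos(dphi_rod));
      const double polT = (g1 == 0.0) ? 1.0 : std::pow(ca, g1);
      const double polR = (g2 == 0.0) ? 1.0 : std::pow(ca, g2);
      uT[q] = d[q] * gain * polT;
      uR[q] = d[q] * gain * polR;

      bessel_j_seq(beta * d[q], nmax, Jv[q]);
      bessel_y_seq(beta * d[q], nmax, Jv[q], Ytmp);
      Hv[q].assign(nmax + 1, cplx(0.0, 0.0));
      for (int n = 0; n <= nmax; ++n) Hv[q][n] = Jv[q][n] + mi * Ytmp[n];
    }

    cplx acc(0.0, 0.0);
    for (int q = 0; q < Q; ++q) {
      if (skip[q]) continue;
      for (int m = q + 1; m < Q; ++m) {
        if (skip[m]) continue;
        const bool qlo = d[q] <= d[m];
        const std::vector<cplx>& Jlo = qlo ? Jv[q] : Jv[m];
        const std::vector<cplx>& Hhi = qlo ? Hv[m] : Hv[q];
        const double dphi = phi[q] - phi[m];
        const double c1 = std::cos(dphi);
        double cprev = 1.0, ccur = c1;
        cplx G(0.0, 0.0);
        for (int n = 0; n <= nmax; ++n) {
          cplx t;
          if (kernel_mode == 1)
            t = cn[n] * Hv[q][n] * Hv[m][n];
          else {
            t = Jlo[n] * Hhi[n];
            if (kernel_mode == 2) t += cn[n] * Hv[q][n] * Hv[m][n];
          }
          // vanishing high-order terms whose factors under/overflowed
          if (!std::isfinite(t.real()) || !std::isfinite(t.imag()))
            t = cplx(0.0, 0.0);
          if (n == 0)
            G += t;
          else {
            G += 2.0 * ccur * t;
            const double cnext = 2.0 * c1 * ccur - cprev;
            cprev = ccur;
            ccur = cnext;
          }
        }
        G *= prefac;
        acc += std::conj(G) *
               (uT[q] * uR[m] * Smat(q, m) + uT[m] * uR[q] * Smat(m, q));
      }
    }
    out[v] = std::abs(acc);
  }
  return out;
}
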