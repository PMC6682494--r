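#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cd;

// Extended-phase-graph recursion over every spatial element (row) of a flip
// matrix.  Each row holds the flip-angle history (degrees) of one tissue
// element; phases (degrees) are shared across elements.  States are stored as
// F+_k, F-_k (= conj(F_{-k})) and Z_k for k = 0..kmax.  The per-pulse cycle is
//   RF rotation -> record demodulated F_0 at TE -> relax over TR
//   -> (spoiled only) unit k-shift of transverse states.
// Elements are skipped outside the window where their flip history is nonzero;
// after the last pulse the recursion is continued while residual transverse
// signal is above ~1e-9 of m0 so trailing-edge decay is still represented.
//
// [[Rcpp::export]]
ComplexMatrix epg_engine_cpp(NumericMatrix flips, NumericVector phases,
                             double e1, double e2, double e2te,
                             double m0, bool shift, int kmax) {
  const int L = flips.nrow();
  const int T = flips.ncol();
  if ((int)phases.size() != T)
    stop("phases length must match the number of pulses");
  if (kmax < 0) stop("kmax must be >= 0");

  ComplexMatrix out(L, T);
  std::fill(out.begin(), out.end(), Rcomplex{0.0, 0.0});

  // precompute per-pulse trig of the RF phase
  std::vector<cd> eip(T), e2ip(T), emip(T);
  const double d2r = M_PI / 180.0;
  for (int t = 0; t < T; ++t) {
    double p = phases[t] * d2r;
    eip[t]  = cd(std::cos(p), std::sin(p));
    e2ip[t] = eip[t] * eip[t];
    emip[t] = std::conj(eip[t]);
  }

  // extra pulses simulated past the last excitation (transverse decay tail)
  int tail = 0;
  if (e2 > 0.0 && e2 < 1.0)
    tail = (int)std::ceil(std::log(1e-9) / std::log(e2));
  else if (e2 >= 1.0)
    tail = T;

  std::vector<cd> Fp(kmax + 1), Fm(kmax + 1), Z(kmax + 1);

  for (int r = 0; r < L; ++r) {
    // active pulse window of this element
    int t0 = -1, t1 = -1;
    for (int t = 0; t < T; ++t) {
      if (flips(r, t) != 0.0) { if (t0 < 0) t0 = t; t1 = t; }
    }
    if (t0 < 0) continue;
    int tEnd = std::min(T - 1, t1 + tail);

    std::fill(Fp.begin(), Fp.end(), cd(0, 0));
    std::fill(Fm.begin(), Fm.end(), cd(0, 0));
    std::fill(Z.begin(),  Z.end(),  cd(0, 0));
    Z[0] = cd(m0, 0);
    int kcur = 0;

    for (int t = t0; t <= tEnd; ++t) {
      double a = flips(r, t) * d2r;
      if (a != 0.0) {
        double ca = std::cos(a), sa = std::sin(a);
        double c2 = std::cos(a / 2.0), s2 = std::sin(a / 2.0);
        double c2s = c2 * c2, s2s = s2 * s2;
        cd T11(c2s, 0), T22(c2s, 0), T33(ca, 0);
        cd T12 = e2ip[t] * s2s;
        cd T21 = std::conj(T12);
        cd T13 = cd(0, -1) * eip[t] * sa;
        cd T23 = std::conj(T13);          // = i e^{-ip} sin a
        cd T31 = cd(0, -0.5) * emip[t] * sa;
        cd T32 = cd(0,  0.5) * eip[t]  * sa;
        for (int k = 0; k <= kcur; ++k) {
          cd fp = Fp[k], fm = Fm[k], z = Z[k];
          Fp[k] = T11 * fp + T12 * fm + T13 * z;
          Fm[k] = T21 * fp + T22 * fm + T23 * z;
          Z[k]  = T31 * fp + T32 * fm + T33 * z;
        }
      }
      // demodulated echo signal at TE
      cd s = Fp[0] * e2te * emip[t];
      out(r, t) = Rcomplex{s.real(), s.imag()};

      // relaxation over one TR with Z_0 recovery
      for (int k = 0; k <= kcur; ++k) {
        Fp[k] *= e2; Fm[k] *= e2; Z[k] *= e1;
      }
      Z[0] += m0 * (1.0 - e1);

      if (shift) {
        int knew = std::min(kcur + 1, kmax);
        for (int k = knew; k >= 1; --k) Fp[k] = Fp[k - 1];
        Fp[0] = (kmax >= 1) ? std::conj(Fm[1]) : cd(0, 0);
        for (int k = 0; k < knew; ++k) Fm[k] = Fm[k + 1];
        Fm[knew] = cd(0, 0);
        // k = 0 transverse redundancy: Fm[0] must mirror Fp[0]
        Fm[0] = std::conj(Fp[0]);
        kcur = knew;
      }
    }
  }
  return out;
}
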