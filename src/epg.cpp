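#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// Extended-phase-graph echo amplitudes for a CPMG-style echo train.
//
// Convention: instantaneous pulses, excitation about x (phase 0),
// refocusing about y (phase pi/2). One gradient dephasing unit per half
// echo spacing; relaxation applied over each half interval; echo read as
// |F0| after the second half interval of each cycle. Z0 regrows towards
// unit equilibrium magnetisation.
//
// t2, t1 in ms, b1 relative (scales both excitation and refocusing),
// esp = echo spacing in ms. Returns an n x nEchoes matrix of amplitudes.
// grad^T grad with forward differences and Neumann boundaries, 3D.
// [[Rcpp::export(name = ".gradTGradCpp")]]
NumericVector gradtgrad_cpp(NumericVector x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(x.size());
  const double *p = x.begin();
  double *o = out.begin();
  auto at = [&](int i, int j, int k) { return p[i + nx * (j + ny * k)]; };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double v = 0, c = at(i, j, k);
        if (i > 0) v += c - at(i - 1, j, k);
        if (i < nx - 1) v -= at(i + 1, j, k) - c;
        if (j > 0) v += c - at(i, j - 1, k);
        if (j < ny - 1) v -= at(i, j + 1, k) - c;
        if (k > 0) v += c - at(i, j, k - 1);
        if (k < nz - 1) v -= at(i, j, k + 1) - c;
        o[i + nx * (j + ny * k)] = v;
      }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export(name = ".epgEchoesCpp")]]
NumericMatrix epg_echoes_cpp(NumericVector t2, NumericVector t1,
                             NumericVector b1, double esp, int nEchoes,
                             double refDeg, double excDeg) {
  const int n = t2.size();
  if (t1.size() != n || b1.size() != n)
    stop("t2, t1, b1 must have equal length");
  if (nEchoes < 1) stop("nEchoes must be >= 1");
  NumericMatrix out(n, nEchoes);
  const int K = 2 * nEchoes + 3;  // dephasing orders 0..K-1
  typedef std::complex<double> cd;
  const cd I(0.0, 1.0);

  std::vector<cd> Fp(K), Fm(K), Z(K), Fp2(K), Fm2(K), Z2(K);

  for (int v = 0; v < n; ++v) {
    if (t2[v] <= 0.0) stop("t2 must be > 0");
    if (t1[v] < t2[v]) stop("t1 must be >= t2");
    const double e2 = std::exp(-esp / 2.0 / t2[v]);
    const double e1 = std::exp(-esp / 2.0 / t1[v]);
    std::fill(Fp.begin(), Fp.end(), cd(0, 0));
    std::fill(Fm.begin(), Fm.end(), cd(0, 0));
    std::fill(Z.begin(), Z.end(), cd(0, 0));
    std::fill(Fp2.begin(), Fp2.end(), cd(0, 0));
    std::fill(Fm2.begin(), Fm2.end(), cd(0, 0));
    std::fill(Z2.begin(), Z2.end(), cd(0, 0));
    Z[0] = cd(1, 0);

    int kmax = 0;  // highest populated dephasing order (grows 1 per shift)

    // RF operator coefficients for flip alpha about phase phi
    auto rf = [&](double alpha, double phi) {
      const double ca2 = std::cos(alpha / 2) * std::cos(alpha / 2);
      const double sa2 = std::sin(alpha / 2) * std::sin(alpha / 2);
      const double sa = std::sin(alpha), ca = std::cos(alpha);
      const cd eip = std::exp(I * phi), ei2p = std::exp(2.0 * I * phi);
      const cd t12 = ei2p * sa2, t13 = -I * eip * sa;
      const cd t21 = std::conj(ei2p) * sa2, t23 = I * std::conj(eip) * sa;
      const cd t31 = -0.5 * I * std::conj(eip) * sa, t32 = 0.5 * I * eip * sa;
      for (int k = 0; k <= kmax; ++k) {
        Fp2[k] = ca2 * Fp[k] + t12 * Fm[k] + t13 * Z[k];
        Fm2[k] = t21 * Fp[k] + ca2 * Fm[k] + t23 * Z[k];
        Z2[k] = t31 * Fp[k] + t32 * Fm[k] + ca * Z[k];
      }
      std::swap(Fp, Fp2); std::swap(Fm, Fm2); std::swap(Z, Z2);
    };
    auto relax = [&]() {
      for (int k = 0; k <= kmax; ++k) { Fp[k] *= e2; Fm[k] *= e2; Z[k] *= e1; }
      Z[0] += (1.0 - e1);
    };
    auto shiftup = [&]() {  // one dephasing unit
      if (kmax < K - 1) ++kmax;
      for (int k = kmax; k >= 1; --k) Fp[k] = Fp[k - 1];
      Fp[0] = std::conj(Fm[1]);
      for (int k = 0; k < kmax; ++k) Fm[k] = Fm[k + 1];
      Fm[kmax] = cd(0, 0);
      Fm[0] = std::conj(Fp[0]);
    };

    rf(excDeg * M_PI / 180.0 * b1[v], 0.0);
    const double aref = refDeg * M_PI / 180.0 * b1[v];
    for (int e = 0; e < nEchoes; ++e) {
      relax(); shiftup();
      rf(aref, M_PI / 2.0);
      relax(); shiftup();
      out(v, e) = std::abs(Fp[0]);
    }
  }
  return out;
}
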