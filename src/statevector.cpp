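// Dense statevector kernels.
//
// Amplitude index convention (fixed package-wide): qubit 0 is the MOST
// significant bit of the amplitude index, so the bit position of qubit q in
// an n-qubit register is (n - 1 - q).  A dedicated R-level convention test
// pins this down.
//
// Gate codes (shared with R/simulator.R): 0 H, 1 X, 2 RX, 3 RY, 4 RZ,
// 5 CNOT.

#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cplx;

static inline int popcount32(unsigned int v) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(v);
#else
  int c = 0;
  while (v) { c += v & 1u; v >>= 1; }
  return c;
#endif
}

static void apply_circuit_impl(std::vector<cplx>& v,
                               const int* kind, const int* target,
                               const int* control, const double* angle,
                               int ng, int n_qubits) {
  const R_xlen_t dim = (R_xlen_t)v.size();
  const double inv_sqrt2 = 1.0 / std::sqrt(2.0);

  for (int g = 0; g < ng; ++g) {
    const int k = kind[g];
    const int t = target[g];
    if (t < 0 || t >= n_qubits) stop("gate target out of range");
    const R_xlen_t tb = R_xlen_t(1) << (n_qubits - 1 - t);

    if (k == 5) {  // CNOT
      const int c = control[g];
      if (c < 0 || c >= n_qubits || c == t) stop("CNOT control out of range");
      const R_xlen_t cb = R_xlen_t(1) << (n_qubits - 1 - c);
      for (R_xlen_t i = 0; i < dim; ++i) {
        if ((i & cb) && !(i & tb)) std::swap(v[i], v[i | tb]);
      }
      continue;
    }

    // single-qubit 2x2 unitary [[u00,u01],[u10,u11]]
    cplx u00, u01, u10, u11;
    const double th = angle[g];
    const double ch = std::cos(th / 2.0), sh = std::sin(th / 2.0);
    switch (k) {
    case 0:  // H
      u00 = inv_sqrt2; u01 = inv_sqrt2; u10 = inv_sqrt2; u11 = -inv_sqrt2;
      break;
    case 1:  // X
      u00 = 0.0; u01 = 1.0; u10 = 1.0; u11 = 0.0;
      break;
    case 2:  // RX
      u00 = ch; u01 = cplx(0.0, -sh); u10 = cplx(0.0, -sh); u11 = ch;
      break;
    case 3:  // RY
      u00 = ch; u01 = -sh; u10 = sh; u11 = ch;
      break;
    case 4:  // RZ = diag(exp(-i th/2), exp(+i th/2))
      u00 = cplx(ch, -sh); u01 = 0.0; u10 = 0.0; u11 = cplx(ch, sh);
      break;
    default:
      stop("unknown gate code");
    }
    for (R_xlen_t i = 0; i < dim; ++i) {
      if (!(i & tb)) {
        const cplx a = v[i], b = v[i | tb];
        v[i]      = u00 * a + u01 * b;
        v[i | tb] = u10 * a + u11 * b;
      }
    }
  }
}

// <psi| sum_t coeff_t P_t |psi>.  A Pauli string is encoded as masks
// (x, z) with P = i^{|x&z|} X^x Z^z, so P|b> = i^{|x&z|}
// (-1)^{popcount(b&z)} |b xor x>.  For x != 0, indices pair up as
// (b, b^x); only b < b^x is visited and the conjugate partner is folded
// in analytically.
static cplx expectation_impl(const std::vector<cplx>& v,
                             const int* xmask, const int* zmask,
                             const double* coeff, int nt, int n_qubits) {
  const R_xlen_t dim = (R_xlen_t)v.size();
  static const cplx ipow[4] = {cplx(1, 0), cplx(0, 1), cplx(-1, 0), cplx(0, -1)};
  double tot_re = 0.0, tot_im = 0.0;
  for (int t = 0; t < nt; ++t) {
    const unsigned int x = (unsigned int)xmask[t];
    const unsigned int z = (unsigned int)zmask[t];
    const int ny = popcount32(x & z) & 3;
    double s_re = 0.0, s_im = 0.0;
    if (x == 0) {
      // diagonal string: sum of signed probabilities
      for (R_xlen_t b = 0; b < dim; ++b) {
        const double p = std::norm(v[b]);
        s_re += (popcount32((unsigned int)b & z) & 1) ? -p : p;
      }
    } else {
      // pairs (b, b^x): term_b + term_{b^x} =
      //   sgn(b) conj(v[b^x]) v[b] + sgn(b^x) conj(v[b]) v[b^x]
      // with sgn(b^x) = sgn(b) * (-1)^{popcount(x&z)}
      const int flip = popcount32(x & z) & 1;
      for (R_xlen_t b = 0; b < dim; ++b) {
        const R_xlen_t bp = b ^ (R_xlen_t)x;
        if (b > bp) continue;
        const double sgn = (popcount32((unsigned int)b & z) & 1) ? -1.0 : 1.0;
        const double ar = v[bp].real(), ai = v[bp].imag();
        const double br = v[b].real(), bi = v[b].imag();
        // conj(v[bp]) * v[b]
        const double pr = ar * br + ai * bi;
        const double pi_ = ar * bi - ai * br;
        if (flip) {  // partner enters with opposite sign: imaginary survives
          s_im += sgn * 2.0 * pi_;
        } else {     // partner is the complex conjugate: real survives
          s_re += sgn * 2.0 * pr;
        }
      }
    }
    const cplx sc = ipow[ny] * cplx(s_re, s_im) * coeff[t];
    tot_re += sc.real();
    tot_im += sc.imag();
  }
  return cplx(tot_re, tot_im);
}

static std::vector<cplx> as_cvec(const ComplexVector& amps) {
  std::vector<cplx> v(amps.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)v.size(); ++i)
    v[i] = cplx(amps[i].r, amps[i].i);
  return v;
}

// Apply an ordered gate list to a statevector; returns a new vector
// (the input is never modified, matching the pure-state contract).
// [[Rcpp::export]]
ComplexVector cpp_apply_circuit(ComplexVector amps,
                                IntegerVector kind,
                                IntegerVector target,
                                IntegerVector control,
                                NumericVector angle,
                                int n_qubits) {
  if (amps.size() != (R_xlen_t(1) << n_qubits))
    stop("statevector length does not match 2^n_qubits");
  std::vector<cplx> v = as_cvec(amps);
  apply_circuit_impl(v, kind.begin(), target.begin(), control.begin(),
                     angle.begin(), kind.size(), n_qubits);
  ComplexVector out(v.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)v.size(); ++i) {
    out[i].r = v[i].real();
    out[i].i = v[i].imag();
  }
  return out;
}

// [[Rcpp::export]]
ComplexVector cpp_pauli_expectation(ComplexVector amps,
                                    IntegerVector xmask,
                                    IntegerVector zmask,
                                    NumericVector coeff,
                                    int n_qubits) {
  if (amps.size() != (R_xlen_t(1) << n_qubits))
    stop("statevector length does not match 2^n_qubits");
  std::vector<cplx> v = as_cvec(amps);
  cplx total = expectation_impl(v, xmask.begin(), zmask.begin(),
                                coeff.begin(), xmask.size(), n_qubits);
  ComplexVector out(1);
  out[0].r = total.real();
  out[0].i = total.imag();
  return out;
}

// Parameter-shift gradient, fully in C++: for each parameterized gate
// (indices in `bound`, 0-based into the gate list), evaluate the cost at
// that gate's angle +- pi/2 and accumulate scale * (E+ - E-)/2 onto the
// gate's parameter slot.
// [[Rcpp::export]]
NumericVector cpp_param_shift_gradient(ComplexVector amps,
                                       IntegerVector kind,
                                       IntegerVector target,
                                       IntegerVector control,
                                       NumericVector angle,
                                       IntegerVector bound,
                                       IntegerVector slot,
                                       NumericVector scale,
                                       int n_parameters,
                                       IntegerVector xmask,
                                       IntegerVector zmask,
                                       NumericVector coeff,
                                       int n_qubits) {
  if (amps.size() != (R_xlen_t(1) << n_qubits))
    stop("statevector length does not match 2^n_qubits");
  const std::vector<cplx> psi0 = as_cvec(amps);
  std::vector<double> ang(angle.begin(), angle.end());
  NumericVector grad(n_parameters);
  const double half_pi = 2.0 * std::atan(1.0);
  for (int bi = 0; bi < bound.size(); ++bi) {
    const int g = bound[bi];
    const double a0 = ang[g];
    double e[2];
    for (int s = 0; s < 2; ++s) {
      ang[g] = a0 + (s == 0 ? half_pi : -half_pi);
      std::vector<cplx> v = psi0;
      apply_circuit_impl(v, kind.begin(), target.begin(), control.begin(),
                         ang.data(), kind.size(), n_qubits);
      e[s] = expectation_impl(v, xmask.begin(), zmask.begin(), coeff.begin(),
                              xmask.size(), n_qubits).real();
    }
    ang[g] = a0;
    grad[slot[bi]] += scale[bi] * 0.5 * (e[0] - e[1]);
  }
  return grad;
}
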