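// Two-layer (coated) and homogeneous sphere Mie scattering kernel.
//
// The stratified-sphere coefficients use the effective logarithmic-derivative
// recursion: per-layer log-derivatives D1 (downward recurrence) and D3
// (upward, via the psi*zeta product), combined through the ratio function
// Q_n = [psi_n(z1)/xi_n(z1)] / [psi_n(z2)/xi_n(z2)] so that only bounded
// ratios are ever formed.  This keeps the recursion stable for absorbing
// layers at size parameters of several hundred, where direct evaluation of
// the Riccati-Bessel functions of complex argument would overflow.
//
// Convention: time factor exp(-i w t), relative refractive index m = n + i k
// with k >= 0 (callers may pass m = n - i k; the modulus of the imaginary
// part is used).  xi_n = psi_n - i chi_n.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
typedef std::complex<double> cx;

static const cx I1(0.0, 1.0);

static inline int n_terms(double x) {
  return (int)std::ceil(x + 4.05 * std::cbrt(x) + 2.0);
}

// exp(w) - 1 with small-|w| series to avoid cancellation
static inline cx cexpm1(cx w) {
  if (std::abs(w) < 1e-3) {
    return w * (1.0 + w / 2.0 * (1.0 + w / 3.0 * (1.0 + w / 4.0)));
  }
  return std::exp(w) - 1.0;
}

// D1_n(z) = psi_n'(z)/psi_n(z), n = 0..N, by downward recurrence.
// The start order must exceed both N and |z| for the continued fraction to
// converge onto the minimal solution.
static void calc_D1(cx z, int N, std::vector<cx>& D1) {
  D1.assign(N + 1, cx(0.0, 0.0));
  int start = std::max(N, (int)std::ceil(std::abs(z))) + 16;
  cx d(0.0, 0.0);
  for (int n = start; n >= 1; --n) {
    cx nz = (double)n / z;
    d = nz - 1.0 / (d + nz);
    if (n - 1 <= N) D1[n - 1] = d;
  }
}

// D3_n(z) = xi_n'(z)/xi_n(z) via psi*xi product recurrence (upward).
// Wronskian: psi_n xi_n' - psi_n' xi_n = i  =>  D3 = D1 + i/(psi*xi).
static void calc_D3(cx z, int N, const std::vector<cx>& D1, std::vector<cx>& D3) {
  D3.assign(N + 1, cx(0.0, 0.0));
  // psi_0 xi_0 = 0.5 (1 - exp(2 i z));  |exp(2iz)| <= 1 for Im z >= 0
  cx pz = 0.5 * (1.0 - std::exp(2.0 * I1 * z));
  D3[0] = I1;
  for (int n = 1; n <= N; ++n) {
    cx nz = (double)n / z;
    pz = pz * (nz - D1[n - 1]) * (nz - D3[n - 1]);
    D3[n] = D1[n] + I1 / pz;
  }
}

// Q_n = [psi_n(z1)/xi_n(z1)] / [psi_n(z2)/xi_n(z2)], upward on the ratio so
// every factor stays O(1); Q_n -> 0 for n beyond |z1|.
static void calc_Q(cx z1, cx z2, int N,
                   const std::vector<cx>& D1a, const std::vector<cx>& D3a,
                   const std::vector<cx>& D1b, const std::vector<cx>& D3b,
                   std::vector<cx>& Q) {
  Q.assign(N + 1, cx(0.0, 0.0));
  // q_0(z) = psi_0 xi_0 / |xi_0|^2-free form: psi_0/xi_0 = (1 - exp(-2iz))/2
  // Q_0 written with decaying exponentials only (Im z >= 0):
  cx A = -2.0 * I1 * z1;  // Re(A) = 2 Im(z1) >= 0
  cx B = -2.0 * I1 * z2;
  Q[0] = std::exp(A - B) * (-cexpm1(-A)) / (-cexpm1(-B));
  for (int n = 1; n <= N; ++n) {
    cx n1 = (double)n / z1, n2 = (double)n / z2;
    Q[n] = Q[n - 1] * ((D3a[n] + n1) / (D1a[n] + n1)) *
           ((D1b[n] + n2) / (D3b[n] + n2));
  }
}

// Riccati-Bessel psi_n, chi_n of real argument, n = 0..N, by the classical
// upward three-term recurrence (adequate because N exceeds x by only a few
// times x^(1/3), where the upward error growth is still negligible).
static void psi_chi(double x, int N, std::vector<double>& psi,
                    std::vector<double>& chi) {
  psi.assign(N + 1, 0.0);
  chi.assign(N + 1, 0.0);
  double psim1 = std::cos(x);  // psi_{-1}
  psi[0] = std::sin(x);
  chi[0] = std::cos(x);
  double chim1 = -std::sin(x);  // chi_{-1}
  if (N >= 1) {
    psi[1] = psi[0] / x - psim1;
    chi[1] = chi[0] / x - chim1;
  }
  for (int n = 1; n < N; ++n) {
    double c = (2.0 * n + 1.0) / x;
    psi[n + 1] = c * psi[n] - psi[n - 1];
    chi[n + 1] = c * chi[n] - chi[n - 1];
  }
}

// Homogeneous-sphere coefficients a_n, b_n (BHMIE-style, log-derivative form)
static void homogeneous_ab(double x, cx m, int N, std::vector<cx>& a,
                           std::vector<cx>& b) {
  std::vector<cx> D1;
  calc_D1(m * x, N, D1);
  std::vector<double> psi, chi;
  psi_chi(x, N, psi, chi);
  a.assign(N + 1, cx(0, 0));
  b.assign(N + 1, cx(0, 0));
  for (int n = 1; n <= N; ++n) {
    cx xin = psi[n] - I1 * chi[n], xinm = psi[n - 1] - I1 * chi[n - 1];
    cx fa = D1[n] / m + (double)n / x;
    cx fb = m * D1[n] + (double)n / x;
    a[n] = (fa * psi[n] - psi[n - 1]) / (fa * xin - xinm);
    b[n] = (fb * psi[n] - psi[n - 1]) / (fb * xin - xinm);
  }
}

// Two-layer coefficients: core (x1, m1) inside shell (x2, m2).
static void coated_ab(double x1, double x2, cx m1, cx m2, int N,
                      std::vector<cx>& a, std::vector<cx>& b) {
  if (x1 <= 0.0) {  // no core: homogeneous sphere of shell material
    homogeneous_ab(x2, m2, N, a, b);
    return;
  }
  cx u = m1 * x1, z1 = m2 * x1, z2 = m2 * x2;
  std::vector<cx> D1u, D1z1, D3z1, D1z2, D3z2, Q;
  calc_D1(u, N, D1u);
  calc_D1(z1, N, D1z1);
  calc_D3(z1, N, D1z1, D3z1);
  calc_D1(z2, N, D1z2);
  calc_D3(z2, N, D1z2, D3z2);
  calc_Q(z1, z2, N, D1z1, D3z1, D1z2, D3z2, Q);
  std::vector<double> psi, chi;
  psi_chi(x2, N, psi, chi);
  a.assign(N + 1, cx(0, 0));
  b.assign(N + 1, cx(0, 0));
  for (int n = 1; n <= N; ++n) {
    // TM (a-type): interface condition U continuous, U'/m continuous
    cx G1 = m2 * D1u[n] - m1 * D1z1[n];
    cx G2 = m2 * D1u[n] - m1 * D3z1[n];
    cx Ha = (G2 * D1z2[n] - Q[n] * G1 * D3z2[n]) / (G2 - Q[n] * G1);
    // TE (b-type): U/m continuous, U' continuous
    cx H1 = m1 * D1u[n] - m2 * D1z1[n];
    cx H2 = m1 * D1u[n] - m2 * D3z1[n];
    cx Hb = (H2 * D1z2[n] - Q[n] * H1 * D3z2[n]) / (H2 - Q[n] * H1);
    cx xin = psi[n] - I1 * chi[n], xinm = psi[n - 1] - I1 * chi[n - 1];
    cx fa = Ha / m2 + (double)n / x2;
    cx fb = m2 * Hb + (double)n / x2;
    a[n] = (fa * psi[n] - psi[n - 1]) / (fa * xin - xinm);
    b[n] = (fb * psi[n] - psi[n - 1]) / (fb * xin - xinm);
  }
}

static inline cx sanitize_m(Rcomplex m) {
  return cx(m.r, std::fabs(m.i));
}

static void efficiencies(const std::vector<cx>& a, const std::vector<cx>& b,
                         double x, int N, double& Qext, double& Qsca) {
  double se = 0.0, ss = 0.0;
  for (int n = 1; n <= N; ++n) {
    double w = 2.0 * n + 1.0;
    se += w * (a[n].real() + b[n].real());
    ss += w * (std::norm(a[n]) + std::norm(b[n]));
  }
  Qext = 2.0 / (x * x) * se;
  Qsca = 2.0 / (x * x) * ss;
}

static void check_finite(double Qext, double Qsca, double x1, double x2,
                         cx m1, cx m2) {
  if (!std::isfinite(Qext) || !std::isfinite(Qsca)) {
    stop("numerical-stability error in coated-sphere recurrence "
         "(x_core=%g, x_shell=%g, m_core=%g%+gi, m_shell=%g%+gi)",
         x1, x2, m1.real(), m1.imag(), m2.real(), m2.imag());
  }
}

static void check_cap(double x, int nmax_cap) {
  int N = n_terms(x);
  if (N > nmax_cap) {
    stop("size parameter x = %g needs %d series terms, exceeding the "
         "configured cap of %d; raise nmax_cap explicitly if this is "
         "intentional", x, N, nmax_cap);
  }
}

// Angular functions pi_n, tau_n for all mu, n = 1..N (columns)
static void fill_pi_tau(const arma::vec& mu, int N, arma::mat& Pi,
                        arma::mat& Tau) {
  int nm = mu.n_elem;
  Pi.set_size(nm, N);
  Tau.set_size(nm, N);
  arma::vec pim1(nm, arma::fill::zeros);  // pi_0
  arma::vec pin(nm, arma::fill::ones);    // pi_1
  for (int n = 1; n <= N; ++n) {
    Pi.col(n - 1) = pin;
    Tau.col(n - 1) = n * (mu % pin) - (n + 1) * pim1;
    if (n < N) {
      arma::vec pinp = ((2.0 * n + 1.0) * (mu % pin) - (n + 1.0) * pim1) / n;
      pim1 = pin;
      pin = pinp;
    }
  }
}

// Unpolarised angular intensity S11 = (|S1|^2 + |S2|^2)/2 on the rows of
// Pi/Tau, using BLAS matrix products.
static arma::vec s11_from_ab(const std::vector<cx>& a, const std::vector<cx>& b,
                             int N, const arma::mat& Pi, const arma::mat& Tau) {
  arma::mat M(N, 4);
  for (int n = 1; n <= N; ++n) {
    double f = (2.0 * n + 1.0) / (n * (n + 1.0));
    cx A = f * a[n], B = f * b[n];
    M(n - 1, 0) = A.real();
    M(n - 1, 1) = A.imag();
    M(n - 1, 2) = B.real();
    M(n - 1, 3) = B.imag();
  }
  arma::mat U = Pi.cols(0, N - 1) * M;   // n_mu x 4
  arma::mat V = Tau.cols(0, N - 1) * M;  // n_mu x 4
  arma::vec S1r = U.col(0) + V.col(2), S1i = U.col(1) + V.col(3);
  arma::vec S2r = V.col(0) + U.col(2), S2i = V.col(1) + U.col(3);
  return 0.5 * (S1r % S1r + S1i % S1i + S2r % S2r + S2i % S2i);
}

//' @noRd
// [[Rcpp::export(name = "mie_single_cpp")]]
List mie_single_cpp(double x_core, double x_shell, Rcomplex m_core,
                    Rcomplex m_shell, NumericVector mu, bool homogeneous,
                    int nmax_cap) {
  if (x_shell <= 0) stop("size parameter must be positive");
  check_cap(x_shell, nmax_cap);
  int N = n_terms(x_shell);
  cx mc = sanitize_m(m_core), ms = sanitize_m(m_shell);
  std::vector<cx> a, b;
  if (homogeneous)
    homogeneous_ab(x_shell, ms, N, a, b);
  else
    coated_ab(x_core, x_shell, mc, ms, N, a, b);
  double Qext, Qsca;
  efficiencies(a, b, x_shell, N, Qext, Qsca);
  check_finite(Qext, Qsca, x_core, x_shell, mc, ms);
  List out = List::create(
      _["Qext"] = Qext, _["Qsca"] = Qsca, _["Qabs"] = Qext - Qsca,
      _["nterms"] = N);
  if (mu.size() > 0) {
    arma::vec amu(mu.begin(), mu.size());
    arma::mat Pi, Tau;
    fill_pi_tau(amu, N, Pi, Tau);
    arma::vec s11 = s11_from_ab(a, b, N, Pi, Tau);
    out["S11"] = NumericVector(s11.begin(), s11.end());
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = "mie_batch_cpp")]]
List mie_batch_cpp(NumericVector x_core, NumericVector x_shell,
                   ComplexVector m_core, ComplexVector m_shell,
                   NumericVector mu, NumericVector w_back,
                   IntegerVector acc_group, NumericVector acc_weight,
                   int n_acc, int nmax_cap) {
  int ne = x_shell.size();
  int nm = mu.size();
  if (x_core.size() != ne || m_core.size() != ne || m_shell.size() != ne)
    stop("batch input lengths differ");
  if (nm > 0 && w_back.size() != nm) stop("w_back must match mu");

  // series cap and shared angular tables sized to the largest particle
  int Nmax = 1;
  for (int e = 0; e < ne; ++e) {
    if (x_shell[e] <= 0) stop("size parameter must be positive");
    check_cap(x_shell[e], nmax_cap);
    Nmax = std::max(Nmax, n_terms(x_shell[e]));
  }
  arma::mat Pi, Tau;
  arma::vec amu, wb;
  if (nm > 0) {
    amu = arma::vec(mu.begin(), nm);
    wb = arma::vec(w_back.begin(), nm);
    fill_pi_tau(amu, Nmax, Pi, Tau);
  }
  arma::mat acc;
  if (n_acc > 0 && nm > 0) acc.zeros(nm, n_acc);

  NumericVector Qext(ne), Qsca(ne), Qabs(ne), bbint(ne, NA_REAL);
  IntegerVector nterms(ne);
  std::vector<cx> a, b;
  for (int e = 0; e < ne; ++e) {
    int N = n_terms(x_shell[e]);
    nterms[e] = N;
    cx mc = sanitize_m(m_core[e]), ms = sanitize_m(m_shell[e]);
    coated_ab(x_core[e], x_shell[e], mc, ms, N, a, b);
    double qe, qs;
    efficiencies(a, b, x_shell[e], N, qe, qs);
    check_finite(qe, qs, x_core[e], x_shell[e], mc, ms);
    Qext[e] = qe;
    Qsca[e] = qs;
    Qabs[e] = qe - qs;
    if (nm > 0) {
      arma::vec s11 = s11_from_ab(a, b, N, Pi, Tau);
      bbint[e] = arma::dot(wb, s11);
      if (n_acc > 0) {
        int g = acc_group[e];
        if (g >= 1 && g <= n_acc) acc.col(g - 1) += acc_weight[e] * s11;
      }
    }
    if (e % 64 == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(_["Qext"] = Qext, _["Qsca"] = Qsca,
                          _["Qabs"] = Qabs, _["bb_int"] = bbint,
                          _["nterms"] = nterms);
  if (n_acc > 0 && nm > 0) out["S11_acc"] = wrap(acc);
  return out;
}
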