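#include <Rcpp.h>
using namespace Rcpp;

// Shared low-level kernels for the forward-Euler transcription of the
// sensitive/resistant Hahnfeldt system.
//
// Parameter vector layout (all rates per day, volumes mm^3):
//   p = (lambda1, lambda2, tau1, tau2, mu, b, d, beta1, beta, gamma)
// Weight vector layout:
//   w = (omega1, omega2, eta1, eta2, xi, epsilon, theta)
//
// States are floored at XFLOOR before logarithms; the floor is far below any
// trajectory of interest and only guards degenerate NLP iterates.

static const double XFLOOR = 1e-12;

static inline void rhs3(const double* p, double N1, double N2, double K,
                        double u, double v, double* f) {
  double N = N1 + N2;
  double lg = std::log(N / K);
  f[0] = -p[0] * N1 * lg - p[2] * N1 + p[3] * N2 - p[7] * N1 * u;
  f[1] = -p[1] * N2 * lg + p[2] * N1 - p[3] * N2;
  f[2] = -p[4] * K + p[5] * N - p[6] * std::pow(N, 2.0 / 3.0) * K
         - p[8] * K * u - p[9] * K * v;
}

// Jacobian of the vector field wrt (N1, N2, K), row-major 3x3.
static inline void jac3(const double* p, double N1, double N2, double K,
                        double u, double v, double* J) {
  double N = N1 + N2;
  double lg = std::log(N / K);
  double N13 = std::pow(N, -1.0 / 3.0);
  J[0] = -p[0] * lg - p[0] * N1 / N - p[2] - p[7] * u;
  J[1] = -p[0] * N1 / N + p[3];
  J[2] = p[0] * N1 / K;
  J[3] = -p[1] * N2 / N + p[2];
  J[4] = -p[1] * lg - p[1] * N2 / N - p[3];
  J[5] = p[1] * N2 / K;
  J[6] = p[5] - (2.0 / 3.0) * p[6] * N13 * K;
  J[7] = J[6];
  J[8] = -p[4] - p[6] * std::pow(N, 2.0 / 3.0) - p[8] * u - p[9] * v;
}

static inline double runningL(const double* w, double N1, double N2, double u,
                              double* parts /* tumor, resist, dose */) {
  double th = std::tanh((N2 - N1) / w[5]);
  double tumor = w[2] * N1 + w[3] * N2;
  double resist = 0.5 * w[4] * (1.0 + th);
  double dose = w[6] * u;
  if (parts) { parts[0] = tumor; parts[1] = resist; parts[2] = dose; }
  return tumor + resist + dose;
}

// [[Rcpp::export]]
NumericMatrix euler_rollout(NumericVector p, NumericVector x0, NumericVector u,
                            double v, double h) {
  int M = u.size();
  NumericMatrix X(M + 1, 3);
  double x[3] = { x0[0], x0[1], x0[2] };
  X(0, 0) = x[0]; X(0, 1) = x[1]; X(0, 2) = x[2];
  double f[3];
  for (int k = 0; k < M; ++k) {
    for (int j = 0; j < 3; ++j) if (x[j] < XFLOOR) x[j] = XFLOOR;
    rhs3(REAL(p), x[0], x[1], x[2], u[k], v, f);
    for (int j = 0; j < 3; ++j) x[j] += h * f[j];
    X(k + 1, 0) = x[0]; X(k + 1, 1) = x[1]; X(k + 1, 2) = x[2];
  }
  return X;
}

// Objective of the reduced transcription (states eliminated by the Euler
// recursion) with its exact gradient via the discrete adjoint.
// J = omega1 N1_M + omega2 N2_M
//     + h * sum_{k=0}^{M-1} (eta1 N1_k + eta2 N2_k + f(N1_k,N2_k) + theta u_k)
// [[Rcpp::export]]
List euler_objgrad(NumericVector p, NumericVector x0, NumericVector u,
                   double v, double h, NumericVector w, bool want_grad = true) {
  int M = u.size();
  NumericMatrix X(M + 1, 3);
  double x[3] = { x0[0], x0[1], x0[2] };
  X(0, 0) = x[0]; X(0, 1) = x[1]; X(0, 2) = x[2];
  double f[3], parts[3];
  double run_tumor = 0.0, run_resist = 0.0, run_dose = 0.0;
  const double* pp = REAL(p);
  const double* ww = REAL(w);
  for (int k = 0; k < M; ++k) {
    for (int j = 0; j < 3; ++j) if (x[j] < XFLOOR) x[j] = XFLOOR;
    runningL(ww, x[0], x[1], u[k], parts);
    run_tumor += parts[0]; run_resist += parts[1]; run_dose += parts[2];
    rhs3(pp, x[0], x[1], x[2], u[k], v, f);
    for (int j = 0; j < 3; ++j) x[j] += h * f[j];
    X(k + 1, 0) = x[0]; X(k + 1, 1) = x[1]; X(k + 1, 2) = x[2];
  }
  run_tumor *= h; run_resist *= h; run_dose *= h;
  double terminal = ww[0] * X(M, 0) + ww[1] * X(M, 1);
  double J = terminal + run_tumor + run_resist + run_dose;

  NumericVector grad(M);
  if (want_grad) {
    // adjoint sweep: lam_M = dphi/dx
    double lam[3] = { ww[0], ww[1], 0.0 };
    double Jm[9];
    for (int k = M - 1; k >= 0; --k) {
      double N1 = std::max(X(k, 0), XFLOOR);
      double N2 = std::max(X(k, 1), XFLOOR);
      double K  = std::max(X(k, 2), XFLOOR);
      // dJ/du_k = h * theta + h * lam_{k+1} . f_u
      grad[k] = h * ww[6]
        + h * (lam[0] * (-pp[7] * N1) + lam[2] * (-pp[8] * K));
      // lam_k = h * dL/dx + (I + h f_x)^T lam_{k+1}
      jac3(pp, N1, N2, K, u[k], v, Jm);
      double th = std::tanh((N2 - N1) / ww[5]);
      double sech2 = 1.0 - th * th;
      double Lx0 = ww[2] - 0.5 * ww[4] * sech2 / ww[5];
      double Lx1 = ww[3] + 0.5 * ww[4] * sech2 / ww[5];
      double nl[3];
      nl[0] = h * Lx0 + lam[0] + h * (Jm[0] * lam[0] + Jm[3] * lam[1] + Jm[6] * lam[2]);
      nl[1] = h * Lx1 + lam[1] + h * (Jm[1] * lam[0] + Jm[4] * lam[1] + Jm[7] * lam[2]);
      nl[2] =            lam[2] + h * (Jm[2] * lam[0] + Jm[5] * lam[1] + Jm[8] * lam[2]);
      lam[0] = nl[0]; lam[1] = nl[1]; lam[2] = nl[2];
    }
  }

  return List::create(
    _["objective"] = J,
    _["gradient"] = grad,
    _["states"] = X,
    _["terminal_part"] = terminal,
    _["running_tumor_part"] = run_tumor,
    _["resistance_part"] = run_resist,
    _["dose_part"] = run_dose);
}

// [[Rcpp::export]]
NumericVector rhs_cpp(NumericVector p, NumericVector x, double u, double v) {
  double f[3];
  rhs3(REAL(p), x[0], x[1], x[2], u, v, f);
  return NumericVector::create(f[0], f[1], f[2]);
}

// [[Rcpp::export]]
NumericMatrix jac_cpp(NumericVector p, NumericVector x, double u, double v) {
  double J[9];
  jac3(REAL(p), x[0], x[1], x[2], u, v, J);
  NumericMatrix out(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = J[3 * i + j];
  return out;
}
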