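#include <Rcpp.h>
using namespace Rcpp;

// Explicit Euler integrators for the dimensionless competitive-inhibition
// schemes. States (X, Y, P, Q) follow the iterative schemes of the theory;
// (S, I, E) are co-integrated with their own Euler updates so that the
// conservation planes V+P+S=1 and U/rho+Q+I=1 act as genuine accuracy
// diagnostics rather than identities. Storage is decimated to at most
// n_store points.

static inline int store_grid(int nsteps, int nstore) {
  int k = nsteps / (nstore - 1);
  if (k < 1) k = 1;
  return k;
}

// [[Rcpp::export]]
List euler_full_cpp(double eta_S, double eps_S, double kappa_S,
                    double eta_I, double eps_I, double kappa_I, double rho,
                    double tau_end, double dtau, int n_store,
                    double s_floor) {
  const double mu_S = eta_S + kappa_S, mu_I = eta_I + kappa_I;
  long nsteps = (long)std::ceil(tau_end / dtau);
  int k = store_grid(nsteps, n_store);
  int cap = (int)(nsteps / k) + 2;
  NumericVector tau(cap), Xo(cap), Yo(cap), Po(cap), Qo(cap),
      So(cap), Io(cap), Eo(cap);
  double X = 0, Y = 0, P = 0, Q = 0, S = 1, I = 1, E = 1;
  int m = 0;
  tau[m] = 0; Xo[m] = X; Yo[m] = Y; Po[m] = P; Qo[m] = Q;
  So[m] = S; Io[m] = I; Eo[m] = E; m++;
  std::string bad = "";
  long n;
  for (n = 1; n <= nsteps; n++) {
    double Sc = 1.0 - eps_S * X - P;   // conservation-substituted reactants
    double Ic = 1.0 - eps_I * Y - Q;
    double dX = (Sc * (1.0 - X - Y) - mu_S * X) / eta_S;
    double dY = rho * (Ic * (1.0 - X - Y) - mu_I * Y) / eta_I;
    double dP = eps_S * X;
    double dQ = rho * eps_I * Y;
    X += dX * dtau; Y += dY * dtau; P += dP * dtau; Q += dQ * dtau;
    S += (-eps_S * dX - dP) * dtau;
    I += (-eps_I * dY - dQ) * dtau;
    E += -(dX + dY) * dtau;
    if (X < -0.01 || X > 1.01) { bad = "X"; break; }
    if (Y < -0.01 || Y > 1.01) { bad = "Y"; break; }
    if (P < -0.01 || P > 1.01) { bad = "P"; break; }
    if (Q < -0.01 || Q > 1.01) { bad = "Q"; break; }
    if (n % k == 0 || n == nsteps) {
      tau[m] = n * dtau; Xo[m] = X; Yo[m] = Y; Po[m] = P; Qo[m] = Q;
      So[m] = S; Io[m] = I; Eo[m] = E; m++;
      if (S < s_floor && I < s_floor) break;
    }
  }
  Range r(0, m - 1);
  return List::create(_["tau"] = tau[r], _["X"] = Xo[r], _["Y"] = Yo[r],
                      _["P"] = Po[r], _["Q"] = Qo[r], _["S"] = So[r],
                      _["I"] = Io[r], _["E"] = Eo[r], _["bad"] = bad);
}

// [[Rcpp::export]]
List euler_partial_cpp(double eta_S, double eps_S, double kappa_S,
                       double chi_I, double eps_I, double kappa_I,
                       double tau_end, double dtau, int n_store,
                       double s_floor) {
  const double mu_S = eta_S + kappa_S;
  long nsteps = (long)std::ceil(tau_end / dtau);
  int k = store_grid(nsteps, n_store);
  int cap = (int)(nsteps / k) + 2;
  NumericVector tau(cap), Xo(cap), Yo(cap), Po(cap), So(cap), Io(cap),
      Eo(cap);
  double X = 0, Y = 0, P = 0, S = 1, I = 1, E = 1;
  int m = 0;
  tau[m] = 0; Xo[m] = X; Yo[m] = Y; Po[m] = P;
  So[m] = S; Io[m] = I; Eo[m] = E; m++;
  std::string bad = "";
  for (long n = 1; n <= nsteps; n++) {
    double Sc = 1.0 - eps_S * X - P;
    double Ic = 1.0 - eps_I * Y;
    double dX = (Sc * (1.0 - X - Y) - mu_S * X) / eta_S;
    double dY = (Ic * (1.0 - X - Y) - kappa_I * Y) / chi_I;
    double dP = eps_S * X;
    X += dX * dtau; Y += dY * dtau; P += dP * dtau;
    S += (-eps_S * dX - dP) * dtau;
    I += -eps_I * dY * dtau;
    E += -(dX + dY) * dtau;
    if (X < -0.01 || X > 1.01) { bad = "X"; break; }
    if (Y < -0.01 || Y > 1.01) { bad = "Y"; break; }
    if (P < -0.01 || P > 1.01) { bad = "P"; break; }
    if (n % k == 0 || n == nsteps) {
      tau[m] = n * dtau; Xo[m] = X; Yo[m] = Y; Po[m] = P;
      So[m] = S; Io[m] = I; Eo[m] = E; m++;
      // stop only once the substrate is exhausted AND the EI channel has
      // relaxed to its binding equilibrium
      if (S < s_floor && std::fabs(dY) < 1e-7) break;
    }
  }
  Range r(0, m - 1);
  return List::create(_["tau"] = tau[r], _["X"] = Xo[r], _["Y"] = Yo[r],
                      _["P"] = Po[r], _["S"] = So[r], _["I"] = Io[r],
                      _["E"] = Eo[r], _["bad"] = bad);
}

// phi-approximation: coupled linear system in (M, F, N, G) with the
// nonlinear phi terms dropped.
// [[Rcpp::export]]
List euler_phi_cpp(double eta_S, double eps_S, double eta_I, double eps_I,
                   double rho, double alpha_S, double alpha_I,
                   double tau_end, double dtau, int n_store) {
  long nsteps = (long)std::ceil(tau_end / dtau);
  int k = store_grid(nsteps, n_store);
  int cap = (int)(nsteps / k) + 2;
  NumericVector tau(cap), Mo(cap), Fo(cap), No(cap), Go(cap);
  double M = 0, F = 0, N = 0, G = 0;
  int m = 0;
  tau[m] = 0; Mo[m] = M; Fo[m] = F; No[m] = N; Go[m] = G; m++;
  const double c1 = alpha_S / eta_S, c2 = eps_S / eta_S;
  const double c3 = 1.0 / (eta_S * eta_S * eta_S);
  const double c4 = eta_I * eta_I / (rho * std::pow(eta_S, 3));
  const double c5 = rho * alpha_I / eta_I, c6 = eps_I * rho * rho / eta_I;
  const double c7 = rho * rho / std::pow(eta_I, 3);
  const double c8 = rho * rho * eta_S * eta_S / std::pow(eta_I, 3);
  for (long n = 1; n <= nsteps; n++) {
    double dF = -(c1 * F + c2 * M - c3 + c4 * G);
    double dG = -(c5 * G + c6 * N - c7 + c8 * F);
    M += F * dtau; N += G * dtau;
    F += dF * dtau; G += dG * dtau;
    if (n % k == 0 || n == nsteps) {
      tau[m] = n * dtau; Mo[m] = M; Fo[m] = F; No[m] = N; Go[m] = G; m++;
    }
  }
  Range r(0, m - 1);
  return List::create(_["tau"] = tau[r], _["M"] = Mo[r], _["F"] = Fo[r],
                      _["N"] = No[r], _["G"] = Go[r]);
}
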