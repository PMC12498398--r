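// Wertheim TPT1 core for patchy-particle mixtures.
//
// All quantities are in reduced units (sigma = 1, reference bond energy = 1,
// k_B = 1). Free energies are per particle in k_B T; pressures are beta*P in
// units of sigma^-3; chemical potentials are beta*mu.
//
// The association (bonding) pressure and chemical potentials follow from the
// stationarity of the Wertheim functional with respect to the not-bonded
// probabilities X, which leaves only the explicit density dependence of the
// bond-strength integrals (through the hard-sphere contact value) plus the
// ln X terms.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// Solve the law of mass action X_a = 1 / (1 + sum_g B[a][g] X_g) by damped
// fixed-point iteration with a Newton polish. B[a][g] = phi * x_owner(g) *
// Delta[a][g]. Returns the residual max |X (1 + B X) - 1|.
static double solve_mass_action_core(const std::vector<double>& B, int n,
                                     std::vector<double>& X, int max_iter,
                                     double tol) {
  std::vector<double> BX(n), F(n);
  auto compute_BX = [&](const std::vector<double>& Xv) {
    for (int a = 0; a < n; ++a) {
      double s = 0.0;
      for (int g = 0; g < n; ++g) s += B[a * n + g] * Xv[g];
      BX[a] = s;
    }
  };
  auto residual = [&](const std::vector<double>& Xv) {
    compute_BX(Xv);
    double r = 0.0;
    for (int a = 0; a < n; ++a) {
      double f = Xv[a] * (1.0 + BX[a]) - 1.0;
      if (std::fabs(f) > r) r = std::fabs(f);
    }
    return r;
  };

  // damped fixed point (damping 0.5) from X = 1
  for (int a = 0; a < n; ++a) X[a] = 1.0;
  double res = residual(X);
  int it = 0;
  while (res > 1e-9 && it < max_iter) {
    compute_BX(X);
    for (int a = 0; a < n; ++a)
      X[a] = 0.5 * X[a] + 0.5 / (1.0 + BX[a]);
    res = residual(X);
    ++it;
  }

  // Newton polish: J[a][b] = delta_ab (1 + BX_a) + X_a B[a][b]
  std::vector<double> J(n * n), dx(n);
  for (int nit = 0; nit < 50 && res > tol; ++nit) {
    compute_BX(X);
    for (int a = 0; a < n; ++a) {
      F[a] = X[a] * (1.0 + BX[a]) - 1.0;
      for (int b = 0; b < n; ++b)
        J[a * n + b] = X[a] * B[a * n + b] + (a == b ? 1.0 + BX[a] : 0.0);
    }
    // Gaussian elimination with partial pivoting
    std::vector<int> piv(n);
    for (int i = 0; i < n; ++i) piv[i] = i;
    for (int c = 0; c < n; ++c) {
      int p = c;
      for (int r = c + 1; r < n; ++r)
        if (std::fabs(J[r * n + c]) > std::fabs(J[p * n + c])) p = r;
      if (p != c) {
        for (int k = 0; k < n; ++k) std::swap(J[c * n + k], J[p * n + k]);
        std::swap(F[c], F[p]);
      }
      double d = J[c * n + c];
      if (std::fabs(d) < 1e-300) { d = 1e-300; }
      for (int r = c + 1; r < n; ++r) {
        double m = J[r * n + c] / d;
        for (int k = c; k < n; ++k) J[r * n + k] -= m * J[c * n + k];
        F[r] -= m * F[c];
      }
    }
    for (int r = n - 1; r >= 0; --r) {
      double s = F[r];
      for (int k = r + 1; k < n; ++k) s -= J[r * n + k] * dx[k];
      dx[r] = s / J[r * n + r];
    }
    for (int a = 0; a < n; ++a) {
      double xn = X[a] - dx[a];
      if (xn <= 0.0) xn = 0.5 * X[a];   // keep inside (0, 1]
      if (xn > 1.0) xn = 1.0;
      X[a] = xn;
    }
    res = residual(X);
  }
  return res;
}

// Evaluate the full TPT1 equation of state at each density in `rho` for
// composition(s) x (a matrix with one row shared by all densities, or one row
// per density) and temperature T. `owner` gives, for each global patch type,
// the (1-based) species that carries it. `ghs_mode` selects the hard-sphere
// pair-correlation treatment in the bond-strength integral: 0 = g_HS = 1,
// 1 = Carnahan-Starling contact value, 2 = shell-integrated Percus-Yevick
// g(r), supplied as polynomial coefficients (ascending, in phi) of the log
// of the shell-averaged correlation factor.
// [[Rcpp::export]]
List wz_eos_cpp(NumericVector rho, NumericMatrix xmat, double T,
                NumericMatrix eps, IntegerVector owner, int n_species,
                double sigma, double delta, double cos_theta_max,
                int ghs_mode, NumericVector shell_coefs,
                int max_iter = 100000, double tol = 1e-12) {
  const int n = eps.nrow();
  const int m = rho.size();
  const bool shared_x = (xmat.nrow() == 1);
  if (!shared_x && xmat.nrow() != m)
    stop("composition matrix must have 1 row or one row per density");
  const double Vs = PI / 6.0 * sigma * sigma * sigma;
  const double w = 0.5 * (1.0 - cos_theta_max);
  const double shell = 4.0 * PI / 3.0 *
      (std::pow(sigma + delta, 3) - std::pow(sigma, 3));
  const double K0 = w * w * shell / Vs;  // geometric factor of Delta, g_HS = 1

  // Mayer factor per patch pair (temperature only)
  std::vector<double> mayer(n * n);
  for (int a = 0; a < n; ++a)
    for (int g = 0; g < n; ++g)
      mayer[a * n + g] = eps(a, g) > 0.0 ? std::expm1(eps(a, g) / T) : 0.0;

  NumericVector P(m), f_id(m), f_hs(m), f_bond(m), f_tot(m), gibbs(m), resid(m);
  NumericMatrix mu(m, n_species), Xout(m, n);

  std::vector<double> B(n * n), X(n), x(n_species);

  for (int k = 0; k < m; ++k) {
    const int xr = shared_x ? 0 : k;
    for (int i = 0; i < n_species; ++i) x[i] = xmat(xr, i);
    double xlogx = 0.0;
    for (int i = 0; i < n_species; ++i)
      if (x[i] > 0.0) xlogx += x[i] * std::log(x[i]);
    const double r = rho[k];
    const double phi = r * Vs;
    if (!(r > 0.0) || phi >= 1.0) {
      P[k] = NA_REAL; f_id[k] = NA_REAL; f_hs[k] = NA_REAL; f_bond[k] = NA_REAL;
      f_tot[k] = NA_REAL; gibbs[k] = NA_REAL; resid[k] = NA_REAL;
      for (int i = 0; i < n_species; ++i) mu(k, i) = NA_REAL;
      for (int a = 0; a < n; ++a) Xout(k, a) = NA_REAL;
      continue;
    }
    const double omp = 1.0 - phi;
    double gc = 1.0, dlng = 0.0;  // shell correlation factor and d ln g / d phi
    if (ghs_mode == 1) {
      gc = (1.0 - 0.5 * phi) / (omp * omp * omp);
      dlng = 3.0 / omp - 0.5 / (1.0 - 0.5 * phi);
    } else if (ghs_mode == 2) {
      double lng = 0.0, p = 1.0;
      for (int c = 1; c < shell_coefs.size(); ++c) {
        dlng += c * shell_coefs[c] * p;
        p *= phi;
        lng += shell_coefs[c] * p;
      }
      gc = std::exp(lng);
    }
    const double Kg = K0 * gc;

    for (int a = 0; a < n; ++a)
      for (int g = 0; g < n; ++g)
        B[a * n + g] = phi * x[owner[g] - 1] * mayer[a * n + g] * Kg;

    resid[k] = solve_mass_action_core(B, n, X, max_iter, tol);
    for (int a = 0; a < n; ++a) Xout(k, a) = X[a];

    f_id[k] = std::log(r) - 1.0 + xlogx;
    f_hs[k] = (4.0 * phi - 3.0 * phi * phi) / (omp * omp);
    double fb = 0.0, D = 0.0;
    for (int a = 0; a < n; ++a) {
      const double xa = x[owner[a] - 1];
      fb += xa * (std::log(X[a]) - 0.5 * X[a] + 0.5);
      D += 0.5 * r * xa * (1.0 - X[a]);
    }
    f_bond[k] = fb;
    f_tot[k] = f_id[k] + f_hs[k] + f_bond[k];

    const double dfhs = (4.0 - 2.0 * phi) / (omp * omp * omp);  // d f_hs / d phi
    const double P_hs = r * phi * dfhs;
    const double P_bond = -D * (1.0 + phi * dlng);
    P[k] = r + P_hs + P_bond;

    const double mu_hs = f_hs[k] + phi * dfhs;
    const double mu_b_common = -Vs * dlng * D;
    for (int i = 0; i < n_species; ++i) {
      double mb = mu_b_common;
      for (int a = 0; a < n; ++a)
        if (owner[a] - 1 == i) mb += std::log(X[a]);
      mu(k, i) = (x[i] > 0.0 ? std::log(r * x[i]) : R_NegInf) + mu_hs + mb;
    }
    gibbs[k] = f_tot[k] + P[k] / r;
  }

  return List::create(_["P"] = P, _["f_ideal"] = f_id, _["f_hs"] = f_hs,
                      _["f_bonding"] = f_bond, _["f_total"] = f_tot,
                      _["g"] = gibbs, _["mu"] = mu, _["X"] = Xout,
                      _["residual"] = resid);
}
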