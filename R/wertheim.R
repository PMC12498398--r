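#' Thermodynamic state point
#'
#' @param T Temperature in reduced units (bond energy over k_B).
#' @param rho Total number density in units of sigma^-3 (may be `NA` when the
#'   state is specified by pressure instead).
#' @param x Composition vector (molar fractions, summing to 1).
#' @return An object of class `state_point`.
#' @export
state_point <- function(T, rho = NA_real_, x = 1) {
  stopifnot(is.numeric(T), length(T) == 1L, T > 0)
  if (!is.na(rho)) stopifnot(is.numeric(rho), rho >= 0)
  x <- as.numeric(x)
  if (any(x < 0) || abs(sum(x) - 1) > 1e-12)
    stop("`x` entries must be >= 0 and sum to 1", call. = FALSE)
  structure(list(T = T, rho = rho, x = x), class = "state_point")
}

# particle volume
v_sphere <- function(sigma) pi / 6 * sigma^3

design_pars <- function(design) {
  list(eps = design$energy_matrix, owner = design$owner,
       n_species = length(design$species), sigma = design$kf$sigma,
       delta = design$kf$delta, cos_theta_max = design$kf$cos_theta_max)
}

# vectorized EOS evaluation: `rho` a vector, `x` a composition vector shared
# by all densities or a matrix with one composition row per density
wz_eval <- function(design, T, rho, x, ghs = "shell") {
  p <- design_pars(design)
  xm <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1)
  mode <- ghs_mode_code(ghs)
  coefs <- if (mode == 2L) shell_poly_coefs(p$sigma, p$delta) else numeric()
  wz_eos_cpp(as.numeric(rho), xm, T, p$eps, p$owner, p$n_species,
             p$sigma, p$delta, p$cos_theta_max, mode, coefs)
}

#' Hard-sphere contact value used in the bond-strength integral
#'
#' Carnahan-Starling contact value `(1 - phi/2) / (1 - phi)^3`.
#'
#' @param phi Packing fraction.
#' @return Contact value of the hard-sphere radial distribution function.
#' @export
ghs_contact_value <- function(phi) (1 - phi / 2) / (1 - phi)^3

#' Bond-strength matrix
#'
#' Computes the dimensionless bond strengths
#' `Delta[alpha, gamma] = (exp(eps/T) - 1) * K(phi)` where `K` is the
#' geometric bond-volume factor
#' `(1/Vs) * ((1 - cos_theta_max)/2)^2 * 4*pi/3 * ((sigma+delta)^3 - sigma^3) * g`
#' and `g` is the hard-sphere pair correlation averaged over the bonding
#' shell: the full Percus-Yevick `g(r)` integrated across
#' `[sigma, sigma + delta]` (`ghs = "shell"`, the default), the
#' Carnahan-Starling contact value treated as constant across the shell
#' (`ghs = "contact"`), or 1 (`ghs = "unit"`, the low-density form). Pairs
#' with zero bonding energy have `Delta = 0` exactly.
#'
#' @param design A [mixture_design()].
#' @param state A [state_point()] with a finite density.
#' @param ghs `"shell"`, `"contact"` or `"unit"`.
#' @return An object of class `bond_strength_matrix`: list with the
#'   `delta_matrix` and a `details` record of the approximation used.
#' @export
compute_delta <- function(design, state, ghs = c("shell", "contact", "unit")) {
  ghs <- match.arg(ghs)
  kf <- design$kf
  Vs <- v_sphere(kf$sigma)
  phi <- state$rho * Vs
  if (is.na(phi) || phi < 0 || phi >= 1)
    stop("state density gives packing fraction outside [0, 1)", call. = FALSE)
  gval <- switch(ghs,
                 contact = ghs_contact_value(phi),
                 unit = 1,
                 shell = shell_g_factor(phi, kf$sigma, kf$delta))
  w <- (1 - kf$cos_theta_max) / 2
  K <- w^2 * 4 * pi / 3 * ((kf$sigma + kf$delta)^3 - kf$sigma^3) / Vs * gval
  dm <- expm1(design$energy_matrix / state$T) * K
  dm[design$energy_matrix == 0] <- 0
  structure(list(delta_matrix = dm,
                 details = list(ghs = ghs, g_value = gval, K_geom = K,
                                phi = phi, T = state$T)),
            class = "bond_strength_matrix")
}

#' Solve the law of mass action
#'
#' Finds the not-bonded probabilities `X[alpha]` (one per global patch type)
#' satisfying `X[alpha] = 1 / (1 + phi * sum_j x_j * sum_{gamma in j}
#' X[gamma] * Delta[alpha, gamma])` by damped fixed-point iteration
#' (damping 0.5, started from X = 1) with a Newton polish.
#'
#' @param design A [mixture_design()].
#' @param state A [state_point()].
#' @param delta A [compute_delta()] result; computed from the state if omitted.
#' @param tol Convergence tolerance on the fixed-point residual.
#' @param max_iter Maximum fixed-point iterations.
#' @return An object of class `mass_action_solution`: list with `X` (named by
#'   patch type), `residual`, and the owning species of each patch.
#' @export
solve_mass_action <- function(design, state, delta = NULL, tol = 1e-12,
                              max_iter = 1e5) {
  if (is.null(delta)) delta <- compute_delta(design, state)
  dm <- delta$delta_matrix
  phi <- state$rho * v_sphere(design$kf$sigma)
  xw <- state$x[design$owner]          # molar fraction of each patch's owner
  B <- phi * sweep(dm, 2, xw, "*")     # B[a, g] = phi * x_owner(g) * Delta
  n <- nrow(B)
  X <- rep(1, n)
  res <- function(X) max(abs(X * (1 + B %*% X) - 1))
  r <- res(X)
  it <- 0L
  while (r > 1e-9 && it < max_iter) {
    X <- 0.5 * X + 0.5 / (1 + as.numeric(B %*% X))
    r <- res(X)
    it <- it + 1L
  }
  for (k in 1:50) {
    if (r <= tol) break
    BX <- as.numeric(B %*% X)
    FF <- X * (1 + BX) - 1
    J <- diag(1 + BX, n) + X * B
    X <- pmin(pmax(X - solve(J, FF), 1e-300), 1)
    r <- res(X)
  }
  if (r > tol)
    stop(sprintf("mass-action solver did not converge: residual %.3e", r),
         call. = FALSE)
  structure(list(X = stats::setNames(as.numeric(X), seq_len(n)),
                 residual = r, owner = design$owner),
            class = "mass_action_solution")
}

#' Not-bonded probability of an ideal-azeotropic mixture
#'
#' For ideal-azeotropic designs the law of mass action reduces to the
#' single-component form `X + phi * X^2 * Delta - 1 = 0`, whose physical
#' root is returned. The result is independent of composition.
#'
#' @param phi Packing fraction.
#' @param delta Dimensionless bond strength.
#' @return The positive root, or 1 when `phi * delta == 0`.
#' @export
ideal_azeotrope_X <- function(phi, delta) {
  pd <- phi * delta
  ifelse(pd == 0, 1, (-1 + sqrt(1 + 4 * pd)) / (2 * pd))
}

#' Helmholtz free energy per particle
#'
#' Returns the Wertheim TPT1 free-energy breakdown (per particle, in k_B T):
#' ideal part `ln rho - 1 + sum x ln x`, Carnahan-Starling hard-sphere
#' excess `(4 phi - 3 phi^2)/(1 - phi)^2`, and the bonding part
#' `sum_i x_i [ sum_alpha (ln X_alpha - X_alpha / 2) + Gamma(i)/2 ]`.
#'
#' @param design A [mixture_design()].
#' @param state A [state_point()] with finite density.
#' @param ghs Pair-correlation treatment for the bond strengths.
#' @return An object of class `free_energy_breakdown` with fields `f_ideal`,
#'   `f_hs`, `f_bonding`, `f_total`.
#' @export
free_energy <- function(design, state, ghs = "shell") {
  phi <- state$rho * v_sphere(design$kf$sigma)
  if (is.na(phi) || phi >= 1)
    stop("packing fraction must be < 1", call. = FALSE)
  e <- wz_eval(design, state$T, state$rho, state$x, ghs)
  structure(list(f_ideal = e$f_ideal[1], f_hs = e$f_hs[1],
                 f_bonding = e$f_bonding[1], f_total = e$f_total[1]),
            class = "free_energy_breakdown")
}

#' Pressure from the equation of state
#'
#' `beta * P` in units of `sigma^-3`, from the analytic density derivative of
#' the TPT1 free energy at fixed composition.
#'
#' @inheritParams free_energy
#' @return Numeric scalar, `beta * P`.
#' @export
pressure <- function(design, state, ghs = "shell") {
  wz_eval(design, state$T, state$rho, state$x, ghs)$P[1]
}

#' Chemical potentials
#'
#' `beta * mu_i` for every species, from the analytic composition derivatives
#' of the TPT1 free-energy density (de Broglie volumes set to 1).
#'
#' @inheritParams free_energy
#' @return Numeric vector, one entry per species.
#' @export
chemical_potentials <- function(design, state, ghs = "shell") {
  as.numeric(wz_eval(design, state$T, state$rho, state$x, ghs)$mu)
}
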