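# The S0 route to chemical potentials: partial structure factors from
# stored configurations, Ornstein-Zernike k -> 0 extrapolation, and the
# Kirkwood-Buff composition integral.

#' Partial structure factors from stored configurations
#'
#' Computes the partial structure factors
#' `S_ab(k) = < Re[ rho_a(k) rho_b(-k) ] > / N` with
#' `rho_a(k) = sum_{j in species a} exp(i k . r_j)` and `N` the total
#' particle count, averaged over frames and over wavevector shells (all
#' integer multiples of `2 pi / L` with equal modulus). For NPT frames with
#' fluctuating box length the integer wavevector indices are fixed and `k`
#' is reported at the mean box size. This N-normalized convention is
#' recorded in the metadata and is the one assumed by [excess_mu()].
#'
#' @param frames List of configurations (`L`, `positions`, `species`), e.g.
#'   the `frames` of an [run_npt()] result.
#' @param k_max Maximum wavevector modulus (in units of `2 pi / L`).
#' @param min_frames Minimum number of frames required.
#' @return An object of class `structure_factor_data`: `k_grid`, `S_AA`,
#'   `S_BB`, `S_AB`, shell multiplicities, frame count and metadata. The
#'   `S0_*` and `xi_*` fields are filled by [oz_fit()].
#' @export
partial_structure_factors <- function(frames, k_max = 6, min_frames = 50) {
  if (length(frames) < min_frames)
    stop(sprintf("need at least %d frames (got %d)", min_frames,
                 length(frames)), call. = FALSE)
  # integer wavevectors with 0 < |n| <= k_max
  rng <- -floor(k_max):floor(k_max)
  nv <- as.matrix(expand.grid(nx = rng, ny = rng, nz = rng))
  n2 <- rowSums(nv^2)
  keep <- n2 > 0 & n2 <= k_max^2
  nv <- nv[keep, , drop = FALSE]
  n2 <- n2[keep]
  shell <- sqrt(n2)
  Lbar <- mean(vapply(frames, `[[`, 0, "L"))
  acc <- matrix(0, length(n2), 3)  # AA, BB, AB accumulators
  Ntot <- 0
  for (fr in frames) {
    pos <- fr$positions
    spc <- fr$species
    N <- length(spc)
    Ntot <- Ntot + N
    K <- 2 * pi / fr$L * nv
    phase <- pos %*% t(K)                     # N x nk
    ea <- exp(1i * phase)
    rA <- colSums(ea[spc == 1L, , drop = FALSE])
    rB <- if (any(spc == 2L)) colSums(ea[spc == 2L, , drop = FALSE]) else
      complex(length(n2))
    acc[, 1] <- acc[, 1] + Re(rA * Conj(rA)) / N
    acc[, 2] <- acc[, 2] + Re(rB * Conj(rB)) / N
    acc[, 3] <- acc[, 3] + Re(rA * Conj(rB)) / N
  }
  acc <- acc / length(frames)
  sh <- round(shell, 9)
  ug <- sort(unique(sh))
  agg <- function(v) vapply(ug, function(s) mean(v[sh == s]), 0)
  structure(list(k_grid = 2 * pi / Lbar * ug,
                 S_AA = agg(acc[, 1]), S_BB = agg(acc[, 2]),
                 S_AB = agg(acc[, 3]),
                 multiplicity = vapply(ug, function(s) sum(sh == s), 0),
                 n_frames = length(frames), L = Lbar,
                 S0_AA = NA_real_, S0_BB = NA_real_, S0_AB = NA_real_,
                 xi2_AA = NA_real_, xi2_BB = NA_real_, xi2_AB = NA_real_,
                 se = NULL,
                 meta = list(convention = "S_ab(k) = <rho_a rho_b*>/N_total",
                             mean_N = Ntot / length(frames))),
            class = "structure_factor_data")
}

#' @export
print.structure_factor_data <- function(x, ...) {
  cat(sprintf("Partial structure factors: %d shells (k in [%.3f, %.3f]), %d frames\n",
              length(x$k_grid), min(x$k_grid), max(x$k_grid), x$n_frames))
  if (!is.na(x$S0_AA))
    cat(sprintf("  OZ k->0: S0_AA = %.4f, S0_BB = %.4f, S0_AB = %.4f\n",
                x$S0_AA, x$S0_BB, x$S0_AB))
  invisible(x)
}

# Ornstein-Zernike fit of one partial: S(k) = S0 / (1 + k^2 xi2).
# Linear initialization on 1/S, Levenberg-Marquardt refinement.
oz_fit_one <- function(k, S, w = NULL) {
  if (length(k) < 4) stop("need at least 4 k-points for the OZ fit", call. = FALSE)
  if (max(S) - min(S) < 1e-13) {           # constant data: xi2 = 0 exactly
    return(list(S0 = mean(S), xi2 = 0, se_S0 = 0, se_xi2 = 0))
  }
  k2 <- k^2
  init <- if (all(S > 0) || all(S < 0)) {
    cf <- stats::coef(stats::lm(I(1 / S) ~ k2))
    c(S0 = 1 / cf[[1]], xi2 = cf[[2]] / cf[[1]])
  } else c(S0 = S[which.min(k)], xi2 = 1)
  df <- data.frame(k2 = k2, S = S)
  amp <- max(abs(S))
  # box constraints keep the fit identifiable for noisy near-zero partials
  lo <- c(S0 = -3 * amp, xi2 = 0)
  hi <- c(S0 = 3 * amp, xi2 = (20 / min(k))^2)
  init[1] <- min(max(init[[1]], lo[1]), hi[1])
  init[2] <- min(max(init[[2]], lo[2]), hi[2])
  fit <- tryCatch(
    minpack.lm::nlsLM(S ~ S0 / (1 + k2 * xi2), data = df,
                      start = list(S0 = init[[1]], xi2 = init[[2]]),
                      lower = lo, upper = hi,
                      weights = if (is.null(w)) rep(1, length(k)) else w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  wm <- if (is.null(w)) mean(S) else sum(w * S) / sum(w)
  if (is.null(fit))
    return(list(S0 = wm, xi2 = 0, se_S0 = stats::sd(S) / sqrt(length(S)),
                se_xi2 = NA_real_))
  sm <- summary(fit)$coefficients
  list(S0 = sm["S0", 1], xi2 = sm["xi2", 1],
       se_S0 = sm["S0", 2], se_xi2 = sm["xi2", 2])
}

#' Ornstein-Zernike extrapolation of partial structure factors to k = 0
#'
#' Fits each partial structure factor to `S(k) = S0 / (1 + k^2 xi_A xi_B)`
#' over the shells with `k <= k_fit_max`, by least squares (linear
#' initialization on `1/S`, Levenberg-Marquardt refinement), and stores the
#' extrapolated `S0` values, the correlation-length products and their fit
#' standard errors on the input object.
#'
#' @param sf A [partial_structure_factors()] result.
#' @param k_fit_max Upper end of the fit window (absolute k units); defaults
#'   to the 6th shell.
#' @return The updated `structure_factor_data`.
#' @export
oz_fit <- function(sf, k_fit_max = NULL) {
  if (is.null(k_fit_max)) k_fit_max <- sort(sf$k_grid)[min(6, length(sf$k_grid))]
  sel <- sf$k_grid <= k_fit_max + 1e-12
  if (sum(sel) < 4)
    stop("fewer than 4 k-points below k_fit_max", call. = FALSE)
  k <- sf$k_grid[sel]
  w <- sf$multiplicity[sel]
  fits <- list(AA = oz_fit_one(k, sf$S_AA[sel], w),
               BB = oz_fit_one(k, sf$S_BB[sel], w),
               AB = oz_fit_one(k, sf$S_AB[sel], w))
  sf$S0_AA <- fits$AA$S0; sf$xi2_AA <- fits$AA$xi2
  sf$S0_BB <- fits$BB$S0; sf$xi2_BB <- fits$BB$xi2
  sf$S0_AB <- fits$AB$S0; sf$xi2_AB <- fits$AB$xi2
  sf$se <- list(S0_AA = fits$AA$se_S0, S0_BB = fits$BB$se_S0,
                S0_AB = fits$AB$se_S0, xi2_AA = fits$AA$se_xi2,
                xi2_BB = fits$BB$se_xi2, xi2_AB = fits$AB$se_xi2)
  sf$meta$k_fit_max <- k_fit_max
  sf
}

#' Excess chemical potential from k = 0 structure factors (Kirkwood-Buff)
#'
#' Integrates the concentration-fluctuation form of the Kirkwood-Buff
#' relation from the pure reference state `x_A = 1` down the composition
#' grid:
#' `beta mu_A^ex(x_A) = Int_1^{x_A} dx [ x_B / S_cc(0) - 1 / x_A ]` with the
#' Bhatia-Thornton concentration structure factor
#' `S_cc(0) = x_B^2 S0_AA + x_A^2 S0_BB - 2 x_A x_B S0_AB` (N-normalized
#' partials). For an ideal mixture `S_cc = x_A x_B` and the integrand
#' vanishes identically, which fixes both the convention and the integrand
#' reading; the choice is recorded in the metadata. Trapezoidal quadrature;
#' the integrand at the `x = 1` endpoint (a 0/0 limit) is linearly
#' extrapolated from the two nearest interior points. `S0` fit errors are
#' propagated in quadrature.
#'
#' @param x_grid Composition grid including 1, in decreasing order from 1.
#' @param S0_AA,S0_BB,S0_AB Extrapolated structure factors on the grid.
#' @param T Temperature (converts `beta mu` to energy units).
#' @param se List of per-point standard errors (optional, same names).
#' @return An object of class `chemical_potential_curve` with `x_grid`,
#'   `mu_ex`, `se_mu_ex`, `T`; `mu0` is `NA` until [total_mu()].
#' @export
excess_mu <- function(x_grid, S0_AA, S0_BB, S0_AB, T, se = NULL) {
  ord <- order(x_grid, decreasing = TRUE)
  x <- x_grid[ord]
  if (abs(x[1] - 1) > 1e-9)
    stop("composition grid must reach the reference state x = 1", call. = FALSE)
  if (any(diff(x) >= 0)) stop("composition grid must be strictly monotone",
                              call. = FALSE)
  sAA <- S0_AA[ord]; sBB <- S0_BB[ord]; sAB <- S0_AB[ord]
  xB <- 1 - x
  scc <- xB^2 * sAA + x^2 * sBB - 2 * x * xB * sAB
  f <- xB / scc - 1 / x
  dfds <- -xB / scc^2   # d f / d S_cc
  if (!is.null(se)) {
    se_scc <- sqrt((xB^2 * se$S0_AA[ord])^2 + (x^2 * se$S0_BB[ord])^2 +
                   (2 * x * xB * se$S0_AB[ord])^2)
    se_f <- abs(dfds) * se_scc
  } else se_f <- rep(0, length(x))
  # x = 1 endpoint: 0/0; linear extrapolation from the interior
  if (length(x) >= 3) {
    f[1] <- f[2] + (f[2] - f[3]) / (x[2] - x[3]) * (x[1] - x[2])
    se_f[1] <- se_f[2]
  } else f[1] <- 0
  n <- length(x)
  mu <- numeric(n); var_mu <- numeric(n)
  for (i in 2:n) {
    h <- x[i] - x[i - 1]               # negative (descending)
    mu[i] <- mu[i - 1] + 0.5 * h * (f[i] + f[i - 1])
    var_mu[i] <- var_mu[i - 1] + (0.5 * h)^2 * (se_f[i]^2 + se_f[i - 1]^2)
  }
  structure(list(x_grid = x, mu_ex = T * mu, se_mu_ex = T * sqrt(var_mu),
                 T = T, mu0 = NA_real_, x0 = 1,
                 meta = list(integrand = "x_B / S_cc0 - 1 / x_A",
                             Scc = "x_B^2 S_AA + x_A^2 S_BB - 2 x_A x_B S_AB")),
            class = "chemical_potential_curve")
}

#' Assemble the total chemical potential
#'
#' `mu_A(x) = mu0 + T ln(x / x0) + mu_ex(x)` with the pure-state reference
#' `x0 = 1`.
#'
#' @param curve An [excess_mu()] result.
#' @param mu0 Reference chemical potential of the pure species (energy
#'   units), e.g. from grand-canonical density matching ([match_mu0()]).
#' @return The curve with `mu_total` and `mu0` filled in.
#' @export
total_mu <- function(curve, mu0) {
  curve$mu0 <- mu0
  curve$mu_total <- mu0 + curve$T * log(curve$x_grid / curve$x0) + curve$mu_ex
  curve
}

#' @export
print.chemical_potential_curve <- function(x, ...) {
  cat(sprintf("Chemical-potential curve (T = %g): %d compositions, max |mu_ex| = %.4f\n",
              x$T, length(x$x_grid), max(abs(x$mu_ex))))
  if (!is.na(x$mu0)) cat(sprintf("  reference mu0 = %.4f at x0 = %g\n", x$mu0, x$x0))
  invisible(x)
}

#' @export
plot.chemical_potential_curve <- function(x, ...) {
  graphics::plot(x$x_grid, x$mu_ex, type = "b", pch = 1,
                 xlab = "x (species 1)", ylab = "mu (energy units)",
                 ylim = range(c(x$mu_ex, x$mu_total), na.rm = TRUE), ...)
  if (!is.null(x$mu_total)) {
    graphics::points(x$x_grid, x$mu_total, pch = 19, type = "b")
    graphics::curve(x$mu0 + x$T * log(xx / x$x0), xname = "xx", add = TRUE,
                    lty = 2)
  }
  invisible(x)
}

#' Reference chemical potential by grand-canonical density matching
#'
#' Bisects the chemical potential of a pure species until the mean
#' grand-canonical density matches a target (typically the mean NPT density
#' at the state of interest), the standard route to the reference `mu0` of
#' the S0 method.
#'
#' @param design A [mixture_design()].
#' @param species Species to simulate pure (1-based).
#' @param T Temperature.
#' @param rho_target Target number density.
#' @param mu_bracket Initial bracket for `mu` (energy units).
#' @param N0 Initial particle count of the GCMC box.
#' @param L Box edge; defaults to `(N0 / rho_target)^(1/3)`.
#' @param sweeps,equil Sweeps per GCMC run and equilibration cut.
#' @param iters Bisection iterations.
#' @param seed Optional seed.
#' @return List with `mu0`, `rho` (matched density), `se_rho` and the
#'   bisection `trace`.
#' @export
match_mu0 <- function(design, species = 1L, T, rho_target,
                      mu_bracket = c(-1, 1), N0 = 200, L = NULL,
                      sweeps = 4000, equil = 1000, iters = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(L)) L <- (N0 / rho_target)^(1 / 3)
  nsp <- length(design$species)
  mean_rho <- function(mu) {
    npsp <- integer(nsp); npsp[species] <- N0
    st <- make_initial_config(npsp, N0 / L^3, design)
    st$L <- L  # same box for all runs
    muv <- rep(-1e6, nsp); muv[species] <- mu
    r <- run_gcmc(st, design, T, muv, sweeps = sweeps, obs_stride = 5)
    ob <- r$observables
    ba <- block_average(ob$rho[ob$sweep > equil])
    c(ba$mean, ba$se)
  }
  lo <- mu_bracket[1]; hi <- mu_bracket[2]
  trace <- data.frame()
  rlo <- mean_rho(lo); rhi <- mean_rho(hi)
  trace <- rbind(trace, data.frame(mu = c(lo, hi), rho = c(rlo[1], rhi[1])))
  if ((rlo[1] - rho_target) * (rhi[1] - rho_target) > 0)
    stop("mu bracket does not straddle the target density", call. = FALSE)
  best <- list(mu = NA_real_, rho = NA_real_, se = NA_real_, miss = Inf)
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    rm <- mean_rho(mid)
    trace <- rbind(trace, data.frame(mu = mid, rho = rm[1]))
    if (abs(rm[1] - rho_target) < best$miss)
      best <- list(mu = mid, rho = rm[1], se = rm[2],
                   miss = abs(rm[1] - rho_target))
    if ((rm[1] - rho_target) * (rlo[1] - rho_target) > 0) {
      lo <- mid; rlo <- rm
    } else hi <- mid
    if (abs(rm[1] - rho_target) < rm[2]) break  # matched within its own error
  }
  list(mu0 = best$mu, rho = best$rho, se_rho = best$se, trace = trace)
}

#' Full S0 chemical-potential pipeline
#'
#' For each composition of the grid, runs an NPT simulation at `(T, P)`,
#' accumulates partial structure factors from stored frames, extrapolates
#' them to `k = 0` with [oz_fit()], and evaluates the Kirkwood-Buff
#' integral; optionally assembles the total chemical potential from a
#' supplied or GCMC-matched `mu0`.
#'
#' @param design A binary [mixture_design()].
#' @param T Temperature.
#' @param P Pressure in energy units (`beta P = P / T` is used internally).
#' @param x_grid Composition grid (must include 1; descending recommended).
#' @param N Particles per NPT run.
#' @param sweeps,equil NPT sweeps and equilibration cut.
#' @param frame_stride Sweeps between stored frames.
#' @param mu0 Reference chemical potential; `NULL` leaves `mu_total` unset.
#' @param seed Optional seed.
#' @param progress Print one line per composition.
#' @return List with the [chemical_potential_curve()], the per-composition
#'   `S0` table and the mean NPT densities.
#' @export
s0_mu_pipeline <- function(design, T, P, x_grid = seq(1, 0.1, by = -0.1),
                           N = 192, sweeps = 6000, equil = 2000,
                           frame_stride = 40, mu0 = NULL, seed = NULL,
                           progress = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  x_grid <- sort(x_grid, decreasing = TRUE)
  res <- data.frame()
  for (x in x_grid) {
    nA <- round(x * N)
    st <- make_initial_config(c(nA, N - nA), 0.3, design)
    r <- run_npt(st, design, T, P, sweeps = sweeps,
                 obs_stride = 10, frame_stride = frame_stride)
    keep <- which(seq_along(r$frames) * frame_stride > equil)
    sf <- partial_structure_factors(r$frames[keep], k_max = 6,
                                    min_frames = min(50, length(keep)))
    sf <- oz_fit(sf)
    ob <- r$observables
    rho <- block_average(ob$rho[ob$sweep > equil])
    res <- rbind(res, data.frame(
      x = x, S0_AA = sf$S0_AA, S0_BB = sf$S0_BB, S0_AB = sf$S0_AB,
      se_AA = sf$se$S0_AA, se_BB = sf$se$S0_BB, se_AB = sf$se$S0_AB,
      rho = rho$mean, se_rho = rho$se))
    if (progress)
      message(sprintf("x = %.2f: rho = %.4f, S0 = (%.3f, %.3f, %.3f)",
                      x, rho$mean, sf$S0_AA, sf$S0_BB, sf$S0_AB))
  }
  curve <- excess_mu(res$x, res$S0_AA, res$S0_BB, res$S0_AB, T,
                     se = list(S0_AA = res$se_AA, S0_BB = res$se_BB,
                               S0_AB = res$se_AB))
  if (!is.null(mu0)) curve <- total_mu(curve, mu0)
  list(curve = curve, table = res, rho_mean = mean(res$rho))
}
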