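ideal_gas_frames <- function(n_frames, N = 100, L = 8, split = c(0.5, 0.5)) {
  nA <- round(split[1] * N)
  lapply(seq_len(n_frames), function(i)
    list(L = L, positions = matrix(runif(3 * N, 0, L), N, 3),
         species = rep(1:2, times = c(nA, N - nA))))
}

test_that("structure factors of an ideal gas are flat and uncorrelated", {
  set.seed(12)
  fr <- ideal_gas_frames(80)
  sf <- partial_structure_factors(fr, k_max = 5)
  expect_equal(mean(sf$S_AA), 0.5, tolerance = 0.05)
  expect_equal(mean(sf$S_BB), 0.5, tolerance = 0.05)
  expect_lt(abs(mean(sf$S_AB)), 0.03)
  expect_error(partial_structure_factors(fr[1:10]), "at least")
})

test_that("structure factors match the brute-force double sum", {
  set.seed(13)
  # correlated synthetic process: dimerized positions
  fr <- lapply(1:10, function(i) {
    L <- 7; n2 <- 30
    base <- matrix(runif(3 * n2, 0, L), n2, 3)
    pos <- rbind(base, base + matrix(rnorm(3 * n2, 0, 0.2), n2, 3)) %% L
    list(L = L, positions = pos, species = rep(1:2, each = n2))
  })
  sf <- partial_structure_factors(fr, k_max = 3, min_frames = 10)
  # independent oracle: direct pair sum over the same wavevectors
  L <- 7; N <- 60
  rng <- -3:3
  nv <- as.matrix(expand.grid(rng, rng, rng))
  n2m <- rowSums(nv^2); keep <- n2m > 0 & n2m <= 9
  nv <- nv[keep, , drop = FALSE]
  sh <- round(sqrt(n2m[keep]), 9)
  acc <- matrix(0, nrow(nv), 3)
  for (f in fr) {
    K <- 2 * pi / L * nv
    for (ik in seq_len(nrow(nv))) {
      ph <- as.numeric(f$positions %*% K[ik, ])
      sA <- f$species == 1
      rA <- sum(cos(ph[sA])) + 1i * sum(sin(ph[sA]))
      rB <- sum(cos(ph[!sA])) + 1i * sum(sin(ph[!sA]))
      acc[ik, ] <- acc[ik, ] + c(Re(rA * Conj(rA)), Re(rB * Conj(rB)),
                                 Re(rA * Conj(rB))) / N
    }
  }
  acc <- acc / length(fr)
  ug <- sort(unique(sh))
  for (j in 1:3) {
    ora <- vapply(ug, function(s) mean(acc[sh == s, j]), 0)
    got <- switch(j, sf$S_AA, sf$S_BB, sf$S_AB)
    expect_equal(got, ora, tolerance = 1e-10)
  }
})

test_that("structure factors are stable under frame-stride doubling", {
  set.seed(14)
  fr <- ideal_gas_frames(120)
  s1 <- partial_structure_factors(fr, k_max = 4)
  s2 <- partial_structure_factors(fr[seq(1, 120, by = 2)], k_max = 4)
  expect_lt(max(abs(s1$S_AA - s2$S_AA)), 0.15)
})

test_that("the Ornstein-Zernike fit recovers exact and noisy parameters", {
  k <- seq(0.25, 2, length.out = 16)
  S <- 0.7 / (1 + k^2 * 2.25)
  f <- azeopatch:::oz_fit_one(k, S)
  expect_equal(f$S0, 0.7, tolerance = 1e-10)
  expect_equal(f$xi2, 2.25, tolerance = 1e-10)
  # constant data: zero correlation length, exact S0
  fc <- azeopatch:::oz_fit_one(k, rep(0.4, 16))
  expect_equal(fc$S0, 0.4)
  expect_equal(fc$xi2, 0)
  # Gaussian noise: recovery within 3 fit standard errors
  set.seed(99)
  for (rep in 1:3) {
    Sn <- S + rnorm(length(k), 0, 0.01)
    fn <- azeopatch:::oz_fit_one(k, Sn)
    expect_lt(abs(fn$S0 - 0.7), 3 * fn$se_S0 + 0.01)
  }
  expect_error(oz_fit(structure(list(k_grid = c(0.1, 0.2), S_AA = c(1, 1),
                                     S_BB = c(1, 1), S_AB = c(0, 0),
                                     multiplicity = c(1, 1)),
                                class = "structure_factor_data")),
               "4 k-points")
})

test_that("the Kirkwood-Buff integrand vanishes for an ideal mixture", {
  xg <- seq(1, 0.05, by = -0.05)
  cv <- excess_mu(xg, S0_AA = xg, S0_BB = 1 - xg,
                  S0_AB = rep(0, length(xg)), T = 0.17)
  expect_lt(max(abs(cv$mu_ex)), 1e-12)
  cv <- total_mu(cv, 0.152)
  expect_equal(cv$mu_total[1], 0.152)                       # mu(x0) = mu0
  expect_equal(cv$mu_total, 0.152 + 0.17 * log(xg),
               tolerance = 1e-10)                           # ideal line
})

test_that("the composition integral matches a closed-form quadrature oracle", {
  # S0 inputs constructed so the integrand equals f(x) = x exactly:
  # with S0_AB = S0_BB = 0, S_cc = xB^2 S_AA and the integrand is
  # 1/(xB S_AA) - 1/x, so S_AA = x / (xB (x^2 + 1)) gives f = x.
  xg <- seq(1, 0.1, by = -0.05)
  sAA <- ifelse(xg == 1, 1, xg / ((1 - xg) * (xg^2 + 1)))
  cv <- excess_mu(xg, sAA, rep(0, length(xg)), rep(0, length(xg)), T = 1)
  expect_equal(cv$mu_ex, (xg^2 - 1) / 2, tolerance = 1e-10)
  expect_error(excess_mu(seq(0.9, 0.1, -0.1), rep(1, 9), rep(0, 9), rep(0, 9),
                         T = 1), "reach the reference")
})

test_that("species-exchange symmetry: mu_A(x) equals mu_B(1 - x) for symmetric tables", {
  # for a species-symmetric mixture the S0 table obeys
  # S_BB(x_A) = S_AA(1 - x_A); the B-species excess curve is obtained by
  # relabeling, and must coincide with the A curve on the same grid
  xg <- seq(1, 0.1, by = -0.1)
  gAA <- function(x) 0.3 + 0.2 * x
  gAB <- function(x) -0.05 * x * (1 - x)
  muA <- excess_mu(xg, gAA(xg), gAA(1 - xg), gAB(xg), T = 0.17)
  # B viewed as the "first" species at molar fraction x_B = xg
  muB <- excess_mu(xg, gAA(xg), gAA(1 - xg), gAB(1 - xg), T = 0.17)
  expect_equal(muA$mu_ex, muB$mu_ex, tolerance = 1e-10)
})
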