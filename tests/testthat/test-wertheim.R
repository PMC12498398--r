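test_that("bond strengths match the closed-form shell integral", {
  d <- build_n2c8(1, 1)
  st <- state_point(0.1, 0.2, c(0.5, 0.5))
  # low-density form against an independent quadrature of the defining integral
  bs <- compute_delta(d, st, ghs = "unit")
  w <- (1 - d$kf$cos_theta_max) / 2
  Vs <- pi / 6
  quad <- stats::integrate(function(r) 4 * pi * r^2, 1, 1.2,
                           rel.tol = 1e-12)$value
  expected <- expm1(1 / 0.1) * w^2 * quad / Vs
  expect_equal(bs$delta_matrix[1, 5], expected, tolerance = 1e-12)
  # zero-energy pairs have exactly zero bond strength
  expect_true(all(bs$delta_matrix[d$energy_matrix == 0] == 0))
  # contact and shell treatments only rescale by their correlation factor
  bc <- compute_delta(d, st, ghs = "contact")
  expect_equal(bc$delta_matrix[1, 5] / bs$delta_matrix[1, 5],
               ghs_contact_value(0.2 * pi / 6), tolerance = 1e-12)
  bsh <- compute_delta(d, st, ghs = "shell")
  expect_lt(bsh$delta_matrix[1, 5], bc$delta_matrix[1, 5])
  expect_gt(bsh$delta_matrix[1, 5], bs$delta_matrix[1, 5])
  # high-temperature limit: Delta -> 0
  hot <- compute_delta(d, state_point(1e6, 0.2, c(0.5, 0.5)))
  expect_lt(max(hot$delta_matrix), 1e-5)
})

test_that("Percus-Yevick g(r) reproduces the exact contact value", {
  for (eta in c(0.05, 0.2, 0.35)) {
    expect_equal(py_g_hs(1 + 1e-9, eta), (1 + eta / 2) / (1 - eta)^2,
                 tolerance = 1e-6)
  }
  expect_equal(py_g_hs(c(1.05, 1.15), 0), c(1, 1))
})

test_that("mass action: no bonding gives X = 1; closed forms are recovered", {
  hs <- one_species_design(eps = 0)
  ms <- solve_mass_action(hs, state_point(0.1, 0.3))
  expect_equal(unname(ms$X), rep(1, 4))
  expect_lt(ms$residual, 1e-12)

  # phi * Delta = 2 forced through the bond-strength override: X = 0.5 exactly
  di <- build_ideal_azeotrope_binary()
  phi <- 0.2 * pi / 6
  dm <- (di$energy_matrix > 0) * (2 / phi)
  ov <- list(delta_matrix = dm)
  for (x in c(0.1, 0.5, 0.9)) {
    ms <- solve_mass_action(di, state_point(0.1, 0.2, c(x, 1 - x)), delta = ov)
    expect_equal(unname(ms$X), rep(0.5, 8), tolerance = 1e-12)
  }
})

test_that("bond-exclusive designs have equal X at equimolar composition", {
  # Ns = 2 and Ns = 3; X solves X + (phi Delta / Ns) X^2 = 1 at x = 1/Ns
  cases <- list(list(d = build_n2c8(1, 1), ns = 2),
                list(d = three_species_exclusive(), ns = 3))
  for (cs in cases) {
    st <- state_point(0.12, 0.3, rep(1 / cs$ns, cs$ns))
    dd <- compute_delta(cs$d, st)
    ms <- solve_mass_action(cs$d, st, delta = dd)
    expect_lt(max(ms$X) - min(ms$X), 1e-12)
    X <- unname(ms$X[1])
    phiD <- 0.3 * pi / 6 * max(dd$delta_matrix)
    expect_equal(X + phiD / cs$ns * X^2, 1, tolerance = 1e-10)
  }
})

test_that("the ideal-azeotropic X is composition independent and matches Eq.-8 form", {
  di <- build_ideal_azeotrope_binary()
  st0 <- state_point(0.15, 0.3, c(0.5, 0.5))
  dd <- compute_delta(di, st0)
  Xref <- ideal_azeotrope_X(0.3 * pi / 6, max(dd$delta_matrix))
  for (x in c(0, 0.25, 0.5, 0.75, 1)) {
    ms <- solve_mass_action(di, state_point(0.15, 0.3, c(x, 1 - x)), delta = dd)
    expect_equal(unname(ms$X), rep(Xref, 8), tolerance = 1e-12)
  }
  # 21-point grid invariant
  Xs <- vapply(seq(0, 1, length.out = 21), function(x)
    solve_mass_action(di, state_point(0.15, 0.3, c(x, 1 - x)),
                      delta = dd)$X[[1]], 0)
  expect_lt(max(abs(Xs - Xs[11])), 1e-10)
  # closed-form limits
  expect_equal(ideal_azeotrope_X(0, 5), 1)
  expect_equal(ideal_azeotrope_X(0.5, 4), 0.5)  # phi delta = 2
})

test_that("free-energy breakdown has the designed structure and limits", {
  hs <- one_species_design(eps = 0)
  fb <- free_energy(hs, state_point(0.2, 0.3))
  expect_equal(fb$f_bonding, 0)
  expect_equal(fb$f_total, fb$f_ideal + fb$f_hs + fb$f_bonding)
  lo <- free_energy(hs, state_point(0.2, 1e-9))
  expect_lt(abs(lo$f_hs), 1e-8)
  expect_error(free_energy(hs, state_point(0.2, 6 / pi * 1.01)), "packing")

  # find the temperature at which X = 0.5 for the 4-patch fluid, then check
  # the bonding term against direct substitution: 4 (ln 1/2 - 1/4) + 2
  d4 <- one_species_design(eps = 1)
  rho <- 0.3; phi <- rho * pi / 6
  Tstar <- stats::uniroot(function(T) {
    ms <- solve_mass_action(d4, state_point(T, rho))
    ms$X[[1]] - 0.5
  }, c(0.05, 0.3), tol = 1e-12)$root
  fb <- free_energy(d4, state_point(Tstar, rho))
  expect_equal(fb$f_bonding, 4 * (log(0.5) - 0.25) + 2, tolerance = 1e-6)
  expect_lt(fb$f_bonding, 0)
})

test_that("azeotropic solutions reduce the bonding term to the one-component form", {
  d <- build_n2c8(1, 1)
  st <- state_point(0.09, 0.4, c(0.5, 0.5))
  ms <- solve_mass_action(d, st)
  expect_lt(max(ms$X) - min(ms$X), 1e-12)
  X <- ms$X[[1]]
  fb <- free_energy(d, st)
  expect_equal(fb$f_bonding, 4 * (log(X) - X / 2) + 2, tolerance = 1e-6)
})

test_that("pressure and chemical potentials match Richardson finite differences", {
  set.seed(101)
  d <- build_n2c8(1.35, 1)
  for (k in 1:4) {
    T <- runif(1, 0.09, 0.3); rho <- runif(1, 0.05, 0.6); xA <- runif(1, 0.2, 0.8)
    x <- c(xA, 1 - xA)
    st <- state_point(T, rho, x)
    P <- pressure(d, st); mu <- chemical_potentials(d, st)
    f <- function(r, xx) free_energy(d, state_point(T, r, xx))$f_total
    h <- rho * 1e-5
    d1 <- (f(rho + h, x) - f(rho - h, x)) / (2 * h)
    d2 <- (f(rho + h / 2, x) - f(rho - h / 2, x)) / h
    expect_equal(P, rho^2 * (4 * d2 - d1) / 3, tolerance = 1e-6)
    A <- function(ra, rb) (ra + rb) * f(ra + rb, c(ra, rb) / (ra + rb))
    ra <- rho * xA; rb <- rho - ra; ha <- ra * 1e-5
    m1 <- (A(ra + ha, rb) - A(ra - ha, rb)) / (2 * ha)
    m2 <- (A(ra + ha / 2, rb) - A(ra - ha / 2, rb)) / ha
    expect_equal(mu[1], (4 * m2 - m1) / 3, tolerance = 1e-6)
  }
})

test_that("hard-sphere virial limit and binary-symmetry of the EOS", {
  hs <- one_species_design(eps = 0)
  rho <- 0.005; phi <- rho * pi / 6
  expect_equal(pressure(hs, state_point(1, rho)) / rho, 1 + 4 * phi,
               tolerance = 1e-4)
  d <- build_n2c8(1, 1)
  mu <- chemical_potentials(d, state_point(0.1, 0.4, c(0.5, 0.5)))
  expect_equal(mu[1], mu[2], tolerance = 1e-12)
})

test_that("Gibbs-Duhem consistency holds at random state points", {
  set.seed(7)
  designs <- list(build_n2c8(1.2, 1), build_ideal_azeotrope_binary())
  for (k in 1:20) {
    d <- designs[[1 + k %% 2]]
    T <- runif(1, 0.08, 0.4); rho <- runif(1, 0.02, 0.7); xA <- runif(1, 0.05, 0.95)
    st <- state_point(T, rho, c(xA, 1 - xA))
    P <- pressure(d, st)
    f <- free_energy(d, st)$f_total
    mu <- chemical_potentials(d, st)
    expect_lt(abs(P / rho + f - sum(st$x * mu)), 1e-8)
  }
})
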