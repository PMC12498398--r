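test_that("the Kern-Frenkel pair energy follows the geometric criteria", {
  d <- build_n2c8(1.35, 1)
  v <- tet_vectors()[1, ]
  # complementary pair (types 1-5), patches mutually aligned: one bond of -1
  q2 <- quat_align(v, -v)
  e <- pair_energy(c(0, 0, 0), 1.1 * v, c(1, 0, 0, 0), q2, 1, 2, d)
  expect_equal(e, -1)
  # hard-core overlap
  expect_equal(pair_energy(c(0, 0, 0), 0.9 * v, c(1, 0, 0, 0), q2, 1, 2, d),
               Inf)
  # outside the shell
  expect_equal(pair_energy(c(0, 0, 0), 1.25 * v, c(1, 0, 0, 0), q2, 1, 2, d), 0)
  # patch tilted to cos(theta) = 0.97 < cos_theta_max: no bond
  ct <- 0.97; st <- sqrt(1 - ct^2)
  perp <- c(1, -1, 0) / sqrt(2)          # orthogonal to (1,1,1)/sqrt(3)
  tilted <- quat_align(v, -(ct * v + st * perp))
  expect_equal(pair_energy(c(0, 0, 0), 1.1 * v, c(1, 0, 0, 0), tilted, 1, 2, d),
               0)
  # same-species patches 2-2 are self-complementary with the tuned energy
  q22 <- quat_align(tet_vectors()[2, ], -tet_vectors()[2, ])
  e22 <- pair_energy(c(0, 0, 0), 1.1 * tet_vectors()[2, ], c(1, 0, 0, 0),
                     q22, 1, 1, d)
  expect_equal(e22, -1.35)
})

test_that("pair energy is symmetric under particle exchange", {
  set.seed(42)
  d <- build_n2c8(1, 1)
  for (k in 1:25) {
    r1 <- runif(3, 0, 5); r2 <- r1 + runif(3, -1.3, 1.3)
    q1 <- azeopatch:::random_quats(1)[1, ]; q2 <- azeopatch:::random_quats(1)[1, ]
    s <- sample(1:2, 2, replace = TRUE)
    expect_identical(pair_energy(r1, r2, q1, q2, s[1], s[2], d, L = 10),
                     pair_energy(r2, r1, q2, q1, s[2], s[1], d, L = 10))
  }
})

test_that("initial configurations are reproducible, overlap-free and counted", {
  d <- build_ideal_azeotrope_binary()
  st <- make_initial_config(c(400, 100), 0.2, d, seed = 3)
  expect_equal(as.vector(table(st$species)), c(400, 100))
  expect_equal(st$L, (500 / 0.2)^(1 / 3))
  hs <- one_species_design(eps = 0)
  st_hs <- make_initial_config(500, 0.2, hs, seed = 3)
  expect_equal(total_energy(st_hs, hs), 0)          # no overlaps
  st2 <- make_initial_config(c(400, 100), 0.2, d, seed = 3)
  expect_identical(st$positions, st2$positions)     # same seed, same config
  expect_error(make_initial_config(100, 0.9, d), "packing")
})

test_that("Gibbs moves conserve totals exactly and the energy ledger is exact", {
  d <- build_ideal_azeotrope_binary()
  set.seed(21)
  gs <- gibbs_state(make_initial_config(c(24, 24), 0.2, d),
                    make_initial_config(c(24, 24), 0.2, d))
  r <- run_gibbs(gs, d, T = 0.12, sweeps = 3000, obs_stride = 5,
                 audit_stride = 250)
  ob <- r$observables
  a <- ob[ob$box == 1, ]; b <- ob[ob$box == 2, ]
  expect_true(all(a$N + b$N == 96))
  expect_equal(max(abs(a$V + b$V - (a$V[1] + b$V[1]))), 0)
  Escale <- max(1, max(abs(ob$E)))
  expect_lt(r$max_energy_drift, 1e-9 * Escale)
  # final cached energies equal full recomputation
  expect_equal(r$state$energy, total_energy(r$state, d), tolerance = 1e-9)
  expect_equal(r$state_b$energy, total_energy(r$state_b, d), tolerance = 1e-9)
})

test_that("the AVB acceptance factors are antisymmetric under move reversal", {
  for (k in 1:10) {
    n_in <- sample(0:5, 1); n_out <- sample(1:40, 1); V <- runif(1, 100, 4000)
    fwd <- azeopatch:::avb_log_ratio_cpp("in", n_in, n_out, V, 4, 4,
                                         1, 0.2, 0.98)
    rev <- azeopatch:::avb_log_ratio_cpp("out", n_in + 1, n_out - 1, V, 4, 4,
                                         1, 0.2, 0.98)
    expect_equal(fwd + rev, 0, tolerance = 1e-12)
  }
})

test_that("AVB moves do not bias sampling of a non-interacting system", {
  hs <- one_species_design(eps = 0)
  P <- 0.29058  # Carnahan-Starling pressure of phi = 0.1 at T = 1
  set.seed(5)
  st <- make_initial_config(96, 0.18, hs)
  r0 <- run_npt(st, hs, T = 1, P = P, sweeps = 5000,
                schedule = move_schedule(p_avb = 0, p_transfer = 0))
  r1 <- run_npt(st, hs, T = 1, P = P, sweeps = 5000,
                schedule = move_schedule(p_avb = 0.3, p_transfer = 0))
  b0 <- block_average(r0$observables$rho[r0$observables$sweep > 1500])
  b1 <- block_average(r1$observables$rho[r1$observables$sweep > 1500])
  expect_lt(abs(b0$mean - b1$mean), 4 * sqrt(b0$se^2 + b1$se^2) + 1e-4)
  expect_gt(sum(r1$acceptance$avb), 0)
})

test_that("dimer bond statistics match the two-particle partition function", {
  # two particles (one per species) in a periodic box: the probability of a
  # bonded state follows from the configurational measure of the bond
  # volume. For the N2c8 pair (species 1, 2) two patch pairs can bond.
  d <- build_n2c8(1, 1)
  L <- 6; V <- L^3; T <- 0.1
  w <- (1 - d$kf$cos_theta_max) / 2
  vshell <- 4 * pi / 3 * ((1 + d$kf$delta)^3 - 1)
  m <- vshell / V * w^2                 # per complementary ordered patch pair
  npairs <- 2                           # 1-5 and 4-8
  zb <- npairs * m * exp(1 / T)
  Z <- 1 - (4 * pi / 3) / V + npairs * m * expm1(1 / T)
  p_theory <- zb / Z

  set.seed(17)
  st <- make_dimer(d, L = L)
  r <- run_nvt(st, d, T = T, sweeps = 1.5e5, obs_stride = 5,
               schedule = move_schedule(p_translate = 0.3, p_rotate = 0.3,
                                        p_avb = 0.4, p_volume = 0,
                                        p_transfer = 0))
  bonded <- as.numeric(r$observables$E < -0.5)
  ba <- block_average(bonded, nblocks = 15)
  expect_lt(abs(ba$mean - p_theory), 4 * ba$se + 0.1 * p_theory)

  # bond survival decreases with temperature (Boltzmann-suppressed binding)
  r2 <- run_nvt(st, d, T = 0.13, sweeps = 6e4, obs_stride = 5,
                schedule = move_schedule(p_translate = 0.3, p_rotate = 0.3,
                                         p_avb = 0.4, p_volume = 0,
                                         p_transfer = 0))
  p_hot <- mean(r2$observables$E < -0.5)
  expect_lt(p_hot, ba$mean)
})

test_that("grand-canonical sampling reaches the ideal-gas limit", {
  hs <- one_species_design(eps = 0)
  set.seed(31)
  st <- make_initial_config(20, 0.02, hs)
  # strongly negative mu empties the box
  r <- run_gcmc(st, hs, T = 1, mu = -12, sweeps = 2000, obs_stride = 5)
  expect_lt(mean(tail(r$observables$rho, 100)), 1e-3)
  # low-activity limit: rho -> exp(mu / T)
  st2 <- make_initial_config(20, 0.02, hs)
  r2 <- run_gcmc(st2, hs, T = 1, mu = log(0.01), sweeps = 6000, obs_stride = 5)
  ba <- block_average(r2$observables$rho[r2$observables$sweep > 1500])
  expect_equal(ba$mean, 0.01, tolerance = 0.15)
})

test_that("Gibbs coexistence densities agree with the Wertheim binodal", {
  # engine-versus-theory cross-validation on a wider-patch tetravalent fluid
  # whose bonds break often enough to equilibrate quickly
  d <- wide_patch_fluid()
  th <- binodal_point(d, T = 0.13, x = 1)
  set.seed(5)
  gs <- gibbs_state(make_initial_config(96, 0.18, d),
                    make_initial_config(96, 0.18, d))
  r <- run_gibbs(gs, d, T = 0.13, sweeps = 25000, obs_stride = 50,
                 schedule = move_schedule(p_translate = 0.3, p_rotate = 0.3,
                                          p_avb = 0.2, p_volume = 0.02,
                                          p_transfer = 0.18,
                                          transfer_bias = 0.5))
  ob <- r$observables
  late <- ob[ob$sweep > 15000, ]
  rhos <- sort(vapply(1:2, function(b) mean(late$rho[late$box == b]), 0))
  expect_lt(abs(rhos[2] - th$rho_liquid) / th$rho_liquid, 0.10)
  expect_lt(rhos[1], 0.05)   # vapor branch is nearly empty at this T
})
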