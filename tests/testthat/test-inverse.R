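test_that("a target already at the azeotrope converges without energy updates", {
  d <- build_n2c8(1, 1)
  tr <- shift_azeotrope(d, target_x = 0.5, T = 0.08)
  expect_true(tr$converged)
  expect_equal(nrow(tr$iterations), 1)
  expect_equal(tr$iterations$eps_prime[1], 1)
  expect_equal(tr$iterations$x_azeo[1], 0.5, tolerance = 1e-2)
})

test_that("the azeotropic composition responds monotonically to the tuned energy", {
  eps_grid <- c(1, 1.1, 1.2, 1.3, 1.4)
  xs <- vapply(eps_grid, function(e)
    find_azeotrope(build_n2c8(e, 1), T = 0.08)$x_azeo, 0)
  expect_true(all(diff(xs) > 0))
  # the secant step of the design loop relies on this monotonicity
  expect_gt(xs[length(xs)], 0.6)
  expect_equal(xs[1], 0.5, tolerance = 1e-2)
})

test_that("trace rows satisfy the azeotrope criterion when re-checked", {
  d <- build_n2c8(1, 1)
  tr <- shift_azeotrope(d, target_x = 0.55, T = 0.08, tol = 0.01)
  expect_true(tr$converged)
  expect_true(all(tr$iterations$eps_prime > 0))
  expect_lt(abs(tail(tr$iterations$x_azeo, 1) - 0.55), 0.01)
  for (i in seq_len(nrow(tr$iterations))) {
    row <- tr$iterations[i, ]
    di <- set_bond_energy(d, list(c(2, 2), c(3, 3)), row$eps_prime)
    bg <- azeopatch:::branch_grid(di, row$T_azeo, row$P_azeo,
                                  seq(max(0.02, row$x_azeo - 0.03),
                                      min(0.98, row$x_azeo + 0.03),
                                      length.out = 31))
    # tangency: the two branches touch at the reported composition
    expect_lt(min(abs(bg$d), na.rm = TRUE), 5e-3)
  }
})

test_that("bond-energy editing validates its inputs", {
  d <- build_n2c8(1, 1)
  expect_error(set_bond_energy(d, list(c(1, 2)), 1.5), "not a bonding edge")
  d2 <- set_bond_energy(d, list(c(2, 2), c(3, 3)), 1.35)
  expect_equal(d2$energy_matrix[2, 2], 1.35)
  expect_equal(d2$energy_matrix[1, 5], 1)
  expect_equal(self_complementary_pairs(d), list(c(2, 2), c(3, 3), c(6, 6),
                                                 c(7, 7)))
})
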