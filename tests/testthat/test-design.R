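test_that("constructors enforce the design invariants", {
  expect_error(kern_frenkel_params(delta = 1.5), "delta")
  expect_error(kern_frenkel_params(cos_theta_max = 1.2), "cos_theta_max")
  expect_error(species_spec(1, 1:4, tet_vectors() * 2), "unit")
  expect_error(species_spec(1, 1:3, tet_vectors()), "matrix")
  # asymmetric energy matrix rejected
  em <- matrix(0, 4, 4); em[1, 2] <- 1
  expect_error(mixture_design(list(species_spec(1, 1:4, tet_vectors())), em),
               "symmetric")
  em[2, 1] <- 1; em[3, 4] <- em[4, 3] <- -0.5
  expect_error(mixture_design(list(species_spec(1, 1:4, tet_vectors())), em),
               ">= 0")
  # duplicated global patch type rejected
  expect_error(mixture_design(list(species_spec(1, 1:4, tet_vectors()),
                                   species_spec(2, c(4:7), tet_vectors())),
                              matrix(0, 8, 8)), "unique")
})

test_that("the N2c8 factory reproduces the designed edge pattern", {
  expect_error(build_n2c8(0, 1), "positive")
  d <- build_n2c8(1, 1)
  ed <- bonding_edges(d)
  expect_equal(nrow(ed), 6)               # 2 cross + 4 self-complementary
  expect_true(all(ed$eps == 1))
  # every patch type has at least one partner
  expect_true(all(rowSums(d$energy_matrix > 0) >= 1))
  expect_true(is_bond_exclusive(d))
  expect_false(is_ideal_azeotropic(d))    # one partner total, not one per species
  # symmetric with zero entries for non-bonding pairs
  expect_equal(d$energy_matrix, t(d$energy_matrix))
  expect_equal(d$energy_matrix[1, 2], 0)

  dt <- build_n2c8(1.35, 1)
  idx <- which(dt$energy_matrix == 1.35, arr.ind = TRUE)
  expect_equal(nrow(idx), 2)              # exactly the 2-2 and 3-3 self-loops
  expect_equal(unname(idx), cbind(c(2, 3), c(2, 3)))
})

test_that("the ideal-azeotropic factory has one partner per species per patch", {
  d <- build_ideal_azeotrope_binary()
  adj <- d$energy_matrix > 0
  expect_true(all(rowSums(adj) == 2))     # two partners in total ...
  for (sp in d$species)                   # ... exactly one on each species
    expect_true(all(rowSums(adj[, sp$patch_type_ids]) == 1))
  expect_true(is_ideal_azeotropic(d))
  expect_false(is_bond_exclusive(d))
})

test_that("classification respects energies and isolated patches", {
  # ideal topology with one modified edge weight is no longer ideal
  d <- build_ideal_azeotrope_binary()
  em <- d$energy_matrix
  em[1, 2] <- em[2, 1] <- 1.2
  d2 <- mixture_design(d$species, em, d$kf)
  expect_false(is_ideal_azeotropic(d2))
  # a never-bonding patch breaks bond exclusivity
  d3 <- build_n2c8(1, 1)
  em <- d3$energy_matrix
  em[1, 5] <- em[5, 1] <- 0
  d4 <- mixture_design(d3$species, em, d3$kf)
  expect_false(is_bond_exclusive(d4))
})

test_that("design files round-trip and violations name the field", {
  td <- withr::local_tempdir()
  p <- file.path(td, "d.json")
  for (d in list(build_n2c8(1.35, 1), build_ideal_azeotrope_binary(),
                 three_species_exclusive())) {
    write_design(d, p)
    d2 <- read_design(p)
    expect_equal(d2$energy_matrix, d$energy_matrix)
    expect_equal(d2$kf, d$kf)
    expect_equal(lapply(d2$species, unclass), lapply(d$species, unclass),
                 tolerance = 1e-12)
  }
  # asymmetric sparse entries
  obj <- jsonlite::read_json(p, simplifyVector = TRUE)
  write_design(build_n2c8(1, 1), p)
  txt <- jsonlite::read_json(p, simplifyVector = FALSE)
  txt$energy_matrix[["5-1"]] <- 2
  jsonlite::write_json(txt, p, auto_unbox = TRUE, digits = NA)
  expect_error(read_design(p), "asymmetric")
  # patch vector / id cardinality mismatch
  write_design(build_n2c8(1, 1), p)
  txt <- jsonlite::read_json(p, simplifyVector = FALSE)
  txt$species[[1]]$patch_vectors <- txt$species[[1]]$patch_vectors[1:3]
  jsonlite::write_json(txt, p, auto_unbox = TRUE, digits = NA)
  expect_error(read_design(p), "patch_vectors")
  # missing top-level field
  jsonlite::write_json(list(species = list()), p, auto_unbox = TRUE)
  expect_error(read_design(p), "kern_frenkel")
})
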