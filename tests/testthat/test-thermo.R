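test_that("standard-state correction for a 12 nm cubic box", {
  expect_equal(standard_state_correction(12^3, 298.15), -17.2,
               tolerance = 0.002)
  expect_equal(standard_state_correction(1.66054), 0)
  expect_equal(standard_state_correction(exp(1) * 1.66054, 298.15),
               -kB * 298.15)
  expect_error(standard_state_correction(-5), "positive")
})

test_that("standard unbinding free energies from box values", {
  expect_equal(standard_unbinding(-60, 12^3, 298.15), 77.22, tolerance = 0.01)
  expect_equal(standard_unbinding(-25, 12^3, 298.15), 42.22, tolerance = 0.01)
  corr <- standard_state_correction(12^3, 298.15)
  expect_equal(standard_unbinding(-corr, 12^3, 298.15), 0)
  # round trip: negating twice returns the box input
  expect_equal(-standard_unbinding(-60, 12^3, 298.15) - corr, -60)
})

test_that("population depletion factor is the Boltzmann fold-change", {
  expect_equal(population_depletion_factor(25, 298.15), 2.4e4,
               tolerance = 0.01)
  expect_equal(population_depletion_factor(0), 1)
  expect_equal(population_depletion_factor(kB * 298.15 * log(10)), 10)
  # multiplicative in the penalty
  expect_equal(population_depletion_factor(7) * population_depletion_factor(5),
               population_depletion_factor(12))
  expect_error(population_depletion_factor(25, -10), "positive")
})

test_that("per-monomer division", {
  expect_equal(per_monomer(77, 4), 19.25)
  expect_equal(per_monomer(42, 4), 10.5)
  expect_equal(per_monomer(42, 1), 42)
  expect_error(per_monomer(42, 0), "n_monomers")
})

test_that("fold-surface free energy converts to a molar detachment cost", {
  expect_equal(fold_surface_cost(surface_energetics(0.106, 0.20)), 25.5,
               tolerance = 0.05)
  expect_equal(fold_surface_cost(surface_energetics(0, 0.20)), 0)
  expect_equal(fold_surface_cost(surface_energetics(0.106, 0.40)),
               2 * fold_surface_cost(surface_energetics(0.106, 0.20)))
  expect_error(surface_energetics(-1, 0.2))
})

test_that("the bookkeeping chain reproduces all headline numbers quickly", {
  t0 <- Sys.time()
  corr <- standard_state_correction(12^3, 298.15)
  vals <- c(corr,
            standard_unbinding(-60, 12^3, 298.15),
            standard_unbinding(-25, 12^3, 298.15),
            per_monomer(standard_unbinding(-60, 12^3, 298.15), 4),
            per_monomer(standard_unbinding(-25, 12^3, 298.15), 4),
            population_depletion_factor(25, 298.15),
            fold_surface_cost())
  expect_equal(vals, c(-17.22, 77.22, 42.22, 19.31, 10.56, 23978, 25.53),
               tolerance = 0.001)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
})
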