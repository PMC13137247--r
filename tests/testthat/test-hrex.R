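test_that("geometric ladder reproduces the published eight-replica values", {
  lam <- lambda_ladder(8, 0.426934)
  printed <- c(1, 0.885511, 0.784132, 0.694357, 0.614861, 0.544467,
               0.482133, 0.426934)
  expect_true(all(abs(as.numeric(lam) - printed) < 1e-6))
  expect_identical(lam[1], 1)                 # endpoints exact
  expect_identical(lam[8], 0.426934)
  expect_true(all(diff(lam) < 0))
})

test_that("ladder construction is geometric and validated", {
  expect_equal(as.numeric(lambda_ladder(2, 0.5)), c(1, 0.5))
  expect_equal(as.numeric(lambda_ladder(3, 0.25)), c(1, 0.5, 0.25))
  expect_error(lambda_ladder(4, 1.2), "lambda_min")
  expect_error(lambda_ladder(4, 1), "lambda_min")
  expect_error(lambda_ladder(1, 0.5))
})

test_that("exchange probability is the Metropolis factor", {
  expect_equal(exchange_probability(-3, -7, 2, -2, 300), 1) # identical H
  kT <- kB * 300
  # delta = kT log 2 -> acceptance one half
  expect_equal(exchange_probability(0, kT * log(2), 0, 0, 300), 0.5)
  expect_equal(exchange_probability(5, 1, 2, 4, 300), 1)    # delta <= 0
  # symmetric under relabeling the replicas
  set.seed(2)
  for (i in 1:10) {
    e <- rnorm(4, 0, 10)
    expect_equal(exchange_probability(e[1], e[2], e[3], e[4], 300),
                 exchange_probability(e[4], e[3], e[2], e[1], 300))
  }
  expect_error(exchange_probability(0, 0, 0, 0, -1), "temperature")
})

test_that("solute scaling touches only the scalable terms", {
  sys <- cg_chain_system(default_geom, default_pot,
                         wall_restraint("d1", 2.4, 1500))
  terms <- hamiltonian_terms(sys)
  set.seed(4)
  for (i in 1:10) {
    psi <- runif(4, -180, 180)
    expect_equal(hamiltonian_energy(scale_hamiltonian(terms, 1), psi),
                 hamiltonian_energy(terms, psi))      # identity at lambda 1
  }
  half <- scale_hamiltonian(terms, 0.5)
  psi <- c(70, 180, -70, 180)
  wallpart <- wall_energy(petfes:::chain_d1(default_geom, psi),
                          sys$restraint)
  torspart <- sum(torsion_energy(default_pot, psi))
  expect_equal(hamiltonian_energy(half, psi), 0.5 * torspart + wallpart)
  # the gauche-trans barrier scales linearly with lambda
  dwsys <- double_well_system(height = 10)
  t2 <- scale_hamiltonian(hamiltonian_terms(dwsys), 0.3)
  expect_equal(hamiltonian_energy(t2, 0) - hamiltonian_energy(t2, 1),
               0.3 * 10)
  expect_error(scale_hamiltonian(terms, 0), "lambda")
  expect_error(scale_hamiltonian(terms, 1.5), "lambda")
})

test_that("a single-replica ladder reduces to plain wt-MTD", {
  sys <- double_well_system(12, 1, 0.15)
  bias <- metad_bias("s", sigma = 0.05, w0 = 0.5, gamma = 15, pace = 500)
  lad1 <- structure(1, class = "replica_ladder")
  h <- run_hrex_wtmtd(sys, lad1, bias, n_sweeps = 20000,
                      exchange_interval = 500, seed = 5, thin = 10)
  p <- run_wtmtd(sys, bias, n_sweeps = 20000, seed = 5, thin = 10)
  expect_equal(h$trajectories[[1]]$s, p$trajectory$s)
  expect_equal(h$bias[[1]]$heights, p$bias$heights)
})

test_that("identical Hamiltonians accept every exchange", {
  sys <- double_well_system(12, 1, 0.15)
  lad <- structure(c(1, 1, 1), class = "replica_ladder")
  h <- run_hrex_wtmtd(sys, lad, NULL, n_sweeps = 4000,
                      exchange_interval = 200, seed = 6, thin = 10)
  expect_true(all(h$exchange$rate == 1))
  expect_true(all(h$exchange$acceptances <= h$exchange$attempts))
})

test_that("unscaled-replica statistics are invariant to ladder depth", {
  # instantly mixing toy (proposal sd comparable to the well separation)
  sys <- double_well_system(height = 6, s0 = 1, step_sd = 2.5)
  edges <- c(-Inf, seq(-1.5, 1.5, by = 0.5), Inf)
  counts <- lapply(list(structure(1, class = "replica_ladder"),
                        lambda_ladder(4, 0.45)), function(lad) {
    h <- run_hrex_wtmtd(sys, lad, NULL, n_sweeps = 30000,
                        exchange_interval = 500, seed = 8, thin = 10)
    table(cut(h$trajectories[[1]]$s, edges))
  })
  chi <- suppressWarnings(chisq.test(rbind(as.numeric(counts[[1]]),
                                           as.numeric(counts[[2]]))))
  expect_gt(chi$p.value, 0.01)
})

test_that("deep-ladder exchanges actually mix and are bookkept", {
  sys <- double_well_system(12, 1, 0.15)
  h <- run_hrex_wtmtd(sys, lambda_ladder(4, 0.45), NULL, n_sweeps = 10000,
                      exchange_interval = 500, seed = 9, thin = 10)
  expect_equal(nrow(h$exchange), 3)
  expect_true(all(h$exchange$attempts > 0))
  expect_true(all(h$exchange$rate >= 0 & h$exchange$rate <= 1))
  expect_equal(h$analysis_replica, 1L)
  expect_equal(attr(h$trajectories[[1]], "lambda"), 1)
})
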