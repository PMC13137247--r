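test_that("gt_ratio counts labels over all torsions and frames", {
  tr <- data.frame(time = 1:3, psi1 = rep(180, 3), psi2 = rep(175, 3))
  expect_equal(gt_ratio(tr), c(gauche = 0, trans = 1))
  tr2 <- data.frame(time = 1:2, psi1 = c(70, 180), psi2 = c(180, -70))
  expect_equal(gt_ratio(tr2), c(gauche = 0.5, trans = 0.5))
  expect_equal(sum(gt_ratio(tr2)), 1)
  expect_error(gt_ratio(data.frame(time = numeric(0), psi1 = numeric(0))),
               "empty")
})

test_that("an exact two-state Boltzmann sample reproduces 91:9", {
  tr <- generate_fixture(fixture_spec(
    "two_state_torsion", n = 20000, seed = 11,
    params = list(gt_gap = -4.09, temperature = 303.15, jitter = 5)))
  r <- gt_ratio(tr)
  expect_equal(r[["gauche"]], 0.91, tolerance = 0.01)
  expect_equal(r[["trans"]], 0.09, tolerance = 0.1)
})

test_that("trajectories are reproducible from the seed", {
  w <- wall_restraint("d1", 2.4, 1500)
  a <- sample_chain(default_geom, default_pot, w, n_sweeps = 2000, seed = 42)
  b <- sample_chain(default_geom, default_pot, w, n_sweeps = 2000, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- sample_chain(default_geom, default_pot, w, n_sweeps = 2000, seed = 43)
  expect_false(identical(a$d1, c$d1))
})

test_that("sampled torsion distribution matches the Boltzmann density", {
  # unrestrained chain: torsions are independent, so the pooled histogram
  # must match the single-torsion quadrature density (chi-square, alpha 0.01)
  pot <- torsion_potential(gt_gap = -5, barrier = 16)
  tr <- sample_chain(default_geom, pot, NULL, n_sweeps = 3e4, seed = 7,
                     thin = 10, burnin = 0.1)
  psi <- c(as.matrix(tr[paste0("psi", 1:4)]))
  edges <- seq(-180, 180, by = 20)
  obs <- table(cut(psi, edges))
  q <- torsion_boltzmann(pot, 300)
  p_exp <- vapply(seq_len(length(edges) - 1), function(i)
    sum(q$density[q$psi > edges[i] & q$psi <= edges[i + 1]]), numeric(1))
  keep <- p_exp * length(psi) >= 5
  chi <- suppressWarnings(
    chisq.test(as.numeric(obs[keep]), p = p_exp[keep] / sum(p_exp[keep])))
  expect_gt(chi$p.value, 0.01)
})

test_that("trans fraction is monotone in the lower-wall position", {
  sc <- scan_d1(default_geom, default_pot, c(0.5, 2.0, 2.8, 3.4, 4.0),
                n_sweeps = 15000, seed = 5)
  # allow 3-sigma sampling noise: binomial SE on ~45k torsion draws
  se <- 3 * sqrt(0.25 / (15000 * 0.8 * 4))
  expect_true(all(diff(sc$trans) > -3 * se))
  expect_gt(sc$trans[5], 0.99)
  expect_lt(sc$trans[2], 0.5)
})

test_that("an energetically excluded gauche state never appears", {
  pot <- torsion_potential(gt_gap = 150, barrier = 200)
  tr <- sample_chain(default_geom, pot, NULL, n_sweeps = 5000, seed = 3)
  expect_equal(gt_ratio(tr)[["trans"]], 1)
})

test_that("unrestrained equilibrium is recovered for a zero-k wall", {
  sc0 <- scan_d1(default_geom, default_pot, 2.4, n_sweeps = 10000, seed = 9,
                 k = 0)
  free <- gt_ratio(sample_chain(default_geom, default_pot, NULL,
                                n_sweeps = 10000, seed = 10, burnin = 0.2))
  expect_equal(sc0$gauche, free[["gauche"]], tolerance = 0.03)
})
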