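kT300 <- kB * 300

test_that("weights are uniform for zero or constant bias", {
  tr <- cv_trajectory(data.frame(time = 1:100, s = rnorm(100)),
                      temperature = 300)
  expect_equal(frame_weights(tr, NULL), rep(1 / 100, 100))
  # a kernel far wider than the data range is constant over it: shift
  # invariance of the reweighting
  b <- metad_bias("s", sigma = 1e6, w0 = 0.5, gamma = 15)
  b <- deposit(b, 0, temperature = 300)
  expect_equal(frame_weights(tr, b), rep(1 / 100, 100), tolerance = 1e-9)
  expect_error(frame_weights(tr, metad_bias("q", 1, 1, 2)), "biased CV")
})

test_that("reweighting a Gaussian-kernel-biased Gaussian recovers its moments", {
  # unbiased target: N(0, sigma0^2); sampling density multiplied by
  # exp(-V(s)/kT) with V one repulsive Gaussian at the origin
  sigma0 <- 0.2
  b <- metad_bias("s", sigma = 0.3, w0 = 0.5, gamma = 15)
  b <- deposit(b, 0, temperature = 300); b$heights <- 4 # one tall kernel
  grid <- seq(-1, 1, length.out = 8001)
  logdens <- -grid^2 / (2 * sigma0^2) - evaluate_bias(b, grid) / kT300
  dens <- exp(logdens - max(logdens))
  cdf <- cumsum(dens) / sum(dens)
  set.seed(13)
  s <- grid[findInterval(runif(2e5, min(cdf), 1), cdf) + 1]
  tr <- cv_trajectory(data.frame(time = seq_along(s), s = s),
                      temperature = 300)
  w <- frame_weights(tr, b)
  expect_equal(sum(w), 1)
  expect_equal(sum(w * s^2), sigma0^2, tolerance = 0.02)  # variance, closed form
  expect_equal(sum(w * s), 0, tolerance = 3 * sigma0 / sqrt(2e4))
})

test_that("free-energy surfaces follow -kT log(p), shifted to zero", {
  # two-bin system with 0.9/0.1 populations
  tr <- cv_trajectory(data.frame(time = 1:1000,
                                 s = rep(c(0.25, 0.75), c(900, 100))),
                      temperature = 300)
  f <- make_fes(tr, NULL, "s", bins = list(c(0, 0.5, 1)))
  expect_equal(min(f$F[f$occupied]), 0)
  expect_equal(f$F[2] - f$F[1], kT300 * log(9), tolerance = 1e-10)
  expect_equal(kT300 * log(9), 5.48, tolerance = 0.01)
  # Gaussian samples give a quadratic surface with curvature kT/sigma^2
  set.seed(3)
  s <- rnorm(2e5, 0, 0.1)
  trg <- cv_trajectory(data.frame(time = seq_along(s), s = s),
                       temperature = 300)
  fg <- make_fes(trg, NULL, "s", bins = list(seq(-0.25, 0.25, by = 0.02)))
  ctr <- fg$centers[[1]]
  sel <- fg$occupied & abs(ctr) < 0.2
  fit <- lm(fg$F[sel] ~ I(ctr[sel]^2))
  expect_equal(unname(coef(fit)[2]), kT300 / (2 * 0.1^2), tolerance = 0.05)
  # unoccupied bins are NA-flagged, not zero
  f2 <- make_fes(tr, NULL, "s", bins = list(c(0, 0.4, 0.6, 1)))
  expect_true(is.na(f2$F[2]))
  expect_false(f2$occupied[2])
  expect_error(make_fes(tr, rep(0, 1000), "s"), "zero total weight")
})

test_that("a flat distribution yields a flat surface", {
  set.seed(5)
  tr <- cv_trajectory(data.frame(time = 1:5e4, s = runif(5e4)),
                      temperature = 300)
  f <- make_fes(tr, NULL, "s", bins = 20)
  expect_lt(max(f$F[f$occupied]), 0.2)
})

test_that("unbiased analysis with and without reweighting is identical", {
  tr <- generate_fixture(fixture_spec("double_well_cv", 5000, seed = 21))
  f1 <- make_fes(tr, NULL, "s", bins = 40)
  f2 <- make_fes(tr, frame_weights(tr, NULL), "s", bins = 40)
  expect_equal(f1$F, f2$F)
})

test_that("2-D surfaces bin both variables", {
  set.seed(8)
  tr <- cv_trajectory(data.frame(time = 1:2e4, h0 = rnorm(2e4, 0.4, 0.05),
                                 h1 = rnorm(2e4, 0.4, 0.05)),
                      temperature = 300)
  f <- make_fes(tr, NULL, c("h0", "h1"), bins = 15)
  expect_equal(dim(f$F), c(15, 15))
  expect_equal(min(f$F[f$occupied]), 0)
})

test_that("block errors behave like a bootstrap standard error", {
  expect_error(block_error(data.frame(s = 1:10), NULL, "s", n_blocks = 1),
               "n_blocks")
  # identical repeated blocks -> zero error
  blk <- data.frame(time = 1:50, s = rep(seq(0.05, 0.95, 0.1), 5))
  tr <- cv_trajectory(blk[rep(1:50, 4), ], temperature = 300)
  err <- block_error(tr, NULL, "s", bins = c(0, 0.5, 1), n_blocks = 4)
  expect_equal(err, c(0, 0), tolerance = 1e-12)
  # i.i.d. frames: block error vs bootstrap within 20 percent
  set.seed(17)
  s <- rnorm(2e4, 0, 0.15)
  tr2 <- cv_trajectory(data.frame(time = seq_along(s), s = s),
                       temperature = 300)
  edges <- seq(-0.3, 0.3, by = 0.1)
  be <- block_error(tr2, NULL, "s", bins = edges, n_blocks = 50)
  boot <- replicate(200, {
    i <- sample.int(2e4, replace = TRUE)
    p <- table(cut(s[i], edges)) / 2e4
    -kT300 * log(as.numeric(p))
  })
  bse <- apply(boot, 1, sd)
  sel <- is.finite(be) & bse > 0
  # per-bin ratios carry ~10% estimator noise (50 blocks); the aggregate
  # level must agree within 20%
  expect_lt(abs(mean(be[sel] / bse[sel]) - 1), 0.2)
  expect_true(all(abs(be[sel] / bse[sel] - 1) < 0.5))
  # invariance to a constant shift of the bias (weights renormalize)
  w <- rep(1 / 2e4, 2e4)
  expect_equal(block_error(tr2, w * 7, "s", bins = edges, n_blocks = 10),
               block_error(tr2, w, "s", bins = edges, n_blocks = 10))
})

test_that("bound/unbound integration gives -kT log of the weight ratio", {
  part <- state_partition("d_COM", 3, "below")
  tr <- cv_trajectory(data.frame(time = 1:1000,
                                 d_COM = rep(c(2, 4), c(900, 100))),
                      temperature = 300)
  r <- state_delta_f(tr, NULL, part)
  expect_equal(r$dF, -kT300 * log(9))
  expect_equal(r$dF, -5.48, tolerance = 0.01)
  # frames exactly at the threshold count as bound
  tr_thr <- cv_trajectory(data.frame(time = 1:2, d_COM = c(3, 4)),
                          temperature = 300)
  expect_equal(state_delta_f(tr_thr, NULL, part)$dF, 0)
  # antisymmetry under swapping the regions
  part_up <- state_partition("d_COM", 3, "above")
  expect_equal(state_delta_f(tr, NULL, part_up)$dF, -r$dF)
  # empty region is an error
  allb <- cv_trajectory(data.frame(time = 1:5, d_COM = rep(1, 5)),
                        temperature = 300)
  expect_error(state_delta_f(allb, NULL, part), "undefined dF")
  # symmetric double well partitioned at its symmetry point
  dw <- generate_fixture(fixture_spec("double_well_cv", 40000, seed = 31))
  r0 <- state_delta_f(dw, NULL, state_partition("s", 0, "below"))
  expect_lt(abs(r0$dF), 3 * max(r0$error, 0.05))
})

test_that("delta F is additive over a three-way split of closed-form weights", {
  kT <- kT300
  tr <- cv_trajectory(data.frame(time = 1:1000,
                                 s = rep(c(1, 2, 3), c(500, 300, 200))),
                      temperature = 300)
  dAB <- -kT * log(500 / 300)
  dBC <- -kT * log(300 / 200)
  dAC <- -kT * log(500 / 200)
  expect_equal(dAB + dBC, dAC)
  # and the implementation reproduces each pairwise value on subsets
  sub <- tr[tr$s != 3, ]; attr(sub, "temperature") <- 300
  expect_equal(state_delta_f(sub, NULL, state_partition("s", 1.5))$dF, dAB)
})

test_that("convergence series ends at the full-trajectory estimate", {
  tr <- generate_fixture(fixture_spec("bound_unbound_mixture", 8000, seed = 41,
                                      params = list(delta_f = -5.48)))
  part <- state_partition("d_COM", 3, "below")
  ser <- convergence_series(tr, NULL, part, window = 2000, stride = 1500)
  full <- state_delta_f(tr, NULL, part)
  expect_equal(ser$dF[nrow(ser)], full$dF)
  expect_equal(ser$frames[nrow(ser)], 8000)
  # stationary data: the series stays within noise of the truth
  expect_true(all(abs(ser$dF - (-5.48)) < 0.5))
  expect_error(convergence_series(tr, NULL, part, window = 100, stride = 0),
               "stride")
  expect_error(convergence_series(tr, NULL, part, window = 1e6, stride = 10),
               "window")
})

test_that("a population shift mid-run drifts then plateaus", {
  # regime 1 (5% of frames): equal populations; regime 2: 9:1 mixture
  set.seed(51)
  n1 <- 1000; n2 <- 19000
  d <- c(ifelse(runif(n1) < 0.5, 2, 4), ifelse(runif(n2) < 0.9, 2, 4))
  tr <- cv_trajectory(data.frame(time = seq_along(d), d_COM = d),
                      temperature = 300)
  part <- state_partition("d_COM", 3, "below")
  ser <- convergence_series(tr, NULL, part, window = 500, stride = 500)
  expect_gt(ser$dF[1], -1)                         # starts near 0
  plateau <- -kT300 * log(0.9 / 0.1)
  expect_equal(ser$dF[nrow(ser)], plateau, tolerance = 0.15)
})

test_that("relative free-energy differences propagate errors in quadrature", {
  a <- free_energy_result(-25, 0.3, system = "aPET")
  cpet <- free_energy_result(-60, 0.4, system = "cPET")
  dd <- delta_delta_f(a, cpet)
  expect_equal(dd$dF, 35)
  expect_equal(dd$error, sqrt(0.3^2 + 0.4^2))
  expect_equal(delta_delta_f(a, a)$dF, 0)
  expect_equal(delta_delta_f(cpet, a)$dF, -dd$dF)   # antisymmetry
  b2 <- free_energy_result(-60, 0.4, temperature = 310)
  expect_error(delta_delta_f(a, b2), "temperature")
})
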