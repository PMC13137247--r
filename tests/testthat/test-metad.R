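test_that("well-tempered height rule", {
  expect_equal(wt_height(0, 0.5, 15, 300), 0.5)
  expect_equal(wt_height(123, 0.5, Inf, 300), 0.5)   # standard-MTD limit
  V <- kB * 14 * 300
  expect_equal(wt_height(V, 0.5, 15, 300), 0.5 / exp(1))
  expect_true(all(diff(wt_height(seq(0, 10, 1), 0.5, 15, 300)) < 0))
  expect_error(wt_height(0, 0.5, 1, 300), "bias factor")
  expect_error(wt_height(0, 0.5, 0.5, 300), "bias factor")
})

test_that("bias evaluation is a Gaussian kernel sum", {
  b <- metad_bias("d1", sigma = 0.05, w0 = 0.5, gamma = 15)
  expect_equal(evaluate_bias(b, 1.0), 0)              # empty bias
  b <- deposit(b, 2.0, temperature = 300)
  expect_equal(evaluate_bias(b, 2.0), 0.5)            # at its center
  expect_equal(evaluate_bias(b, 2.05), 0.5 * exp(-0.5))  # one sigma away
  expect_error(evaluate_bias(b, matrix(1, 1, 2)), "dimension mismatch")
  b2 <- metad_bias(c("h0", "h1"), sigma = c(0.05, 0.1), w0 = 1, gamma = 10)
  b2 <- deposit(b2, c(0.3, 0.4), temperature = 300)
  expect_equal(evaluate_bias(b2, c(0.3, 0.4)), 1)
  expect_equal(evaluate_bias(b2, c(0.35, 0.5)), exp(-0.5 * (1 + 1)))
})

test_that("sequential deposits damp by the accumulated bias", {
  b <- metad_bias("d1", sigma = 0.05, w0 = 0.5, gamma = 15)
  b <- deposit(b, 2.0, temperature = 300)
  expect_equal(b$heights[1], 0.5)                     # first deposit: full w0
  b <- deposit(b, 2.0, temperature = 300)
  expect_equal(b$heights[2], 0.5 * exp(-0.5 / (kB * 14 * 300)))
  v1 <- evaluate_bias(b, 2.0)
  b <- deposit(b, 2.0, temperature = 300)
  expect_gt(evaluate_bias(b, 2.0), v1)                # bias grows monotonically
  # total bias is non-decreasing everywhere over deposits
  pts <- seq(1.5, 2.5, by = 0.1)
  v_before <- evaluate_bias(b, pts)
  b <- deposit(b, 2.2, temperature = 300)
  expect_true(all(evaluate_bias(b, pts) >= v_before))
})

test_that("replica-scaled heights follow w / lambda", {
  expect_equal(replica_scaled_height(0.5, 1), 0.5)
  expect_equal(replica_scaled_height(0.5, 0.5), 1.0)
  expect_equal(replica_scaled_height(0.5, 0.426934), 0.5 / 0.426934)
  expect_equal(replica_scaled_height(0.5, 0.426934), 1.1712, tolerance = 1e-4)
  expect_error(replica_scaled_height(0.5, 0), "lambda")
})

test_that("bias checkpoints round-trip with identical values", {
  b <- metad_bias("d1", sigma = 0.05, w0 = 0.5, gamma = 15, pace = 500)
  set.seed(1)
  for (x in runif(25, 1, 3)) b <- deposit(b, x, temperature = 300)
  path <- withr::local_tempfile(fileext = ".checkpoint")
  write_bias_checkpoint(b, path)
  b2 <- read_bias_checkpoint(path)
  expect_equal(b2$centers, b$centers)
  expect_equal(b2$heights, b$heights)
  expect_equal(b2$sigma, b$sigma)
  expect_equal(b2$gamma, b$gamma)
  expect_equal(b2$w0, b$w0)
  # second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".checkpoint")
  write_bias_checkpoint(b2, path2)
  expect_identical(readLines(path), readLines(path2))
})
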