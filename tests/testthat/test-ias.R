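test_that("the Bayes mapping gives nu^2 sqrt(2) / theta0", {
  expect_equal(gamma_from_bayes(0.001, 1), sqrt(2) * 1e-6, tolerance = 1e-15)
  expect_equal(gamma_from_bayes(0.001, sqrt(2)), 1e-6, tolerance = 1e-15)
  expect_error(gamma_from_bayes(0, 1), "positive")
  expect_error(gamma_from_bayes(0.001, -2), "positive")
  cfg <- ias_config(nu = 0.01, theta0 = 2)
  expect_equal(cfg$gamma, 1e-4 * sqrt(2) / 2)
  expect_error(ias_config(gamma = 1, nu = 0.001, theta0 = 1), "conflicts")
})

test_that("the three IAS update routes coincide", {
  set.seed(3)
  L <- matrix(rnorm(12 * 40), 12)
  y <- L[, 7] + 0.5 * L[, 20]
  cfg <- ias_config(n_iter = 15L)
  xs <- lapply(c("dual", "normal", "stacked"),
               function(m) ias_solve(L, y, cfg, method = m)$x)
  expect_equal(xs[[1]], xs[[2]], tolerance = 1e-8)
  expect_equal(xs[[1]], xs[[3]], tolerance = 1e-8)
})

test_that("noiseless single-source data concentrates on the generating column", {
  set.seed(8)
  # well-separated dictionary: near-orthogonal random columns
  L <- qr.Q(qr(matrix(rnorm(40 * 40), 40)))[, 1:30]
  k <- 13L
  y <- L[, k]
  est <- ias_solve(L, y, ias_config(n_iter = 50L))
  expect_gt(abs(est$x[k]) / sum(abs(est$x)), 0.9)
  expect_lte(tail(est$objective, 1L), est$objective[1])
})

test_that("vanishing penalty reproduces least squares when M <= L", {
  set.seed(5)
  L <- matrix(rnorm(20 * 8), 20)
  y <- rnorm(20)
  est <- ias_solve(L, y, ias_config(gamma = 1e-16, nu = NULL, theta0 = NULL,
                                    n_iter = 30L))
  expect_equal(est$x, qr.solve(L, y), tolerance = 1e-6)
})

test_that("degenerate data and estimates are flagged", {
  L <- matrix(rnorm(10 * 5), 10)
  est <- ias_solve(L, numeric(10), ias_config())
  expect_true(est$degenerate)
  expect_equal(est$x, numeric(5))
  expect_error(ias_solve(matrix(c(1, NA), 1), 1, ias_config()), "non-finite")
  expect_error(dipole_from_estimate(numeric(3),
                                    list(positions = diag(3), moments = diag(3))),
               "degenerate")
})

test_that("the dipole summary is the |x|-weighted average", {
  space <- list(positions = rbind(c(1, 0, 0), c(0, 1, 0), c(3, 3, 3)),
                moments = rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)))
  one <- dipole_from_estimate(c(0, 2, 0), space)
  expect_equal(one$position, c(0, 1, 0))
  expect_equal(one$moment, c(1, 0, 0))
  two <- dipole_from_estimate(c(1, -1, 0), space)   # sign-invariant weights
  expect_equal(two$position, c(0.5, 0.5, 0))
  expect_equal(two$moment, c(0.5, 0, 0.5))
  flip <- dipole_from_estimate(c(-1, 1, 0), space)
  expect_equal(flip, two)
})

test_that("tidy and glance summarize an estimate", {
  set.seed(2)
  L <- matrix(rnorm(10 * 6), 10)
  est <- ias_solve(L, L[, 2], ias_config(n_iter = 10L))
  td <- tidy(est)
  expect_equal(nrow(td), 6L)
  gl <- glance(est)
  expect_equal(gl$n_iter, 10L)
  expect_equal(gl$l1_norm, sum(abs(est$x)))
  expect_false(gl$degenerate)
})
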